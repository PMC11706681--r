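---
title: "Methods: spatiotemporal statistics of mitotic events in root tips"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal statistics of mitotic events in root tips}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodyn)
```

# The data and the questions

Time-lapse light-sheet imaging of a root meristem produces, after
segmentation and tracking (which are upstream of this package), a table
of mitotic events: for each detected cell division, the root it occurred
in, the experimental condition (`intact` or `regenerating`, i.e. tip
excised), the frame index, and a 3D centre of mass in micrometres. The
frame cadence is 15 minutes (`delta_t_h = 0.25`) for up to 7 days
(672 frames); time in hours is always `frame_index * delta_t_h`, with
the first frame defining t = 0. Excision is taken to coincide with the
start of imaging; the package has no separate excision-time parameter.

The analyses answer three questions. Is the *temporal* sequence of
divisions random, bursty, or periodic? Are divisions *spatially*
clustered, and at what scale? And *when*, after excision, do
regenerating roots start to differ from intact ones?

Coordinates are absolute microscope-frame micrometres. Because a root
tip offers no persistent landmark over days of growth, no coordinate
normalisation is attempted and only relative (within-frame) distances
are ever analysed.

# Temporal analysis

**Counts and bursts.** `counts_per_frame()` turns the event table into a
per-root series N(t) on the full frame grid (zeros included; the package
requires a complete grid — gapped recordings must be zero-filled
explicitly, and the values then underestimate activity in the gaps). A
*burst* is a frame with N(t) at or above `mean(N) + 1·sd(N)`; its size
is N(t) itself. Two conventions deserve note:

- *Pooling.* `burst_threshold()` pools the per-frame counts of all
  series it is given before computing mean and SD, so passing a
  condition's four roots yields one threshold per condition — matching
  how a single threshold value per condition is usually reported.
  Passing a single series gives per-root thresholds instead; the scope
  is the caller's choice and is recorded in pipeline metadata.
- *SD flavour.* Sample SD (n−1) by default; `sd_type = "population"` is
  available. With thousands of frames the difference is negligible, but
  the choice is recorded.
- The comparison is inclusive (≥), and zero-count frames are never
  bursts even when the threshold is ≤ 0 (a burst is a collection of
  events, so it must be nonempty).

**Poisson null.** If divisions were uncorrelated, per-frame counts (and
burst sizes) would be Poissonian. `mode_matched_poisson(m)` builds the
null "peaking at m": any rate in `[m, m+1)` has mode m, and the midpoint
`λ = m + 0.5` is used so the match does not sit on the boundary where
two modes tie; the offset is configurable. `compare_to_poisson()`
evaluates the one-sample K-S statistic on the integer support (both CDFs
jump only at integers, so the supremum is attained there) and returns
overlay data for plotting. Its asymptotic p-value is conservative for a
discrete null — it is reported as a descriptive divergence measure, as
is standard for this comparison.

A structural caveat, verified by simulation during development: burst
sizes extracted from *any* thresholded series are a tail-truncated
version of the count distribution, so even a purely Poissonian series
yields a burst-size sample that a full Poisson matched at the burst-size
mode cannot fit (the null has ~40% of its mass below the truncation
point). The mode-matched comparison is therefore informative about the
*shape of the tail* (e.g. bimodality from injected bursts), not a
goodness-of-fit test whose null is ever "accepted"; the package's test
suite documents this property rather than asserting the contrary.

**Periodogram.** `periodogram()` computes the plain FFT periodogram of
the mean-removed series: one-sided PSD on the native Fourier grid,
unwindowed and untapered (the minimal "standard spectral analysis");
Welch averaging or tapering can be layered on by the user but are not
defaults. The scaling satisfies the discrete Parseval identity
`sum(psd) * df = Var(N)` exactly (population variance of the
mean-removed series), which the tests check to 1e-8 relative tolerance
on random series. Peaks are local PSD maxima (DC excluded by
construction), and `top_periods()` flags each against a
Bonferroni-corrected white-noise level: under white noise the PSD
ordinates are asymptotically exponential with mean equal to the average
PSD, so a peak is significant at family level α when its power exceeds
`mean(psd) * log(m/α)` over m bins. This is an approximate,
descriptive flag, not a calibrated test against coloured noise.

With several roots per condition, `condition_periodogram()` computes one
periodogram per root and averages PSDs bin-wise. Averaging (rather than
concatenating or summing series) keeps root-to-root amplitude
differences from dominating and is the convention recorded in pipeline
metadata; it is a design choice, as a single published curve per
condition does not disclose which convention produced it.

A frequency-grid subtlety governs what "recovering a 16-h period" can
mean: over 168 h of recording the Fourier periods near 16 h are
168/10 = 16.8 h and 168/11 ≈ 15.27 h. A 16-h component falls exactly
midway between them and its power splits evenly across the two bins, so
no method on this grid can return "16 h" as a unique peak. Tests and
recovery experiments therefore either inject the on-grid neighbour
16.8 h or assert that the two bracketing bins dominate.

# Spatial analysis

Each event is modelled as a 6 × 4 × 4 µm cuboid cell (a typical
meristematic cell) around its centre of mass; the cell "diameter" is the
maximum diagonal √(6²+4²+4²) = √68 ≈ 8.246 µm, printed as 8.24 µm at
two decimals. The DBSCAN radius is three cell diameters; the default
uses the printed rounded chain ε = 3 × 8.24 = 24.72 µm exactly, with the
unrounded variant (3√68 ≈ 24.7386 µm) available via
`epsilon_from_diameter(cell_diameter(6, 4, 4))`. At these scales the
choice is immaterial (0.02 µm on a 24.7-µm radius), but defaulting to
the printed value makes reported ε values reproduce exactly.

`dbscan_labels()` implements standard DBSCAN (Euclidean metric, core
point = ≥ `min_samples` neighbours within ε counting itself) with
deterministic label numbering by first-member input index. The default
`min_samples = 2` makes the algorithm exactly ε-connectivity clustering:
every non-noise point is core, clusters are the connected components of
the ε-neighbourhood graph, and singletons are noise. This is the
weakest — and therefore least assumption-laden — density requirement
consistent with "events within three cell diameters of each other form a
cluster", and it is what the test suite's union-find oracle checks
exactly. A consequence worth remembering downstream: clusters of size 1
cannot exist, so isolated events are excluded from cluster-size
distributions and centres of mass.

Clustering is strictly per frame (and per root): with no persistent
landmark there is no meaningful way to link clusters across frames, and
none is attempted. `summarize_clusters()` reports per-frame cluster
counts, sizes and unweighted member-mean centres;
`cluster_count_size_distribution()` aggregates (cluster count, cluster
size) pairs over frames; `pairwise_centre_distances()` returns all
within-frame centre distances, which the comparison harness pools per
time bin.

# Condition comparisons

`ks_two_sample()` computes the two-sample K-S statistic as the ECDF
supremum evaluated over the pooled sample points — exact under
arbitrary ties, which matters because per-frame counts are small
integers (the result flags tie fractions above 50%). The p-value is the
asymptotic Kolmogorov survival function at `sqrt(n1*n2/(n1+n2)) * D`
(100-term series), matching mainstream defaults; an exact, tie-aware
option (`exact = TRUE`, via the Smirnov distribution) exists for
`n1*n2 ≤ 10000`. Type-I error at α = 0.05 calibrates to the
[0.03, 0.07] band in 2000-replicate null simulations (the asymptotic
p is slightly conservative, ~0.035–0.05 at n = 100 per side).

`run_comparisons()` crosses three metrics (per-frame counts, burst
sizes, pairwise centre distances) with the pooled window and the four
post-excision bins 0–6 h, 6–24 h, 24–72 h, >72 h. Bin intervals are
half-open `[lower, upper)` — the only exclusive reading of overlapping
printed labels like "0–6" and "6–24" — so exactly 6 h falls in the
second bin. Within a condition, values are pooled across roots
(concatenated), the convention recorded in the report's attributes.
Cells with fewer than 3 values per side are marked
`insufficient_data` rather than tested. Raw p-values are reported with
no multiple-testing correction, mirroring common per-comparison
reporting; the report carries the number of comparisons so users can
correct as they wish. Verdict wording: p < 0.001 highly significant,
p < 0.01 significant, p < 0.05 marginally significant.

`gaussian_kde()` provides the smoothed overlays used alongside
histograms: Gaussian kernel, Scott's-rule bandwidth
`sd(x) * n^(-1/5)`, grid spanning the sample range ± 3 bandwidths. It
refuses zero-variance samples (suggesting a histogram) rather than
returning a spike.

# The synthetic generator

`synth_config()` defines one condition's generative model:

| parameter | default | meaning |
|---|---|---|
| `n_frames`, `delta_t_h` | 672, 0.25 h | 7 days at 15-min cadence |
| `lambda_base` | 5 events/frame | noisy baseline (single mode at ~3–5 events) |
| `burst_rate` | 0.01 /frame | probability of a burst episode |
| `burst_size_mean` | 10 events | mean extra events in a burst frame |
| `period_h`, `mod_amplitude` | 0, 0 | optional sinusoidal modulation of the baseline |
| `domain_um` | 120³ µm | meristem-scale box |
| `cluster_sigma_um` | 2 µm | within-cluster Gaussian spread |
| `events_per_cluster_mean` | 3 | Thomas-process offspring mean (clusters of 2–4) |
| `switch_time_h`, `*_post` | off | post-excision regime change (burst parameters) |

Counts at frame t are Poisson with mean
`lambda_base * (1 + mod_amplitude * cos(2π t Δt / period_h))` plus,
with probability `burst_rate`, an independent Poisson(`burst_size_mean`)
increment. Positions per frame follow a Thomas (Neyman–Scott) process:
parents uniform in the box, drawn one at a time with
`max(1, Poisson(events_per_cluster_mean))` offspring until the frame's
event budget is consumed, offspring displaced by isotropic
Gaussian(σ = `cluster_sigma_um`) and clipped to the box. Clipping (not
rejection) keeps event counts exact and introduces negligible bias for
σ ≪ domain. Reproducibility: one global seed expands to per-root
substreams (`seed + root ordinal`), so adding roots never perturbs
earlier ones, and the same seed reproduces the table bit for bit. Ground
truth (burst frames, parent counts, injected periods) is carried in a
`truth` attribute and written to `truth.json` by the pipeline.

`study_configs()` freezes the package's default emulation of the study
design: intact roots carry a 24-h modulation (amplitude 0.3, the
entrained light-cycle rhythm) and rare bursts (rate 0.01, mean size 10);
regenerating roots carry a 16.8-h modulation (amplitude 0.5; the
regeneration-band period placed on the Fourier grid, see above) and
switch at 24 h to burst rate 0.12 with mean size 12. The switched
effect size was fixed by a pre-hoc power sketch: with 4 roots the
24–72 h bin pools 768 frames per side, where the α = 0.01 critical K-S
D is ≈ 0.08, and an 11% excess of high-count frames gives D ≈ 0.11–0.15
— detectable but not trivially so, like the published effect (an excess
of 10–15 events per time-point appearing only after 24 h).

**What the generator does and does not emulate.** It reproduces the
*marginal* temporal structure (baseline + bursts + modulation) and the
*within-frame* spatial structure (small Gaussian clusters), with
temporal and spatial processes independent: no space–time coupling, no
cluster persistence across frames, no root growth or tip drift, no
segmentation noise or missed detections, and a box rather than a
cylindrical root (only relative distances are analysed, so domain shape
only affects edge clipping). Passing recovery tests on these synthetics
therefore validates the *estimators*, not any biological claim about
real roots; conversely real data violating these independences (e.g.
spatially localised bursts) will exercise code paths the generator never
produces.

# Benchmark geometry and problem sizes

Two benchmark-design choices were made a priori from geometry rather
than tuned:

- *Parent recovery.* In the default 120³ µm domain, 50 parents have a
  mean nearest-neighbour spacing of ~18 µm — below ε = 24.72 µm — so
  their ε-graph percolates and no algorithm could recover the parent
  count there (simulation: DBSCAN finds ~15 components of ~50 parents).
  The recovery benchmark therefore places 150 events on ~50 parents in
  a 400³ µm box, where parent spacing far exceeds ε, and compares the
  DBSCAN cluster count to the number of parents with ≥ 2 offspring —
  the population min_samples = 2 can in principle recover (~20% of
  parents draw a single offspring and are by construction noise). The
  measured 100-seed ratio is ≈ 0.98.
- *Period recovery.* 100 seeds at `mod_amplitude = 0.5`,
  `lambda_base = 5`, 672 frames, injected period 16.8 h (on-grid);
  the top periodogram peak matches in 100% of seeds.

Test-suite problem sizes (chosen to exercise the asymptotics the
methods rely on while keeping the suite quick): oracle equivalence on
100 random frames of ≤ 50 points; 1000 tied sample pairs for the K-S
statistic; 2000 null replicates for type-I calibration; 100 seeds for
each recovery and significance-pattern experiment; 30 random series for
Parseval. The whole suite runs in well under a minute.

# Known limitations

- Asymptotic K-S p-values under heavy ties are approximate
  (conservative); the tie flag and the exact option mitigate but do not
  remove this.
- The white-noise peak-significance level assumes a flat spectrum;
  autocorrelated baselines (e.g. slow drifts) inflate low-frequency
  power and can flag spurious long periods. Detrending beyond mean
  removal is the user's responsibility.
- The complete-grid requirement means dropped frames must be
  zero-filled, biasing counts downward in the gaps; a Lomb–Scargle
  variant for gapped series would be the natural extension.
- DBSCAN label determinism is guaranteed, but with `min_samples > 2`
  border points are assigned to the first cluster that reaches them, as
  in every standard DBSCAN.
- The Poisson burst increment is a stand-in: no published burst-size
  law exists to match, and heavier-tailed alternatives would change
  burst-size (not count-baseline) statistics.
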