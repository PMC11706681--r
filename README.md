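# mitodyn

Quantitative analysis of the spatiotemporal dynamics of cell division in
growing and regenerating plant root tips.

Long-term light-sheet imaging of *Arabidopsis* root meristems (a
G2/M-phase cyclin reporter imaged every 15 minutes for up to 7 days)
yields tables of **mitotic events**: one row per detected division with a
root identifier, condition (`intact` or `regenerating`), frame index and
a 3D centre of mass in micrometres. `mitodyn` implements the statistics
used to characterise such data and to compare regenerating roots (tip
excised just above the quiescent centre) with intact ones:

- **Temporal intermittency.** Per-frame event counts `N(t)`; a *burst*
  is a frame with `N(t) ≥ mean(N) + sd(N)` (pooled over the roots of a
  condition), its *size* is `N(t)` itself.
- **Poisson null.** Burst-size distributions are compared to the Poisson
  distribution "peaking at" the observed modal size `m` (rate
  `λ = m + 0.5`, the midpoint of the `[m, m+1)` interval whose mode is
  `m`) via a one-sample Kolmogorov–Smirnov statistic: uncorrelated
  divisions would look Poissonian, correlated ones do not.
- **Periodicity.** A plain FFT periodogram of the mean-removed count
  series (one-sided PSD, Parseval-normalised so `Σ psd·Δf = Var(N)`),
  averaged across the roots of a condition, with peak extraction and a
  Bonferroni-corrected white-noise significance flag.
- **Spatial clustering.** DBSCAN on each frame's 3D positions with a
  geometry-derived radius: events are modelled as 6 × 4 × 4 µm cuboid
  cells of maximum diagonal √68 ≈ 8.24 µm, and `ε = 3 × 8.24 = 24.72 µm`
  (three cell diameters), `min_samples = 2`, so clustering is exactly
  ε-connectivity and singletons are noise. Cluster count/size
  distributions and pairwise centre-of-mass distances follow.
- **Condition comparison.** Two-sample Kolmogorov–Smirnov tests
  (tie-exact ECDF supremum, asymptotic Kolmogorov p-value with effective
  sample size `n₁n₂/(n₁+n₂)`) of every metric, in the pooled window and
  in the post-excision time bins 0–6 h, 6–24 h, 24–72 h and >72 h
  (half-open intervals).
- **Synthetic data.** A generator reproducing the statistical structure
  the analysis assumes — Poisson baseline, burst episodes, optional
  sinusoidal modulation, optional post-switch regime change, and a
  Thomas (Neyman–Scott) spatial process — with full ground-truth
  bookkeeping, so parameter recovery can be asserted without imaging
  data.

## Worked example

```r
library(mitodyn)
cfgs <- study_configs()   # 4+4 roots, 672 frames at 0.25 h
tab <- simulate_table(cfgs$intact, cfgs$regenerating,
                      n_roots_per_condition = 4, seed = 1)
tab
#> <event_table> 30294 events, 8 roots, 672 frames (dt = 0.25 h)
#>   events by condition: intact=13718, regenerating=16576

intact_series <- lapply(unique(tab$root_id[tab$condition == "intact"]),
                        counts_per_frame, table = tab)
thr <- burst_threshold(intact_series)   # 7.85 events (mean + 1 SD, pooled)
detect_bursts(intact_series[[1]], thr)
#> <burst_set> threshold 7.85 events: 118 bursts

top_periods(condition_periodogram(tab, "regenerating"), k = 3)
#>     period_h       psd significant
#> 1 16.8000000 517.40996        TRUE
#> 2  0.5299685  27.63499       FALSE
#> 3  1.0909091  24.99673       FALSE

run_comparisons(tab, metrics = c("events_per_frame", "centre_distances"))
#> <comparison_report> intact vs regenerating, 10 tests (no correction)
#>          bin           metric n_intact n_regen d_stat  p_value            verdict
#> 1        all events_per_frame     2688    2688 0.1004 3.33e-12 highly_significant
#> 2    bin_0_6 events_per_frame       96      96 0.1146 5.54e-01    not_significant
#> 3   bin_6_24 events_per_frame      288     288 0.0451 9.31e-01    not_significant
#> 4  bin_24_72 events_per_frame      768     768 0.1419 3.82e-07 highly_significant
#> 5  bin_gt_72 events_per_frame     1536    1536 0.1042 1.16e-07 highly_significant
#> ...
```

Reading the output: the regenerating condition carries a 16.8-h
periodicity that the periodogram recovers as its single significant
peak; and because the simulated regeneration effect (more frequent,
larger bursts) switches on 24 h after excision, the per-frame count
distributions are indistinguishable in the 0–6 h and 6–24 h bins but
differ strongly afterwards — the late-onset signature of a
regeneration-induced change in division dynamics.

Real event tables enter the same way via `read_events("events.csv",
delta_t_h = 0.25)`; a thin command-line wrapper
(`inst/cli/mitodyn.R`, subcommands `simulate`, `analyse`, `compare`)
drives the same functions from a shell and writes CSV/JSON bundles.

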