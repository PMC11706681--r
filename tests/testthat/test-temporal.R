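test_that("counts_per_frame counts events on the frame grid", {
  tab <- tiny_table()
  s <- counts_per_frame(tab, "r1")
  expect_equal(s$counts, c(2L, 0L, 1L, 0L))
  expect_equal(s$condition, "intact")
  expect_equal(s$delta_t_h, 0.25)
  expect_error(counts_per_frame(tab, "nope"), "unknown root_id")

  # permutation of table rows leaves the series unchanged
  set.seed(1)
  shuf <- event_table(as.data.frame(tab)[sample(nrow(tab)), ],
                      delta_t_h = 0.25, n_frames = 4L)
  expect_equal(counts_per_frame(shuf, "r1")$counts, s$counts)
})

test_that("counts conserve events on simulated tables", {
  cfg <- synth_config(n_frames = 96L, seed = 8L)
  tab <- simulate_table(cfg, cfg, 2L, seed = 8L)
  truth <- attr(tab, "truth")
  for (r in unique(tab$root_id)) {
    s <- counts_per_frame(tab, r)
    expect_equal(sum(s$counts), sum(tab$root_id == r))
    expect_equal(sum(s$counts), truth$roots[[r]]$n_events)
  }
})

test_that("burst threshold is mean + 1 SD of pooled counts", {
  s1 <- frame_series(c(2L, 4L, 6L))
  expect_equal(burst_threshold(s1), 4 + 2)  # mean 4, sample SD 2
  expect_equal(burst_threshold(frame_series(rep(5L, 10))), 5)  # SD 0

  # pooling convention: a group threshold uses the concatenated counts
  s2 <- frame_series(c(1L, 3L))
  pooled <- c(2, 4, 6, 1, 3)
  expect_equal(burst_threshold(list(s1, s2)),
               mean(pooled) + sd(pooled))

  # location consistency: shifting all counts by +c shifts threshold by +c
  shift <- frame_series(c(2L, 4L, 6L) + 7L)
  expect_equal(burst_threshold(shift), burst_threshold(s1) + 7)

  expect_equal(burst_threshold(s1, sd_type = "population"),
               4 + 2 * sqrt(2 / 3))
  expect_error(burst_threshold(list()), "empty")
})

test_that("detect_bursts flags frames at or above the threshold", {
  s <- frame_series(c(3L, 3L, 30L, 3L))
  b <- detect_bursts(s, 16.1)
  expect_equal(b$bursts$frame_index, 2L)
  expect_equal(b$bursts$size, 30L)
  expect_equal(b$bursts$time_h, 0.5)

  # vacuous threshold: every nonzero frame is a burst
  s0 <- frame_series(c(0L, 2L, 0L, 5L))
  b0 <- detect_bursts(s0, 0)
  expect_equal(b0$bursts$frame_index, c(1L, 3L))
  expect_equal(b0$bursts$size, c(2L, 5L))

  # inclusive comparison: a count exactly at threshold is a burst
  expect_equal(detect_bursts(frame_series(c(1L, 6L)), 6)$bursts$size, 6L)
  expect_equal(nrow(detect_bursts(s, 100)$bursts), 0L)
})

test_that("mode-matched Poisson has the requested mode", {
  for (m in c(0L, 11L, 13L)) {
    null <- mode_matched_poisson(m)
    expect_equal(null$lambda, m + 0.5)
    expect_equal(which.max(null$pmf(0:50)) - 1L, m)
  }
  expect_equal(sum(mode_matched_poisson(11L)$pmf(0:200)), 1, tolerance = 1e-12)
  expect_error(mode_matched_poisson(-1L), "mode")
})

test_that("compare_to_poisson separates matched and mismatched samples", {
  # self-consistency: a genuine Poisson(11.5) sample scores a tiny D
  set.seed(123)
  sample_ok <- rpois(10000, 11.5)
  cmp <- compare_to_poisson(sample_ok, mode_matched_poisson(11L))
  expect_lt(cmp$d_stat, 0.02)

  # closed-form oracle: constant sample at the mode
  cmp11 <- compare_to_poisson(rep(11L, 50), mode_matched_poisson(11L))
  d_oracle <- max(ppois(0:10, 11.5), 1 - ppois(11, 11.5))
  expect_equal(cmp11$d_stat, d_oracle, tolerance = 1e-12)

  # hand-constructed separation: bimodal mix vs mode-matched Poisson
  bim <- c(rep(3L, 60), rep(30L, 40))
  expect_gt(compare_to_poisson(bim, mode_matched_poisson(11L))$d_stat, 0.3)

  expect_error(compare_to_poisson(integer(0), mode_matched_poisson(1L)),
               "empty")
  # overlay frequencies sum to 1 and pair empirical with pmf
  expect_equal(sum(cmp11$overlay$empirical), 1)
  expect_equal(cmp11$overlay$pmf, dpois(0:11, 11.5))
})

test_that("periodogram matches the closed-form DFT of a sinusoid", {
  n <- 672L; dt <- 0.25
  t_h <- (0:(n - 1)) * dt

  # constant series: zero power everywhere after mean removal
  expect_true(all(periodogram(frame_series(rep(4L, n)))$psd == 0))
  expect_error(periodogram(frame_series(c(1L, 2L, 3L))), "at least 4")

  # on-grid cosine, period 16.8 h = 10 cycles in 168 h: unique top peak
  # with the closed-form peak power A^2 * n * dt / 2
  amp <- 3
  x <- amp * cos(2 * pi * t_h / 16.8)
  pg <- periodogram(x, delta_t_h = dt)
  expect_equal(pg$peaks$period_h[1], 16.8, tolerance = 1e-12)
  expect_equal(max(pg$psd), amp^2 * n * dt / 2, tolerance = 1e-9)
  expect_gt(pg$peaks$psd[1], 1e6 * max(pg$psd[abs(pg$period_h - 16.8) > 1]))

  # off-grid 16-h cosine (10.5 cycles): power splits evenly between the
  # two adjacent bracketing Fourier bins, which dominate everything else
  # (being adjacent, only one of them can be a *local maximum*)
  x16 <- amp * cos(2 * pi * t_h / 16)
  pg16 <- periodogram(x16, delta_t_h = dt)
  top2 <- sort(pg16$period_h[order(-pg16$psd)[1:2]])
  expect_equal(top2, sort(c(168 / 11, 168 / 10)), tolerance = 1e-9)
  expect_gt(sum(sort(pg16$psd, decreasing = TRUE)[1:2]), 0.8 * sum(pg16$psd))
  expect_true(pg16$peaks$period_h[1] %in% top2)
})

test_that("periodogram satisfies the Parseval identity", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(10:500, 1)
    x <- rpois(n, sample(1:20, 1)) + rnorm(n)
    dt <- runif(1, 0.05, 2)
    pg <- periodogram(x, delta_t_h = dt)
    v <- mean((x - mean(x))^2)
    expect_equal(sum(pg$psd) * pg$df, v, tolerance = 1e-8)
  }
})

test_that("top_periods recovers injected periodicities and flags noise", {
  n <- 672L; dt <- 0.25
  t_h <- (0:(n - 1)) * dt
  set.seed(55)

  # single sinusoid + noise: one dominant significant peak
  x <- 5 * cos(2 * pi * t_h / 16.8) + rnorm(n)
  tp <- top_periods(periodogram(x, delta_t_h = dt), k = 1)
  expect_equal(tp$period_h, 16.8, tolerance = 1e-9)
  expect_true(tp$significant)

  # two sinusoids (16.8 h strong, 11.2 h weak) + noise: both in the top 2
  hit <- vapply(1:30, function(i) {
    y <- 5 * cos(2 * pi * t_h / 16.8) + 2.5 * sin(2 * pi * t_h / 11.2) +
      rnorm(n)
    tp2 <- top_periods(periodogram(y, delta_t_h = dt), k = 2)
    setequal(round(tp2$period_h, 6), round(c(16.8, 11.2), 6))
  }, logical(1))
  expect_gte(mean(hit), 0.95)

  # white noise: k periods returned, none clearing the Bonferroni level
  flagged <- vapply(1:30, function(i) {
    tpn <- top_periods(periodogram(rnorm(n), delta_t_h = dt), k = 3)
    sum(tpn$significant)
  }, numeric(1))
  expect_equal(nrow(top_periods(periodogram(rnorm(n), dt), k = 3)), 3L)
  expect_lte(mean(flagged > 0), 0.1)
})

test_that("condition periodogram averages per-root spectra", {
  cfg <- synth_config(n_frames = 672L, lambda_base = 5, burst_rate = 0,
                      period_h = 16.8, mod_amplitude = 0.8)
  tab <- simulate_table(cfg, cfg, 3L, seed = 12L, positions = FALSE)
  pg <- condition_periodogram(tab, "intact")
  roots <- unique(tab$root_id[tab$condition == "intact"])
  manual <- rowMeans(vapply(roots, function(r) {
    periodogram(counts_per_frame(tab, r))$psd
  }, numeric(336)))
  expect_equal(pg$psd, manual)
  expect_equal(pg$peaks$period_h[1], 16.8, tolerance = 1e-9)
  expect_error(condition_periodogram(tab, "regenerating2"), "no roots")
})
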