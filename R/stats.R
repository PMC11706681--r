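# Kolmogorov survival function Q(lambda) = 2 * sum_{j>=1} (-1)^(j-1) exp(-2 j^2 lambda^2),
# truncated at `terms`; the limiting null distribution of sqrt(n) * D.
kolmogorov_sf <- function(lambda, terms = 100L) {
  if (lambda <= 0) return(1)
  j <- seq_len(terms)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(1, max(0, p))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic is the supremum of the absolute difference of the two
#' empirical CDFs. Both ECDFs are step functions that jump only at sample
#' values, so the supremum is attained at a point of the pooled sample and
#' is evaluated there — exact under arbitrary ties. The two-sided p-value
#' comes from the asymptotic Kolmogorov distribution with effective sample
#' size `n1 * n2 / (n1 + n2)`; an exact p-value (conditional on the tie
#' pattern) is available for small samples.
#'
#' Count data are heavily tied; the asymptotic p-value is then
#' approximate (conservative), and the result flags a pooled tie fraction
#' above 50%.
#'
#' @param a,b non-empty numeric samples.
#' @param exact compute the exact (tie-aware) p-value via
#'   [stats::psmirnov()]; only allowed for `n1 * n2 <= 10000`.
#' @return a `ks_result`: list with `d_stat`, `p_value`, `n1`, `n2`,
#'   `tie_fraction`, `ties_flagged`, `method`.
#' @export
ks_two_sample <- function(a, b, exact = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("samples must not contain missing values")
  n1 <- length(a); n2 <- length(b)
  grid <- sort(unique(c(a, b)))
  fa <- vapply(grid, function(x) sum(a <= x), numeric(1)) / n1
  fb <- vapply(grid, function(x) sum(b <= x), numeric(1)) / n2
  d <- max(abs(fa - fb))
  pooled <- c(a, b)
  tie_fraction <- 1 - length(grid) / length(pooled)
  if (exact) {
    if (n1 * n2 > 10000) stop("exact p-value limited to n1 * n2 <= 10000")
    p <- stats::psmirnov(d, sizes = c(n1, n2), z = pooled,
                         two.sided = TRUE, lower.tail = FALSE)
    method <- "exact"
  } else {
    ne <- n1 * n2 / (n1 + n2)
    p <- kolmogorov_sf(sqrt(ne) * d)
    method <- "asymptotic"
  }
  structure(list(d_stat = d, p_value = p, n1 = n1, n2 = n2,
                 tie_fraction = tie_fraction,
                 ties_flagged = tie_fraction > 0.5, method = method),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("two-sample K-S: D = %.4f, p = %.4g (%s), n1 = %d, n2 = %d%s\n",
              x$d_stat, x$p_value, x$method, x$n1, x$n2,
              if (x$ties_flagged) sprintf(" [tie fraction %.0f%%]",
                                          100 * x$tie_fraction) else ""))
  invisible(x)
}

#' Gaussian kernel density estimate with Scott's-rule bandwidth
#'
#' Smoothed distribution estimate used for reporting alongside
#' histograms. The default bandwidth is Scott's rule for one dimension,
#' `sd(sample) * n^(-1/5)`; the evaluation grid spans the sample range
#' extended by three bandwidths on each side.
#'
#' @param sample numeric sample of size >= 2 with nonzero variance.
#' @param bandwidth `"scott"` (default), `"silverman"`, or a positive
#'   number.
#' @param n_grid number of grid points.
#' @return list with `x` (grid), `y` (density values, >= 0), `bw`.
#' @export
gaussian_kde <- function(sample, bandwidth = "scott", n_grid = 512L) {
  sample <- as.numeric(sample)
  if (length(sample) < 2L) stop("kernel density estimation needs >= 2 points")
  s <- stats::sd(sample)
  if (s == 0) {
    stop("zero-variance sample: density estimate is degenerate; ",
         "use a histogram instead")
  }
  bw <- if (is.numeric(bandwidth)) {
    if (bandwidth <= 0) stop("bandwidth must be > 0")
    bandwidth
  } else {
    switch(match.arg(bandwidth, c("scott", "silverman")),
           scott = s * length(sample)^(-1 / 5),
           silverman = stats::bw.nrd0(sample))
  }
  est <- stats::density(sample, bw = bw, kernel = "gaussian",
                        from = min(sample) - 3 * bw,
                        to = max(sample) + 3 * bw, n = n_grid)
  list(x = est$x, y = est$y, bw = bw)
}

#' Condition comparison across time bins and metrics
#'
#' Runs two-sample K-S comparisons of intact vs regenerating roots for
#' each requested metric in the pooled "all" window and in each
#' post-excision time bin:
#' \describe{
#'   \item{events_per_frame}{per-frame event counts, frames pooled across
#'     the roots of a condition, a frame binned by its time.}
#'   \item{burst_sizes}{burst sizes from [detect_bursts()] against the
#'     per-condition pooled [burst_threshold()], binned by burst time.}
#'   \item{centre_distances}{pairwise cluster centre-of-mass distances
#'     from per-frame DBSCAN clustering, pooled within each bin.}
#' }
#' Cells with fewer than `min_n` values on either side are reported as
#' insufficient data rather than tested. Raw per-comparison p-values are
#' reported (no multiple-testing correction); the verdict wording is
#' p < 0.001 highly significant, p < 0.01 significant, p < 0.05
#' marginally significant.
#'
#' @param table an [event_table()] containing both conditions.
#' @param params a [cluster_params()] for the spatial metric.
#' @param metrics subset of
#'   `c("events_per_frame", "burst_sizes", "centre_distances")`.
#' @param min_n minimum sample size per side for a test (default 3).
#' @param sd_type passed to [burst_threshold()].
#' @return a `comparison_report`: data frame with `bin`, `metric`,
#'   `n_intact`, `n_regen`, `d_stat`, `p_value`, `verdict`; attribute
#'   `conventions` records pooling and threshold choices.
#' @export
run_comparisons <- function(table, params = cluster_params(),
                            metrics = c("events_per_frame", "burst_sizes",
                                        "centre_distances"),
                            min_n = 3L, sd_type = "sample") {
  stopifnot(inherits(table, "event_table"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  conds <- c("intact", "regenerating")
  present <- conds %in% unique(table$condition)
  if (!all(present)) {
    stop("both conditions must be present; missing: ",
         paste(conds[!present], collapse = ", "))
  }
  bins <- c("all", time_bin_levels())
  frame_bin <- bin_of_time((seq_len(n_frames(table)) - 1L) * delta_t(table))

  # per-condition building blocks
  samples <- list()
  thresholds <- c(intact = NA_real_, regenerating = NA_real_)
  for (cond in conds) {
    roots <- unique(table$root_id[table$condition == cond])
    series <- lapply(roots, function(r) counts_per_frame(table, r))
    if ("events_per_frame" %in% metrics) {
      counts <- unlist(lapply(series, `[[`, "counts"), use.names = FALSE)
      cbin <- rep(as.character(frame_bin), length(series))
      for (b in bins) {
        sel <- if (b == "all") TRUE else cbin == b
        samples[[paste(cond, "events_per_frame", b)]] <- counts[sel]
      }
    }
    if ("burst_sizes" %in% metrics) {
      thr <- burst_threshold(series, sd_type = sd_type)
      thresholds[cond] <- thr
      bs <- do.call(rbind, lapply(series, function(s) detect_bursts(s, thr)$bursts))
      bbin <- as.character(bin_of_time(bs$time_h))
      for (b in bins) {
        sel <- if (b == "all") TRUE else bbin == b
        samples[[paste(cond, "burst_sizes", b)]] <- bs$size[sel]
      }
    }
    if ("centre_distances" %in% metrics) {
      sums <- summarize_frames(table, params, condition = cond)
      dists <- lapply(sums, pairwise_centre_distances)
      dbin <- rep(as.character(bin_of_time(
        vapply(sums, `[[`, numeric(1), "time_h"))),
        lengths(dists))
      dists <- unlist(dists, use.names = FALSE)
      if (is.null(dists)) dists <- numeric(0)
      for (b in bins) {
        sel <- if (b == "all") TRUE else dbin == b
        samples[[paste(cond, "centre_distances", b)]] <- dists[sel]
      }
    }
  }

  rows <- list()
  for (metric in metrics) {
    for (b in bins) {
      sa <- samples[[paste("intact", metric, b)]]
      sb <- samples[[paste("regenerating", metric, b)]]
      if (length(sa) < min_n || length(sb) < min_n) {
        rows[[paste(metric, b)]] <- data.frame(
          bin = b, metric = metric, n_intact = length(sa),
          n_regen = length(sb), d_stat = NA_real_, p_value = NA_real_,
          verdict = "insufficient_data", stringsAsFactors = FALSE)
        next
      }
      ks <- ks_two_sample(sa, sb)
      rows[[paste(metric, b)]] <- data.frame(
        bin = b, metric = metric, n_intact = ks$n1, n_regen = ks$n2,
        d_stat = ks$d_stat, p_value = ks$p_value,
        verdict = significance_verdict(ks$p_value), stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(report,
            conventions = list(
              pooling = "per-frame values pooled across roots within condition",
              burst_threshold = thresholds, sd_type = sd_type,
              epsilon_um = params$epsilon_um,
              min_samples = params$min_samples,
              n_comparisons = sum(!is.na(report$p_value)),
              correction = "none (raw per-comparison p-values)"),
            class = c("comparison_report", "data.frame"))
}

significance_verdict <- function(p) {
  if (p < 0.001) "highly_significant"
  else if (p < 0.01) "significant"
  else if (p < 0.05) "marginally_significant"
  else "not_significant"
}

#' @export
print.comparison_report <- function(x, ...) {
  conv <- attr(x, "conventions")
  cat("<comparison_report> intact vs regenerating,",
      conv$n_comparisons, "tests (no correction)\n")
  df <- as.data.frame(x)
  df$d_stat <- round(df$d_stat, 4)
  df$p_value <- signif(df$p_value, 3)
  print(df)
  invisible(x)
}
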