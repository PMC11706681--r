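#' Per-frame event counts for one root
#'
#' @param table an [event_table()].
#' @param root_id root identifier present in `table`.
#' @return a `frame_series`: list with `root_id`, `condition`, integer
#'   `counts` (length `n_frames(table)`, zeros where the root had no
#'   events) and `delta_t_h`.
#' @export
counts_per_frame <- function(table, root_id) {
  stopifnot(inherits(table, "event_table"))
  rows <- table$root_id == root_id
  if (!any(rows)) stop("unknown root_id: ", root_id)
  nf <- n_frames(table)
  counts <- tabulate(table$frame_index[rows] + 1L, nbins = nf)
  frame_series(counts, delta_t_h = delta_t(table), root_id = root_id,
               condition = unique(table$condition[rows])[1L])
}

#' Construct a per-frame count series
#'
#' @param counts non-negative integer vector, one entry per frame.
#' @param delta_t_h hours per frame.
#' @param root_id,condition optional labels carried along.
#' @return a `frame_series` object.
#' @export
frame_series <- function(counts, delta_t_h = 0.25, root_id = NA_character_,
                         condition = NA_character_) {
  counts <- as.integer(counts)
  if (length(counts) < 1L) stop("a frame series needs at least one frame")
  if (any(counts < 0L)) stop("counts must be non-negative")
  if (delta_t_h <= 0) stop("delta_t_h must be > 0")
  structure(list(root_id = root_id, condition = condition, counts = counts,
                 delta_t_h = delta_t_h),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series> root %s (%s): %d frames, %d events, dt = %g h\n",
              x$root_id, x$condition, length(x$counts), sum(x$counts),
              x$delta_t_h))
  invisible(x)
}

#' Burst-detection threshold: mean + 1 SD of pooled per-frame counts
#'
#' A burst is a time-point whose event count is at least one standard
#' deviation above the mean of the whole temporal series. When several
#' series (e.g. the roots of one condition) are given, their per-frame
#' counts are pooled before computing mean and SD, yielding one threshold
#' per condition.
#'
#' @param series_group a `frame_series` or a list of them.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return threshold in events (mean + 1 SD of the pooled counts).
#' @export
burst_threshold <- function(series_group, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (inherits(series_group, "frame_series")) series_group <- list(series_group)
  if (length(series_group) == 0L) stop("empty series group")
  pooled <- unlist(lapply(series_group, function(s) {
    stopifnot(inherits(s, "frame_series"))
    s$counts
  }), use.names = FALSE)
  if (length(pooled) == 0L) stop("no frames in series group")
  m <- mean(pooled)
  s <- if (length(pooled) == 1L) 0 else stats::sd(pooled)
  if (sd_type == "population") {
    n <- length(pooled)
    s <- s * sqrt((n - 1) / n)
  }
  m + s
}

#' Detect bursts in a per-frame count series
#'
#' Bursts are the frames whose (nonzero) count reaches the threshold; the
#' size of a burst is simply that frame's event count.
#'
#' @param series a [frame_series()].
#' @param threshold events; typically from [burst_threshold()].
#' @return a `burst_set`: list with `threshold`, and data frame `bursts`
#'   (`frame_index`, `size`, `time_h`) sorted by frame.
#' @export
detect_bursts <- function(series, threshold) {
  stopifnot(inherits(series, "frame_series"), is.finite(threshold))
  hit <- which(series$counts >= threshold & series$counts > 0L)
  bursts <- data.frame(frame_index = hit - 1L,
                       size = series$counts[hit],
                       time_h = (hit - 1L) * series$delta_t_h)
  structure(list(threshold = threshold, root_id = series$root_id,
                 condition = series$condition, bursts = bursts),
            class = "burst_set")
}

#' @export
print.burst_set <- function(x, ...) {
  cat(sprintf("<burst_set> threshold %.2f events: %d bursts\n",
              x$threshold, nrow(x$bursts)))
  if (nrow(x$bursts) > 0L) print(utils::head(x$bursts, 10L))
  invisible(x)
}

#' Poisson null matched to an observed mode
#'
#' A Poisson distribution "peaking at" `m` is any Poisson with rate in
#' `[m, m + 1)`; the midpoint `m + 0.5` is used so the match does not sit
#' on the boundary where the mode is shared between two values.
#'
#' @param mode non-negative integer, the observed peak (e.g. the modal
#'   burst size).
#' @param offset rate offset within `[0, 1)`; default 0.5.
#' @return a `poisson_null`: list with `lambda`, `mode`, and functions
#'   `pmf(k)` and `cdf(k)`.
#' @export
mode_matched_poisson <- function(mode, offset = 0.5) {
  if (length(mode) != 1L || mode < 0 || mode != floor(mode)) {
    stop("mode must be a single non-negative integer")
  }
  if (offset < 0 || offset >= 1) stop("offset must be in [0, 1)")
  lambda <- mode + offset
  structure(list(lambda = lambda, mode = as.integer(mode),
                 pmf = function(k) stats::dpois(k, lambda),
                 cdf = function(k) stats::ppois(k, lambda)),
            class = "poisson_null")
}

#' Compare a discrete sample to a Poisson null (one-sample K-S)
#'
#' Computes the Kolmogorov-Smirnov statistic between the sample's ECDF and
#' the Poisson CDF, evaluated over the integer support (both functions
#' only jump at integers, so the supremum is attained there), plus the
#' binned empirical frequencies and Poisson pmf for overlay plotting. The
#' p-value uses the asymptotic Kolmogorov distribution and is conservative
#' for a discrete null.
#'
#' @param burst_sizes non-empty vector of non-negative integers (e.g.
#'   burst sizes).
#' @param null a [mode_matched_poisson()].
#' @return list with `d_stat`, `p_value`, `n`, `lambda`, and data frame
#'   `overlay` (`k`, `empirical`, `pmf`).
#' @export
compare_to_poisson <- function(burst_sizes, null) {
  stopifnot(inherits(null, "poisson_null"))
  if (length(burst_sizes) == 0L) stop("empty sample")
  if (any(burst_sizes < 0 | burst_sizes != floor(burst_sizes))) {
    stop("sample must contain non-negative integers")
  }
  n <- length(burst_sizes)
  kmax <- max(burst_sizes)
  k <- 0:kmax
  ecdf_k <- vapply(k, function(v) mean(burst_sizes <= v), numeric(1))
  d <- max(abs(ecdf_k - null$cdf(k)))
  p <- kolmogorov_sf(sqrt(n) * d)
  overlay <- data.frame(k = k,
                        empirical = tabulate(burst_sizes + 1L, kmax + 1L) / n,
                        pmf = null$pmf(k))
  list(d_stat = d, p_value = p, n = n, lambda = null$lambda, overlay = overlay)
}

#' Periodogram (power spectral density) of a count series
#'
#' Plain FFT periodogram of the mean-removed series on the native Fourier
#' frequency grid, one-sided, scaled so that `sum(psd) * df` equals the
#' (population) variance of the mean-removed series — the discrete
#' Parseval identity. Periods are reported in hours. Peaks are the local
#' maxima of the PSD (DC excluded by construction), sorted by descending
#' power.
#'
#' @param series a [frame_series()] with at least 4 frames, or a numeric
#'   vector (then `delta_t_h` is taken from the `delta_t_h` argument).
#' @param delta_t_h sampling interval in hours, used when `series` is a
#'   bare numeric vector.
#' @return a `periodogram_result`: list with `period_h`, `freq_per_h`,
#'   `psd` (all ordered by increasing frequency, i.e. decreasing period),
#'   `df` (frequency-bin width), and data frame `peaks` (`period_h`,
#'   `psd`).
#' @export
periodogram <- function(series, delta_t_h = 0.25) {
  if (inherits(series, "frame_series")) {
    x <- as.numeric(series$counts)
    delta_t_h <- series$delta_t_h
  } else {
    x <- as.numeric(series)
  }
  n <- length(x)
  if (n < 4L) stop("periodogram needs at least 4 frames")
  x <- x - mean(x)
  X <- stats::fft(x)
  m <- n %/% 2L
  k <- seq_len(m)
  scale <- rep(2, m)
  if (n %% 2L == 0L) scale[m] <- 1  # Nyquist bin is not mirrored
  psd <- scale * (delta_t_h / n) * Mod(X[k + 1L])^2
  freq <- k / (n * delta_t_h)
  period <- 1 / freq
  peaks_idx <- local_maxima(psd)
  peaks <- data.frame(period_h = period[peaks_idx], psd = psd[peaks_idx])
  peaks <- peaks[order(-peaks$psd), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(period_h = period, freq_per_h = freq, psd = psd,
                 df = 1 / (n * delta_t_h), delta_t_h = delta_t_h,
                 peaks = peaks),
            class = "periodogram_result")
}

# indices of strict-left / weak-right local maxima; boundary bins count
# when they exceed their single neighbour
local_maxima <- function(v) {
  n <- length(v)
  if (n == 1L) return(1L)
  left <- c(TRUE, v[-1L] > v[-n])
  right <- c(v[-n] >= v[-1L], TRUE)
  which(left & right & v > 0)
}

#' @export
print.periodogram_result <- function(x, ...) {
  cat(sprintf("<periodogram> %d frequency bins, df = %.5g / h\n",
              length(x$psd), x$df))
  cat("top peaks:\n")
  print(utils::head(x$peaks, 5L))
  invisible(x)
}

#' Strongest periodicities of a periodogram
#'
#' Returns the `k` highest-power peak periods (fewer when fewer local
#' maxima exist). Each is flagged against a Bonferroni-corrected
#' white-noise level: under Gaussian white noise the PSD ordinates are
#' approximately exponential with mean equal to the average PSD, so a peak
#' is deemed significant when its power exceeds
#' `mean(psd) * log(m / alpha)` for `m` frequency bins.
#'
#' @param pg a [periodogram()] result.
#' @param k number of peaks to report (>= 1).
#' @param alpha family-wise significance level for the white-noise flag.
#' @return data frame with `period_h`, `psd`, `significant`.
#' @export
top_periods <- function(pg, k = 3L, alpha = 0.05) {
  stopifnot(inherits(pg, "periodogram_result"), k >= 1L)
  out <- utils::head(pg$peaks, k)
  m <- length(pg$psd)
  level <- mean(pg$psd) * log(m / alpha)
  out$significant <- out$psd > level
  out
}

#' Average periodograms across the roots of a condition
#'
#' Computes one periodogram per root and averages the PSDs bin-wise
#' (all roots share the frame grid, hence the frequency grid).
#'
#' @param table an [event_table()].
#' @param condition `"intact"` or `"regenerating"`.
#' @return a `periodogram_result` whose `psd` is the across-root mean.
#' @export
condition_periodogram <- function(table, condition) {
  stopifnot(inherits(table, "event_table"))
  roots <- unique(table$root_id[table$condition == condition])
  if (length(roots) == 0L) stop("no roots with condition: ", condition)
  pgs <- lapply(roots, function(r) periodogram(counts_per_frame(table, r)))
  avg <- pgs[[1L]]
  if (length(pgs) > 1L) {
    avg$psd <- rowMeans(vapply(pgs, function(p) p$psd,
                               numeric(length(avg$psd))))
  }
  peaks_idx <- local_maxima(avg$psd)
  peaks <- data.frame(period_h = avg$period_h[peaks_idx],
                      psd = avg$psd[peaks_idx])
  peaks <- peaks[order(-peaks$psd), , drop = FALSE]
  rownames(peaks) <- NULL
  avg$peaks <- peaks
  avg
}
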