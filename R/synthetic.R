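#' Configuration for the synthetic mitotic-event generator
#'
#' Defines one condition's generative model. Temporally, per-frame event
#' counts are Poisson with mean
#' `lambda_base * (1 + mod_amplitude * cos(2*pi*t*delta_t_h/period_h))`,
#' and each frame independently receives, with probability `burst_rate`, an
#' extra `Poisson(burst_size_mean)` burst increment — a noisy baseline
#' punctuated by isolated bursts. Spatially, the events of a frame follow a
#' Thomas (Neyman-Scott) process: parent centres uniform in a box, offspring
#' displaced isotropically by a Gaussian of scale `cluster_sigma_um`.
#'
#' A regeneration-style regime change can be injected with
#' `switch_time_h`: from that time on, `burst_rate_post` and
#' `burst_size_mean_post` replace the baseline burst parameters.
#'
#' Defaults emulate the root-imaging study design: 672 frames at 15-minute
#' cadence (7 days), a baseline of ~5 events per frame, rare bursts of ~10
#' extra events, and spatial clusters of 2-4 events (mean 3 offspring per
#' parent, 2 um within-cluster spread) in a meristem-scale 120 um box.
#'
#' @param n_frames number of frames.
#' @param delta_t_h hours per frame.
#' @param lambda_base expected baseline events per frame (>= 0).
#' @param burst_rate per-frame probability of a burst episode, in `[0, 1]`.
#' @param burst_size_mean expected extra events in a burst frame.
#' @param period_h period in hours of sinusoidal modulation (0 = none).
#' @param mod_amplitude fractional modulation amplitude in `[0, 1]`.
#' @param domain_um length-3 box extents in micrometres.
#' @param cluster_sigma_um within-cluster isotropic Gaussian SD (> 0).
#' @param events_per_cluster_mean expected offspring per spatial parent.
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @param switch_time_h hours after which the post-switch burst parameters
#'   apply (`NA` = no switch).
#' @param burst_rate_post,burst_size_mean_post burst parameters after
#'   `switch_time_h`; default to the pre-switch values.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_frames = 672L, delta_t_h = 0.25, lambda_base = 5,
                         burst_rate = 0.01, burst_size_mean = 10,
                         period_h = 0, mod_amplitude = 0,
                         domain_um = c(120, 120, 120),
                         cluster_sigma_um = 2, events_per_cluster_mean = 3,
                         seed = NULL, switch_time_h = NA_real_,
                         burst_rate_post = burst_rate,
                         burst_size_mean_post = burst_size_mean) {
  cfg <- list(n_frames = as.integer(n_frames), delta_t_h = delta_t_h,
              lambda_base = lambda_base, burst_rate = burst_rate,
              burst_size_mean = burst_size_mean, period_h = period_h,
              mod_amplitude = mod_amplitude, domain_um = as.numeric(domain_um),
              cluster_sigma_um = cluster_sigma_um,
              events_per_cluster_mean = events_per_cluster_mean,
              seed = if (is.null(seed)) NULL else as.integer(seed),
              switch_time_h = switch_time_h,
              burst_rate_post = burst_rate_post,
              burst_size_mean_post = burst_size_mean_post)
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_frames < 1L) stop("n_frames must be >= 1")
  if (cfg$delta_t_h <= 0) stop("delta_t_h must be > 0")
  if (cfg$lambda_base < 0) stop("lambda_base must be >= 0")
  if (cfg$burst_rate < 0 || cfg$burst_rate > 1) stop("burst_rate must be in [0, 1]")
  if (cfg$mod_amplitude < 0 || cfg$mod_amplitude > 1) {
    stop("mod_amplitude must be in [0, 1]")
  }
  if (cfg$mod_amplitude > 0 && cfg$period_h <= 0) {
    stop("period_h must be > 0 when mod_amplitude > 0")
  }
  if (length(cfg$domain_um) != 3L || any(cfg$domain_um <= 0)) {
    stop("domain_um must be three positive box extents")
  }
  if (cfg$cluster_sigma_um <= 0) stop("cluster_sigma_um must be > 0")
  if (cfg$events_per_cluster_mean <= 0) stop("events_per_cluster_mean must be > 0")
  invisible(cfg)
}

#' Simulate a per-frame event-count series
#'
#' @param config a [synth_config()].
#' @param seed overrides `config$seed`; `NULL` with a `NULL` config seed
#'   draws from the current RNG state (used internally for substreams).
#' @return integer vector of counts, one per frame, with attributes
#'   `burst_frames` (0-based frames that received a burst increment) and
#'   `lambda` (the deterministic modulated baseline mean per frame).
#' @export
simulate_counts <- function(config, seed = config$seed) {
  validate_synth_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_frames
  t_h <- (seq_len(n) - 1L) * config$delta_t_h
  lambda <- if (config$mod_amplitude > 0) {
    config$lambda_base *
      (1 + config$mod_amplitude * cos(2 * pi * t_h / config$period_h))
  } else {
    rep(config$lambda_base, n)
  }
  counts <- stats::rpois(n, lambda)

  post <- if (is.na(config$switch_time_h)) rep(FALSE, n) else t_h >= config$switch_time_h
  rate <- ifelse(post, config$burst_rate_post, config$burst_rate)
  size_mean <- ifelse(post, config$burst_size_mean_post, config$burst_size_mean)
  is_burst <- stats::runif(n) < rate
  if (any(is_burst)) {
    counts[is_burst] <- counts[is_burst] +
      stats::rpois(sum(is_burst), size_mean[is_burst])
  }
  structure(as.integer(counts),
            burst_frames = which(is_burst) - 1L, lambda = lambda)
}

#' Simulate clustered 3D event positions (Thomas process)
#'
#' Parent centres are drawn uniformly in the domain box; parents are drawn
#' one at a time, each granted `max(1, Poisson(events_per_cluster_mean))`
#' offspring, until the budget of `n_events` is consumed (the last parent
#' may receive fewer). Each event sits at its parent plus an isotropic
#' Gaussian displacement of SD `cluster_sigma_um`, clipped to the box.
#'
#' @param n_events number of events to place (>= 0).
#' @inheritParams simulate_counts
#' @return `n_events` x 3 matrix of positions (um), with attributes
#'   `parent` (1-based parent index per event) and `parents` (matrix of
#'   parent centres actually used) for recovery experiments.
#' @export
simulate_positions <- function(n_events, config, seed = config$seed) {
  validate_synth_config(config)
  if (length(n_events) != 1L || n_events < 0 || n_events != floor(n_events)) {
    stop("n_events must be a single non-negative integer")
  }
  if (!is.null(seed)) set.seed(seed)
  n_events <- as.integer(n_events)
  box <- config$domain_um
  if (n_events == 0L) {
    out <- matrix(numeric(0), 0L, 3L,
                  dimnames = list(NULL, c("x_um", "y_um", "z_um")))
    return(structure(out, parent = integer(0),
                     parents = matrix(numeric(0), 0L, 3L)))
  }
  parents <- matrix(NA_real_, 0L, 3L)
  parent_of <- integer(0)
  remaining <- n_events
  while (remaining > 0L) {
    centre <- stats::runif(3) * box
    parents <- rbind(parents, centre)
    k <- min(remaining, max(1L, stats::rpois(1L, config$events_per_cluster_mean)))
    parent_of <- c(parent_of, rep.int(nrow(parents), k))
    remaining <- remaining - k
  }
  disp <- matrix(stats::rnorm(3L * n_events, sd = config$cluster_sigma_um),
                 ncol = 3L)
  pos <- parents[parent_of, , drop = FALSE] + disp
  pos <- pmin(pmax(pos, 0), matrix(box, n_events, 3L, byrow = TRUE))
  dimnames(pos) <- list(NULL, c("x_um", "y_um", "z_um"))
  dimnames(parents) <- list(NULL, c("x_um", "y_um", "z_um"))
  structure(pos, parent = parent_of, parents = parents)
}

#' Simulate a two-condition mitotic-event table
#'
#' Generates `n_roots_per_condition` intact and regenerating roots. Each
#' root gets its own deterministic RNG substream (`seed + root ordinal`,
#' intact roots first), so adding roots does not perturb earlier ones.
#' Counts come from [simulate_counts()]; each frame's positions from an
#' independent [simulate_positions()] draw.
#'
#' @param config_intact,config_regen [synth_config()] for each condition
#'   (they must share `n_frames` and `delta_t_h`).
#' @param n_roots_per_condition number of roots per condition (>= 1).
#' @param seed base seed for the substreams (default 1).
#' @param positions if `FALSE`, coordinates are filled with zeros; counts
#'   are unchanged. Useful for purely temporal experiments.
#' @return an [event_table()] with attribute `truth`: a list with per-root
#'   burst frames, the injected periods, and per-root parent counts.
#' @export
simulate_table <- function(config_intact, config_regen, n_roots_per_condition,
                           seed = 1L, positions = TRUE) {
  validate_synth_config(config_intact)
  validate_synth_config(config_regen)
  if (n_roots_per_condition < 1L) stop("n_roots_per_condition must be >= 1")
  if (config_intact$n_frames != config_regen$n_frames ||
      config_intact$delta_t_h != config_regen$delta_t_h) {
    stop("the two configs must share n_frames and delta_t_h")
  }
  n_roots <- as.integer(n_roots_per_condition)
  seed <- as.integer(seed)

  rows <- list()
  truth <- list(seed = seed,
                period_h = c(intact = config_intact$period_h,
                             regenerating = config_regen$period_h),
                roots = list())
  ordinal <- 0L
  for (cond in c("intact", "regenerating")) {
    cfg <- if (cond == "intact") config_intact else config_regen
    for (r in seq_len(n_roots)) {
      ordinal <- ordinal + 1L
      root_id <- sprintf("%s_%d", cond, r)
      set.seed(seed + ordinal)
      counts <- simulate_counts(cfg, seed = NULL)
      n_parents <- 0L
      frames <- rep.int(seq_along(counts) - 1L, counts)
      if (positions && length(frames) > 0L) {
        pos_list <- vector("list", cfg$n_frames)
        for (f in which(counts > 0L)) {
          p <- simulate_positions(counts[f], cfg, seed = NULL)
          n_parents <- n_parents + nrow(attr(p, "parents"))
          pos_list[[f]] <- p
        }
        pos <- do.call(rbind, pos_list[!vapply(pos_list, is.null, logical(1))])
      } else {
        pos <- matrix(0, length(frames), 3L,
                      dimnames = list(NULL, c("x_um", "y_um", "z_um")))
      }
      if (length(frames) > 0L) {
        rows[[root_id]] <- data.frame(
          root_id = root_id, condition = cond, frame_index = frames,
          x_um = pos[, 1L], y_um = pos[, 2L], z_um = pos[, 3L],
          stringsAsFactors = FALSE)
      }
      truth$roots[[root_id]] <- list(
        condition = cond, burst_frames = attr(counts, "burst_frames"),
        n_events = sum(counts), n_parents = n_parents)
    }
  }
  events <- if (length(rows) > 0L) do.call(rbind, rows) else {
    data.frame(root_id = character(0), condition = character(0),
               frame_index = integer(0), x_um = numeric(0),
               y_um = numeric(0), z_um = numeric(0))
  }
  rownames(events) <- NULL
  out <- event_table(events, delta_t_h = config_intact$delta_t_h,
                     n_frames = config_intact$n_frames)
  attr(out, "truth") <- truth
  out
}
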