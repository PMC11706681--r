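#' Default study configurations emulating the imaging experiment
#'
#' A convenience pair of [synth_config()]s mirroring the study design the
#' package targets: four roots per condition imaged every 15 minutes for
#' 7 days (672 frames). The intact condition carries a 24-h modulation
#' (the entrained light-cycle periodicity) and rare bursts; the
#' regenerating condition carries a 16.8-h modulation (the
#' regeneration-band periodicity, placed on the Fourier grid of a 168-h
#' recording) and, from 24 h on, more frequent and larger bursts — the
#' post-excision transition.
#'
#' @param n_frames,delta_t_h frame grid shared by both conditions.
#' @return list with elements `intact` and `regenerating`.
#' @export
study_configs <- function(n_frames = 672L, delta_t_h = 0.25) {
  list(
    intact = synth_config(
      n_frames = n_frames, delta_t_h = delta_t_h, lambda_base = 5,
      burst_rate = 0.01, burst_size_mean = 10,
      period_h = 24, mod_amplitude = 0.3),
    regenerating = synth_config(
      n_frames = n_frames, delta_t_h = delta_t_h, lambda_base = 5,
      burst_rate = 0.01, burst_size_mean = 10,
      period_h = 16.8, mod_amplitude = 0.5,
      switch_time_h = 24, burst_rate_post = 0.12, burst_size_mean_post = 12))
}

#' Simulate a study and write the event table plus ground truth
#'
#' @param config_intact,config_regen [synth_config()]s (default:
#'   [study_configs()]).
#' @param n_roots_per_condition roots per condition.
#' @param seed base seed.
#' @param out_dir output directory (created if needed). Writes
#'   `events.csv` and `truth.json` (per-root burst frames, injected
#'   periods, parent counts).
#' @return the simulated [event_table()], invisibly.
#' @export
pipeline_simulate <- function(out_dir, config_intact = study_configs()$intact,
                              config_regen = study_configs()$regenerating,
                              n_roots_per_condition = 4L, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  table <- simulate_table(config_intact, config_regen,
                          n_roots_per_condition, seed = seed)
  write_events(table, file.path(out_dir, "events.csv"))
  truth <- attr(table, "truth")
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("simulate: %d events, %d roots -> %s", nrow(table),
                  2L * n_roots_per_condition, out_dir))
  invisible(table)
}

#' Run the full analysis on an event table
#'
#' Computes per-root frame counts, per-condition burst thresholds and
#' bursts, per-condition averaged periodograms with their top peaks,
#' per-frame DBSCAN clusterings with summaries, and pairwise cluster
#' centre distances; writes everything as CSV plus a JSON summary with
#' all effective parameters.
#'
#' @param input an [event_table()] or a path to an events CSV.
#' @param out_dir output directory.
#' @param delta_t_h sampling interval, used when `input` is a path.
#' @param params a [cluster_params()].
#' @param sd_type burst-threshold SD flavour, see [burst_threshold()].
#' @param top_k number of top periods reported per condition.
#' @return list with `counts`, `bursts`, `periodograms`, `clusters`,
#'   `summaries`, `distances`, `summary`, invisibly.
#' @export
pipeline_analyse <- function(input, out_dir, delta_t_h = 0.25,
                             params = cluster_params(), sd_type = "sample",
                             top_k = 3L) {
  table <- if (inherits(input, "event_table")) input else {
    read_events(input, delta_t_h = delta_t_h)
  }
  if (nrow(table) == 0L) stop("event table is empty: nothing to analyse")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  conds <- intersect(c("intact", "regenerating"), unique(table$condition))

  counts_rows <- list(); burst_rows <- list(); pg_rows <- list()
  summary_json <- list(
    package_version = as.character(utils::packageVersion("mitodyn")),
    n_events = nrow(table), n_frames = n_frames(table),
    delta_t_h = delta_t(table),
    parameters = list(epsilon_um = params$epsilon_um,
                      min_samples = params$min_samples,
                      sd_type = sd_type,
                      burst_pooling = "per-condition",
                      periodogram = "plain FFT, mean-removed, unwindowed, PSDs averaged across roots"),
    conditions = list())

  for (cond in conds) {
    roots <- unique(table$root_id[table$condition == cond])
    series <- lapply(roots, function(r) counts_per_frame(table, r))
    names(series) <- roots
    thr <- burst_threshold(series, sd_type = sd_type)
    all_sizes <- integer(0)
    for (r in roots) {
      s <- series[[r]]
      counts_rows[[r]] <- data.frame(root_id = r, condition = cond,
                                     frame_index = seq_along(s$counts) - 1L,
                                     count = s$counts)
      bs <- detect_bursts(s, thr)$bursts
      if (nrow(bs) > 0L) {
        burst_rows[[r]] <- data.frame(root_id = r, condition = cond, bs)
        all_sizes <- c(all_sizes, bs$size)
      }
    }
    pg <- condition_periodogram(table, cond)
    pg_rows[[cond]] <- data.frame(condition = cond, period_h = pg$period_h,
                                  psd = pg$psd)
    tp <- top_periods(pg, k = top_k)
    poisson_cmp <- NULL
    if (length(all_sizes) > 0L) {
      modal <- as.integer(names(which.max(table(all_sizes))))
      cmp <- compare_to_poisson(all_sizes, mode_matched_poisson(modal))
      poisson_cmp <- list(mode = modal, lambda = cmp$lambda,
                          d_stat = cmp$d_stat, p_value = cmp$p_value,
                          n_bursts = cmp$n)
    }
    summary_json$conditions[[cond]] <- list(
      n_roots = length(roots), n_events = sum(table$condition == cond),
      burst_threshold = thr, n_bursts = length(all_sizes),
      top_periods_h = tp$period_h, top_periods_significant = tp$significant,
      poisson_comparison = poisson_cmp)
  }

  clusters <- cluster_events(table, params)
  sums <- summarize_frames(table, params)
  sum_rows <- do.call(rbind, lapply(sums, function(s) {
    data.frame(root_id = s$root_id, frame_index = s$frame_index,
               time_h = s$time_h, n_clusters = s$n_clusters,
               n_noise = s$n_noise,
               sizes = paste(s$sizes, collapse = ";"))
  }))
  dist_rows <- do.call(rbind, lapply(sums, function(s) {
    d <- pairwise_centre_distances(s)
    if (length(d) == 0L) return(NULL)
    data.frame(root_id = s$root_id, frame_index = s$frame_index,
               time_h = s$time_h, dist_um = d)
  }))

  write_csv0 <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  write_csv0(do.call(rbind, counts_rows), "counts.csv")
  write_csv0(if (length(burst_rows) > 0L) do.call(rbind, burst_rows) else
    data.frame(root_id = character(0), condition = character(0),
               frame_index = integer(0), size = integer(0),
               time_h = numeric(0)), "bursts.csv")
  write_csv0(do.call(rbind, pg_rows), "periodogram.csv")
  write_csv0(clusters, "clusters.csv")
  write_csv0(sum_rows, "cluster_summary.csv")
  write_csv0(if (is.null(dist_rows)) data.frame(root_id = character(0),
    frame_index = integer(0), time_h = numeric(0), dist_um = numeric(0))
    else dist_rows, "distances.csv")
  write_events(table, file.path(out_dir, "events.csv"))
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("analyse: %d events, %d clusterable frames -> %s",
                  nrow(table), length(sums), out_dir))
  invisible(list(counts = do.call(rbind, counts_rows),
                 bursts = if (length(burst_rows) > 0L)
                   do.call(rbind, burst_rows) else NULL,
                 periodograms = pg_rows, clusters = clusters,
                 summaries = sums, distances = dist_rows,
                 summary = summary_json))
}

#' Compare conditions of an analysed bundle
#'
#' @param bundle a directory written by [pipeline_analyse()] (its
#'   `events.csv` is re-read), or an [event_table()] with both conditions.
#' @param out_dir output directory; writes `comparison.json` and
#'   `comparison.txt`.
#' @param delta_t_h sampling interval when re-reading from disk.
#' @inheritParams run_comparisons
#' @return the [run_comparisons()] report, invisibly.
#' @export
pipeline_compare <- function(bundle, out_dir, delta_t_h = 0.25,
                             params = cluster_params(),
                             metrics = c("events_per_frame", "burst_sizes",
                                         "centre_distances")) {
  table <- if (inherits(bundle, "event_table")) bundle else {
    read_events(file.path(bundle, "events.csv"), delta_t_h = delta_t_h)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- run_comparisons(table, params = params, metrics = metrics)
  out <- list(conventions = attr(report, "conventions"),
              comparisons = as.data.frame(report))
  jsonlite::write_json(out, file.path(out_dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "comparison.txt"))
  message(sprintf("compare: %d comparisons -> %s", nrow(report), out_dir))
  invisible(report)
}

#' Read a flat YAML configuration into a [synth_config()]
#'
#' Unknown keys are rejected; listed keys override the defaults.
#'
#' @param path YAML file of scalar keys mirroring [synth_config()]
#'   arguments.
#' @return a [synth_config()].
#' @export
read_synth_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(synth_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad) > 0L) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  do.call(synth_config, vals)
}
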