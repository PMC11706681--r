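#' Construct a validated mitotic-event table
#'
#' The central data container of the package: one row per detected cell
#' division, with the root it belongs to, its experimental condition, the
#' frame in which it was detected and its 3D centre of mass in micrometres.
#' Time in hours is always derived from the frame index and the sampling
#' interval (`time_h = frame_index * delta_t_h`); the frame index is
#' authoritative.
#'
#' @param events data frame with columns `root_id`, `condition`,
#'   `frame_index`, `x_um`, `y_um`, `z_um` and optionally `event_id` (one is
#'   generated when absent). `condition` must be `"intact"` or
#'   `"regenerating"`.
#' @param delta_t_h sampling interval in hours per frame (default 0.25,
#'   i.e. one stack every 15 minutes).
#' @param n_frames number of frames in the recording. Defaults to
#'   `max(frame_index) + 1` (0 for an empty table); must be at least that.
#' @return an object of class `event_table` (a data frame with columns
#'   `event_id`, `root_id`, `condition`, `frame_index`, `time_h`, `x_um`,
#'   `y_um`, `z_um` and attributes `delta_t_h`, `n_frames`).
#' @seealso [read_events()], [assign_time_bins()]
#' @export
event_table <- function(events, delta_t_h = 0.25, n_frames = NULL) {
  stopifnot(is.data.frame(events))
  if (!is.numeric(delta_t_h) || length(delta_t_h) != 1L || delta_t_h <= 0) {
    stop("`delta_t_h` must be a single positive number of hours")
  }
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  # tolerate bare x/y/z column names from external trackers
  for (ax in c("x", "y", "z")) {
    um <- paste0(ax, "_um")
    if (!um %in% names(events) && ax %in% names(events)) {
      names(events)[names(events) == ax] <- um
    }
  }
  required <- c("root_id", "condition", "frame_index", "x_um", "y_um", "z_um")
  missing_cols <- setdiff(required, names(events))
  if (length(missing_cols) > 0L) {
    stop("event table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(events)
  if (!"event_id" %in% names(events)) {
    events$event_id <- if (n > 0L) paste0("ev", seq_len(n)) else character(0)
  }
  events$event_id <- as.character(events$event_id)
  events$root_id <- as.character(events$root_id)
  events$condition <- as.character(events$condition)

  bad_cond <- which(!events$condition %in% c("intact", "regenerating"))
  if (length(bad_cond) > 0L) {
    stop("row ", bad_cond[1L], ": condition must be 'intact' or 'regenerating', got '",
         events$condition[bad_cond[1L]], "'")
  }
  fi <- suppressWarnings(as.numeric(events$frame_index))
  bad <- which(!is.finite(fi) | fi < 0 | fi != floor(fi))
  if (length(bad) > 0L) {
    stop("row ", bad[1L], ": frame_index must be a non-negative integer, got '",
         events$frame_index[bad[1L]], "'")
  }
  events$frame_index <- as.integer(fi)
  for (col in c("x_um", "y_um", "z_um")) {
    v <- suppressWarnings(as.numeric(events[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      stop("row ", bad[1L], ": ", col, " must be a finite number, got '",
           events[[col]][bad[1L]], "'")
    }
    events[[col]] <- v
  }
  if (anyDuplicated(events$event_id)) {
    stop("event_id values must be unique")
  }

  min_frames <- if (n > 0L) max(events$frame_index) + 1L else 0L
  if (is.null(n_frames)) {
    n_frames <- min_frames
  } else {
    n_frames <- as.integer(n_frames)
    if (n_frames < min_frames) {
      stop("n_frames (", n_frames, ") is smaller than 1 + max(frame_index) (",
           min_frames, ")")
    }
  }
  events$time_h <- events$frame_index * delta_t_h
  out <- events[, c("event_id", "root_id", "condition", "frame_index",
                    "time_h", "x_um", "y_um", "z_um")]
  rownames(out) <- NULL
  structure(out, delta_t_h = delta_t_h, n_frames = n_frames,
            class = c("event_table", "data.frame"))
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events, %d roots, %d frames (dt = %g h)\n",
              nrow(x), length(unique(x$root_id)), n_frames(x), delta_t(x)))
  if (nrow(x) > 0L) {
    tab <- table(x$condition)
    cat("  events by condition:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
    print(utils::head(as.data.frame(x), 6L))
    if (nrow(x) > 6L) cat("  ...", nrow(x) - 6L, "more rows\n")
  }
  invisible(x)
}

#' Sampling interval and frame count of an event table
#'
#' @param table an `event_table`.
#' @return `delta_t()`: hours per frame; `n_frames()`: number of frames.
#' @export
delta_t <- function(table) attr(table, "delta_t_h")

#' @rdname delta_t
#' @export
n_frames <- function(table) attr(table, "n_frames")

#' Read a mitotic-event table from delimited text
#'
#' Accepts comma- or tab-separated text (auto-detected from the header
#' line) with at least the columns `root_id`, `condition`, `frame_index`
#' and coordinates (`x_um`/`y_um`/`z_um`, or bare `x`/`y`/`z`). A `time_h`
#' column, if present, is ignored and recomputed from `frame_index` so the
#' frame grid stays authoritative.
#'
#' @param path path to the delimited text file.
#' @inheritParams event_table
#' @return an [event_table()].
#' @export
read_events <- function(path, delta_t_h = 0.25, n_frames = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("file is empty (no header line): ", path)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = TRUE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  raw$time_h <- NULL
  event_table(raw, delta_t_h = delta_t_h, n_frames = n_frames)
}

#' Write a mitotic-event table as CSV
#'
#' Writes the standard eight-column layout (`event_id`, `root_id`,
#' `condition`, `frame_index`, `time_h`, `x_um`, `y_um`, `z_um`), comma
#' separated, UTF-8. [read_events()] on the written file restores the
#' table field-for-field.
#'
#' @param table an `event_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Post-excision time bins
#'
#' The analysis windows used throughout the package: 0-6 h, 6-24 h,
#' 24-72 h and beyond 72 h after the start of imaging. Intervals are
#' half-open `[lower, upper)`, so a time of exactly 6 h falls in the
#' 6-24 h bin; together they partition `[0, Inf)`.
#'
#' @return character vector of the four bin labels, in temporal order.
#' @export
time_bin_levels <- function() c("bin_0_6", "bin_6_24", "bin_24_72", "bin_gt_72")

#' Bin edges in hours (lower edges; the last bin is unbounded above).
#' @rdname time_bin_levels
#' @export
time_bin_edges <- function() c(0, 6, 24, 72, Inf)

#' Assign each event to a post-excision time bin
#'
#' @param table an `event_table`.
#' @return a factor of bin labels (levels [time_bin_levels()]), one per
#'   event, named by `event_id`.
#' @export
assign_time_bins <- function(table) {
  stopifnot(inherits(table, "event_table"))
  bins <- cut(table$time_h, breaks = time_bin_edges(),
              labels = time_bin_levels(), right = FALSE)
  names(bins) <- table$event_id
  bins
}

# Bin labels for arbitrary hour values (used for frames as well as events).
bin_of_time <- function(time_h) {
  cut(time_h, breaks = time_bin_edges(), labels = time_bin_levels(),
      right = FALSE)
}
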