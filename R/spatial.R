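#' Modelled cell diameter (maximum diagonal of a cuboid cell)
#'
#' Events are modelled as cuboid cells of edge lengths `dx`, `dy`, `dz`
#' micrometres around each centre of mass; the "diameter" is the cuboid's
#' maximum diagonal, i.e. the Euclidean norm of the edge vector. For the
#' default meristematic cell model, 6 x 4 x 4 um, this is
#' `sqrt(68) = 8.246` um (8.24 at the printed precision).
#'
#' @param dx,dy,dz cell edge lengths in micrometres (all >= 0, not all 0).
#' @return diameter in micrometres.
#' @export
cell_diameter <- function(dx = 6, dy = 4, dz = 4) {
  if (any(c(dx, dy, dz) < 0)) stop("cell edges must be non-negative")
  d <- sqrt(dx^2 + dy^2 + dz^2)
  if (d == 0) stop("cell edges must not all be zero")
  d
}

#' DBSCAN neighbourhood radius from the cell diameter
#'
#' The clustering radius is `k` cell diameters; with the printed rounded
#' diameter 8.24 um and the default `k = 3`, epsilon is exactly 24.72 um.
#'
#' @param diameter cell diameter in micrometres (> 0).
#' @param k number of cell diameters (integer >= 1, default 3).
#' @return epsilon in micrometres.
#' @export
epsilon_from_diameter <- function(diameter = 8.24, k = 3L) {
  if (diameter <= 0) stop("diameter must be > 0")
  if (k < 1) stop("k must be >= 1")
  k * diameter
}

#' Clustering parameters
#'
#' @param epsilon_um neighbourhood radius in micrometres (> 0). The
#'   default is three times the printed 8.24-um cell diameter; set
#'   `epsilon_um = epsilon_from_diameter(cell_diameter(6, 4, 4))` for the
#'   unrounded variant (24.7386 um).
#' @param min_samples core-point threshold, counting the point itself
#'   (>= 1). The default 2 makes DBSCAN exactly epsilon-connectivity
#'   clustering: any two events within epsilon join a cluster, isolated
#'   events are noise.
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(epsilon_um = 24.72, min_samples = 2L) {
  if (epsilon_um <= 0) stop("epsilon_um must be > 0")
  if (min_samples < 1L) stop("min_samples must be >= 1")
  structure(list(epsilon_um = epsilon_um, min_samples = as.integer(min_samples)),
            class = "cluster_params")
}

#' DBSCAN clustering of one frame's 3D event positions
#'
#' Standard DBSCAN with Euclidean distance: a core point has at least
#' `min_samples` points (itself included) within `epsilon_um`; clusters
#' are maximal density-connected sets of core points plus the border
#' points they reach; remaining points are noise. Cluster labels are
#' integers from 0, numbered by ascending input index of each cluster's
#' first member, so the labelling is deterministic.
#'
#' @param points n x 3 numeric matrix of positions (um); one frame only.
#' @param params a [cluster_params()].
#' @return integer vector of length n: cluster label (>= 0) or -1 for
#'   noise.
#' @export
dbscan_labels <- function(points, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0L) return(integer(0))
  if (ncol(points) != 3L) stop("points must have three coordinate columns")
  if (!all(is.finite(points))) stop("points must be finite")
  eps <- params$epsilon_um
  d <- as.matrix(stats::dist(points))
  neighbours <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  is_core <- vapply(neighbours, length, integer(1)) >= params$min_samples
  labels <- rep.int(-2L, n)  # -2 unvisited, -1 noise
  next_label <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != -2L) next
    if (!is_core[i]) {
      labels[i] <- -1L
      next
    }
    labels[i] <- next_label
    queue <- neighbours[[i]]
    while (length(queue) > 0L) {
      j <- queue[[1L]]
      queue <- queue[-1L]
      if (labels[j] == -2L || labels[j] == -1L) {
        newly <- labels[j] == -2L
        labels[j] <- next_label
        if (is_core[j] && newly) queue <- c(queue, neighbours[[j]])
      }
    }
    next_label <- next_label + 1L
  }
  labels
}

#' Cluster every frame of an event table
#'
#' Applies [dbscan_labels()] independently to each (root, frame) point
#' set; clustering never crosses frames or roots.
#'
#' @param table an [event_table()].
#' @param params a [cluster_params()].
#' @return data frame with `event_id`, `root_id`, `condition`,
#'   `frame_index`, `time_h`, `label` (per-frame labels, -1 = noise), in
#'   the row order of `table`.
#' @export
cluster_events <- function(table, params = cluster_params()) {
  stopifnot(inherits(table, "event_table"))
  out <- data.frame(event_id = table$event_id, root_id = table$root_id,
                    condition = table$condition,
                    frame_index = table$frame_index, time_h = table$time_h,
                    label = rep.int(-1L, nrow(table)),
                    stringsAsFactors = FALSE)
  if (nrow(table) == 0L) return(out)
  key <- paste(table$root_id, table$frame_index, sep = "\r")
  for (idx in split(seq_len(nrow(table)), key)) {
    pts <- as.matrix(table[idx, c("x_um", "y_um", "z_um")])
    out$label[idx] <- dbscan_labels(pts, params)
  }
  out
}

#' Summarize one frame's clustering
#'
#' @param labels integer labels from [dbscan_labels()].
#' @param points the matching n x 3 position matrix (um).
#' @param frame_index optional frame number carried through.
#' @return a `cluster_summary`: list with `frame_index`, `n_clusters`,
#'   `sizes` (member counts by label), `centres` (n_clusters x 3 matrix of
#'   unweighted member means), `n_noise`.
#' @export
summarize_clusters <- function(labels, points, frame_index = NA_integer_) {
  points <- as.matrix(points)
  if (length(labels) != nrow(points)) {
    stop("labels and points disagree in length")
  }
  keep <- labels >= 0L
  labs <- sort(unique(labels[keep]))
  sizes <- integer(0)
  centres <- matrix(numeric(0), 0L, 3L,
                    dimnames = list(NULL, c("x_um", "y_um", "z_um")))
  if (length(labs) > 0L) {
    sizes <- vapply(labs, function(l) sum(labels == l), integer(1))
    centres <- t(vapply(labs, function(l) {
      colMeans(points[labels == l, , drop = FALSE])
    }, numeric(3)))
    colnames(centres) <- c("x_um", "y_um", "z_um")
  }
  structure(list(frame_index = frame_index, n_clusters = length(labs),
                 sizes = sizes, centres = centres,
                 n_noise = sum(labels == -1L)),
            class = "cluster_summary")
}

#' Per-frame cluster summaries for a whole table
#'
#' @inheritParams cluster_events
#' @param condition optional filter (`"intact"` or `"regenerating"`).
#' @return list of [summarize_clusters()] results, one per (root, frame)
#'   that contains at least one event, each with extra fields `root_id`
#'   and `time_h`.
#' @export
summarize_frames <- function(table, params = cluster_params(),
                             condition = NULL) {
  stopifnot(inherits(table, "event_table"))
  if (!is.null(condition)) {
    table <- table[table$condition == condition, , drop = FALSE]
    class(table) <- c("event_table", "data.frame")
  }
  if (nrow(table) == 0L) return(list())
  key <- paste(table$root_id, table$frame_index, sep = "\r")
  groups <- split(seq_len(nrow(table)), key)
  lapply(unname(groups), function(idx) {
    pts <- as.matrix(table[idx, c("x_um", "y_um", "z_um")])
    labels <- dbscan_labels(pts, params)
    s <- summarize_clusters(labels, pts, frame_index = table$frame_index[idx][1L])
    s$root_id <- table$root_id[idx][1L]
    s$time_h <- table$time_h[idx][1L]
    s
  })
}

#' Joint distribution of cluster number and cluster size
#'
#' For each frame, every cluster contributes one observation at
#' (that frame's number of clusters, that cluster's size); frequencies are
#' aggregated over frames. Frames without clusters contribute nothing.
#'
#' @param summaries list of [summarize_clusters()] results.
#' @return data frame with `n_clusters`, `size`, `freq`.
#' @export
cluster_count_size_distribution <- function(summaries) {
  pairs <- do.call(rbind, lapply(summaries, function(s) {
    if (s$n_clusters == 0L) return(NULL)
    data.frame(n_clusters = s$n_clusters, size = s$sizes)
  }))
  if (is.null(pairs)) {
    return(data.frame(n_clusters = integer(0), size = integer(0),
                      freq = integer(0)))
  }
  agg <- stats::aggregate(list(freq = rep.int(1L, nrow(pairs))),
                          by = pairs[c("n_clusters", "size")], FUN = sum)
  agg[order(agg$n_clusters, agg$size), , drop = FALSE]
}

#' Pairwise distances between a frame's cluster centres of mass
#'
#' @param summary a [summarize_clusters()] result.
#' @return numeric vector of the `choose(n_clusters, 2)` Euclidean
#'   distances (um); empty when the frame has fewer than two clusters.
#' @export
pairwise_centre_distances <- function(summary) {
  stopifnot(inherits(summary, "cluster_summary"))
  if (summary$n_clusters < 2L) return(numeric(0))
  as.vector(stats::dist(summary$centres))
}
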