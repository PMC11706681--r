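# Independent brute-force oracles used across test files.

# Connected components of the eps-neighbourhood graph via union-find;
# isolated vertices are noise (-1). Equals DBSCAN with min_samples = 2.
brute_eps_components <- function(points, eps) {
  n <- nrow(points)
  if (n == 0L) return(integer(0))
  d <- as.matrix(dist(points))
  parent <- seq_len(n)
  find <- function(i) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    r
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && d[i, j] <= eps) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- rep(-1L, n)
  for (r in unique(roots)) {
    members <- which(roots == r)
    if (length(members) > 1L) labels[members] <- r
  }
  labels
}

# canonical form of a labelling: clusters as sorted member-index vectors
# ordered by first member, plus the set of noise indices
canonical_partition <- function(labels) {
  clusters <- split(which(labels >= 0L), labels[labels >= 0L])
  clusters <- lapply(unname(clusters), sort)
  ord <- order(vapply(clusters, `[`, numeric(1), 1L))
  list(clusters = clusters[ord], noise = sort(which(labels == -1L)))
}

# double-loop ECDF supremum oracle for the two-sample K-S statistic
ks_d_oracle <- function(a, b) {
  xs <- c(a, b)
  d <- 0
  for (x in xs) {
    d <- max(d, abs(mean(a <= x) - mean(b <= x)))
  }
  d
}

# 100-term Kolmogorov survival series, accumulated term by term,
# written independently of the package implementation
ks_p_oracle <- function(d, n1, n2) {
  lam <- sqrt(n1 * n2 / (n1 + n2)) * d
  if (lam <= 0) return(1)
  acc <- 0
  for (j in 1:100) acc <- acc + (-1)^(j - 1) * exp(-2 * j^2 * lam^2)
  max(0, min(1, 2 * acc))
}

# strip event_table attributes down to a plain data frame for comparison
plain_df <- function(x) {
  x <- as.data.frame(x)
  keep <- attributes(x)[c("names", "row.names")]
  attributes(x) <- c(keep, list(class = "data.frame"))
  rownames(x) <- NULL
  x
}

# small hand-built event table used by several files
tiny_table <- function() {
  event_table(data.frame(
    event_id = c("a", "b", "c", "d"),
    root_id = c("r1", "r1", "r1", "r2"),
    condition = c("intact", "intact", "intact", "regenerating"),
    frame_index = c(0L, 0L, 2L, 1L),
    x_um = c(0, 10, 50, 5), y_um = c(0, 0, 50, 5), z_um = c(0, 0, 50, 5)),
    delta_t_h = 0.25, n_frames = 4L)
}
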