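test_that("cell diameter is the cuboid's maximum diagonal", {
  expect_equal(cell_diameter(6, 4, 4), sqrt(68))
  expect_lt(abs(cell_diameter(6, 4, 4) - 8.24), 0.01)
  expect_equal(cell_diameter(1, 0, 0), 1)
  expect_equal(cell_diameter(3, 4, 12), 13)
  expect_error(cell_diameter(-1, 2, 2), "non-negative")
  expect_error(cell_diameter(0, 0, 0), "zero")
})

test_that("epsilon is k cell diameters", {
  expect_equal(epsilon_from_diameter(8.24, 3), 24.72)
  expect_equal(epsilon_from_diameter(5, 1), 5)
  expect_equal(epsilon_from_diameter(cell_diameter(6, 4, 4), 3), 3 * sqrt(68))
  expect_error(epsilon_from_diameter(0, 3), "diameter")
  expect_error(epsilon_from_diameter(8.24, 0), "k")
})

test_that("DBSCAN handles pairs, isolated points and empty input", {
  p <- cluster_params(epsilon_um = 24.72, min_samples = 2L)
  two <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(dbscan_labels(two, p), c(0L, 0L))
  lone <- rbind(c(0, 0, 0), c(100, 100, 100))
  expect_equal(dbscan_labels(lone, p), c(-1L, -1L))
  expect_equal(dbscan_labels(matrix(numeric(0), 0, 3), p), integer(0))
  # labels numbered by first member input index
  three <- rbind(c(0, 0, 0), c(200, 0, 0), c(205, 0, 0))
  expect_equal(dbscan_labels(three, p), c(-1L, 0L, 0L))
  expect_error(dbscan_labels(rbind(c(NA, 0, 0)), p), "finite")
})

test_that("DBSCAN with min_samples = 2 equals eps-graph connected components", {
  p <- cluster_params(epsilon_um = 24.72, min_samples = 2L)
  set.seed(77)
  for (i in 1:50) {
    n <- sample(1:50, 1)
    pts <- matrix(runif(3 * n, 0, 200), ncol = 3)
    got <- canonical_partition(dbscan_labels(pts, p))
    want <- canonical_partition(brute_eps_components(pts, 24.72))
    expect_equal(got, want)
  }
})

test_that("DBSCAN is invariant under permutation and rigid motion", {
  p <- cluster_params(epsilon_um = 20, min_samples = 2L)
  set.seed(101)
  for (i in 1:10) {
    pts <- matrix(runif(90, 0, 150), ncol = 3)
    base <- canonical_partition(dbscan_labels(pts, p))

    perm <- sample(nrow(pts))
    lab_perm <- dbscan_labels(pts[perm, ], p)
    # map permuted labels back to original indexing
    lab_back <- integer(nrow(pts))
    lab_back[perm] <- lab_perm
    expect_equal(canonical_partition(lab_back), base)

    theta <- runif(1, 0, 2 * pi)
    rot <- rbind(c(cos(theta), -sin(theta), 0),
                 c(sin(theta), cos(theta), 0),
                 c(0, 0, 1))
    moved <- pts %*% rot + matrix(rnorm(3, sd = 50), nrow(pts), 3,
                                  byrow = TRUE)
    expect_equal(canonical_partition(dbscan_labels(moved, p)), base)
  }
})

test_that("growing epsilon only merges clusters (refinement property)", {
  set.seed(202)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    pts <- matrix(runif(3 * n, 0, 120), ncol = 3)
    eps <- runif(1, 5, 30)
    small <- dbscan_labels(pts, cluster_params(eps, 2L))
    big <- dbscan_labels(pts, cluster_params(2 * eps, 2L))
    for (l in unique(small[small >= 0])) {
      members <- which(small == l)
      expect_length(unique(big[members]), 1L)  # cluster stays together
      expect_true(all(big[members] >= 0L))     # and is never demoted
    }
  }
})

test_that("cluster summaries report sizes and unweighted centres", {
  pts <- rbind(c(0, 0, 0), c(2, 0, 0), c(100, 100, 100))
  labels <- c(0L, 0L, -1L)
  s <- summarize_clusters(labels, pts, frame_index = 3L)
  expect_equal(s$n_clusters, 1L)
  expect_equal(s$sizes, 2L)
  expect_equal(unname(s$centres[1, ]), c(1, 0, 0))  # midpoint
  expect_equal(s$n_noise, 1L)

  all_noise <- summarize_clusters(c(-1L, -1L), pts[1:2, ])
  expect_equal(all_noise$n_clusters, 0L)
  expect_length(all_noise$sizes, 0L)
  expect_equal(sum(s$sizes) + s$n_noise, nrow(pts))
})

test_that("count-size distribution expands frames and conserves events", {
  mk <- function(sizes, frame) {
    n <- sum(sizes)
    labels <- rep(seq_along(sizes) - 1L, sizes)
    pts <- matrix(seq_len(3 * n), ncol = 3)
    summarize_clusters(labels, pts, frame_index = frame)
  }
  dist1 <- cluster_count_size_distribution(list(mk(c(2L, 3L), 0L)))
  expect_equal(dist1$n_clusters, c(2L, 2L))
  expect_equal(dist1$size, c(2L, 3L))
  expect_equal(dist1$freq, c(1L, 1L))

  # frames with no clusters contribute nothing
  none <- summarize_clusters(c(-1L), matrix(1:3, 1))
  expect_equal(nrow(cluster_count_size_distribution(list(none))), 0L)

  # recount oracle on a simulated table + event conservation
  cfg <- synth_config(n_frames = 48L, lambda_base = 4, seed = 6L)
  tab <- simulate_table(cfg, cfg, 2L, seed = 6L)
  p <- cluster_params(24.72, 2L)
  sums <- summarize_frames(tab, p)
  d <- cluster_count_size_distribution(sums)
  brute <- table(unlist(lapply(sums, function(s) {
    if (s$n_clusters == 0) return(character(0))
    paste(s$n_clusters, s$sizes)
  })))
  expect_equal(sum(d$freq), sum(unname(brute)))
  expect_equal(setNames(d$freq, paste(d$n_clusters, d$size)),
               setNames(as.integer(brute), names(brute))[paste(d$n_clusters, d$size)])
  clustered <- sum(cluster_events(tab, p)$label >= 0)
  expect_equal(sum(d$size * d$freq), clustered)
})

test_that("pairwise centre distances enumerate all cluster pairs", {
  centres2 <- summarize_clusters(c(0L, 1L), rbind(c(0, 0, 0), c(3, 4, 0)),
                                 frame_index = 0L)
  # single-member "clusters" only arise with min_samples = 1, but the
  # distance computation is label-agnostic
  expect_equal(pairwise_centre_distances(centres2), 5)
  one <- summarize_clusters(c(0L, 0L), rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(pairwise_centre_distances(one), numeric(0))

  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(10, 0, 0), c(11, 0, 0),
               c(0, 20, 0), c(1, 20, 0))
  labels <- c(0L, 0L, 1L, 1L, 2L, 2L)
  s <- summarize_clusters(labels, pts)
  d <- pairwise_centre_distances(s)
  expect_length(d, choose(3, 2))
  cen <- s$centres
  manual <- c(sqrt(sum((cen[1, ] - cen[2, ])^2)),
              sqrt(sum((cen[1, ] - cen[3, ])^2)),
              sqrt(sum((cen[2, ] - cen[3, ])^2)))
  expect_equal(sort(d), sort(manual))
})

test_that("cluster_events never clusters across frames or roots", {
  # same coordinates in different frames / roots must not merge
  tab <- event_table(data.frame(
    root_id = c("r1", "r1", "r1", "r2"),
    condition = c("intact", "intact", "intact", "regenerating"),
    frame_index = c(0L, 0L, 1L, 0L),
    x_um = c(0, 5, 0, 0), y_um = 0, z_um = 0))
  cl <- cluster_events(tab, cluster_params(24.72, 2L))
  expect_equal(cl$label, c(0L, 0L, -1L, -1L))
})
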