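test_that("euclidean distances match hand-computed sensor examples", {
  a <- c(0, 0, 0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 0)
  b <- c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(euclidean_distance(a, b), sqrt(3))
  expect_equal(round_half_up(euclidean_distance(a, b), 1), 1.7)
  expect_equal(euclidean_distance(a, a), 0)
  i1 <- c(0, 0, 0, 0, 2, 2, 0, 0, 0, 0, 0, 0, 3, 0)
  i2 <- c(0, 0, 0, 0, 3, 3, 0, 0, 0, 1, 2, 0, 1, 0)
  i3 <- c(0, 0, 0, 0, 3, 2, 0, 0, 0, 4, 0, 0, 2, 0)
  expect_equal(squared_distance(i1, i2), 11)
  expect_equal(squared_distance(i2, i3), 15)
  expect_equal(squared_distance(i1, i3), 18)
  expect_error(euclidean_distance(1:3, 1:4), "length")
})

test_that("feature-subset draws are uniform with replacement and deduplicated", {
  expect_equal(sample_feature_subset(1L)$idx, 1L)
  withr_seed(7)
  draws <- unlist(replicate(10000L, sample_feature_subset(14L)$raw,
                            simplify = FALSE))
  tab <- table(factor(draws, levels = 1:14))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 1e-3)
  withr_seed(7)
  s1 <- sample_feature_subset(14L)
  withr_seed(7)
  s2 <- sample_feature_subset(14L)
  expect_identical(s1, s2)
  expect_false(anyDuplicated(s1$idx) > 0)
  expect_true(all(s1$idx %in% seq_len(14L)))
  expect_lte(length(s1$idx), length(s1$raw))
})

test_that("cluster-count draws are uniform on [M, 3M]", {
  withr_seed(8)
  draws <- replicate(10000L, sample_cluster_count(7L))
  expect_true(all(draws >= 7L & draws <= 21L))
  p <- stats::chisq.test(table(factor(draws, levels = 7:21)))$p.value
  expect_gt(p, 1e-3)
  singles <- replicate(200L, sample_cluster_count(1L))
  expect_true(all(singles >= 1L & singles <= 3L))
})

test_that("k-means separates two point clouds and handles P = 1", {
  dm <- blob_matrix(n_per_class = 15L, n_classes = 2L, seed = 5L)
  withr_seed(1)
  cc <- subspace_kmeans(dm, P = 2L)
  expect_length(cc$clusters, 2L)
  sizes <- sort(vapply(cc$clusters, `[[`, integer(1), "n"))
  expect_equal(sizes, c(15L, 15L))
  for (cl in cc$clusters) {
    members <- dm$x[apply(dm$x, 1L, function(r)
      isTRUE(all.equal(euclidean_distance(r, cl$centroid),
                       min(vapply(cc$clusters, function(z)
                         euclidean_distance(r, z$centroid), numeric(1)))))),
      , drop = FALSE]
    expect_equal(cl$centroid, unname(colMeans(members)))
  }
  withr_seed(1)
  one <- subspace_kmeans(dm, P = 1L)
  expect_length(one$clusters, 1L)
  expect_equal(one$clusters[[1L]]$n, nrow(dm$x))
  expect_equal(one$clusters[[1L]]$centroid, unname(colMeans(dm$x)))
  expect_error(subspace_kmeans(dm, P = 100L), "cannot seed")
})

test_that("membership counts conserve instances and satisfy local optimality", {
  dm <- smarthome_binary(n = 80L, seed = 14L)
  for (seed in 1:20) {
    withr_seed(seed)
    subset <- sample_feature_subset(14L)
    P <- sample_cluster_count(7L)
    cc <- subspace_kmeans(dm, subset, min(P, nrow(dm$x)),
                          centroid_mode = "mode")
    ns <- vapply(cc$clusters, `[[`, integer(1), "n")
    expect_equal(sum(ns), nrow(dm$x))
    expect_true(all(ns >= 1L))
    for (cl in cc$clusters) {
      expect_equal(sum(cl$class_counts), cl$n)
      expect_true(all(cl$centroid %in% c(0, 1)))  # mode centroids are binary
    }
    # at convergence no instance is closer to another retained centroid
    cents <- do.call(rbind, lapply(cc$clusters, `[[`, "centroid"))
    d2 <- cbce:::cross_dist2(dm$x * 1.0, cents, cc$subset)
    own <- apply(d2, 1L, min)
    assigned <- max.col(-d2, ties.method = "first")
    counts <- table(factor(assigned, levels = seq_along(cc$clusters)))
    expect_equal(as.integer(counts), ns)
  }
})

test_that("tiny problems agree with an independent Lloyd oracle and brute force", {
  # independent naive Lloyd, plain loops, mean centroids, lowest-index ties
  naive_lloyd <- function(x, centers, idx, max_iter = 100L) {
    assign_prev <- rep(0L, nrow(x))
    for (it in seq_len(max_iter)) {
      assignment <- integer(nrow(x))
      for (i in seq_len(nrow(x))) {
        d <- sapply(seq_len(nrow(centers)), function(p)
          sum((x[i, idx] - centers[p, idx])^2))
        assignment[i] <- which.min(d)
      }
      if (identical(assignment, assign_prev)) break
      assign_prev <- assignment
      for (p in seq_len(nrow(centers))) {
        if (any(assignment == p)) {
          centers[p, ] <- colMeans(x[assignment == p, , drop = FALSE])
        }
      }
    }
    list(assignment = assignment, centers = centers)
  }
  wss <- function(x, assignment, idx) {
    sum(sapply(unique(assignment), function(p) {
      m <- x[assignment == p, idx, drop = FALSE]
      sum(sweep(m, 2L, colMeans(m))^2)
    }))
  }
  for (seed in 1:10) {
    withr_seed(seed)
    x <- matrix(sample(0:4, 8L * 3L, replace = TRUE), 8L, 3L)
    colnames(x) <- paste0("s", 1:3)
    dm <- cbce_matrix(x, rep(c("u", "v"), 4L), "numeric")
    idx <- sort(sample(1:3, sample(1:3, 1L)))
    withr_seed(seed + 100L)
    init <- sample.int(8L, 3L)
    withr_seed(seed + 100L)
    cc <- subspace_kmeans(dm, idx, 3L, centroid_mode = "mean")
    oracle <- naive_lloyd(x * 1.0, x[init, , drop = FALSE] * 1.0, idx)
    ours <- numeric(8L)
    cents <- do.call(rbind, lapply(cc$clusters, `[[`, "centroid"))
    d2 <- cbce:::cross_dist2(x * 1.0, cents, idx)
    ours <- max.col(-d2, ties.method = "first")
    expect_equal(wss(x, ours, idx), wss(x, oracle$assignment, idx))
    # Lloyd descends: converged WSS is no worse than the initial
    # assignment's, and no better than the brute-force global optimum
    d2_init <- cbce:::cross_dist2(x * 1.0, x[init, , drop = FALSE] * 1.0, idx)
    init_assign <- max.col(-d2_init, ties.method = "first")
    expect_lte(wss(x, ours, idx), wss(x, init_assign, idx) + 1e-9)
    grid <- expand.grid(rep(list(1:2), 8L))  # all 2-cluster partitions
    global_min <- min(apply(grid, 1L, function(a) wss(x, a, idx)))
    withr_seed(seed + 200L)
    cc2 <- subspace_kmeans(dm, idx, 2L, centroid_mode = "mean")
    cents2 <- do.call(rbind, lapply(cc2$clusters, `[[`, "centroid"))
    a2 <- max.col(-cbce:::cross_dist2(x * 1.0, cents2, idx),
                  ties.method = "first")
    expect_gte(wss(x, a2, idx), global_min - 1e-9)
  }
})

test_that("full-subset mean-centroid clustering matches stats::kmeans", {
  dm <- blob_matrix(n_per_class = 12L, n_classes = 3L, L = 3L, seed = 9L)
  withr_seed(3)
  init <- sample.int(nrow(dm$x), 3L)
  withr_seed(3)
  cc <- subspace_kmeans(dm, P = 3L, centroid_mode = "mean")
  ref <- stats::kmeans(dm$x, centers = dm$x[init, ], algorithm = "Lloyd",
                       iter.max = 100L)
  ours <- sort(vapply(cc$clusters, `[[`, integer(1), "n"))
  expect_equal(ours, sort(unname(ref$size)))
  cents <- do.call(rbind, lapply(cc$clusters, `[[`, "centroid"))
  expect_equal(sort(rowSums(cents)), sort(unname(rowSums(ref$centers))),
               tolerance = 1e-8)
})

test_that("clustering is bitwise reproducible under a fixed seed", {
  dm <- smarthome_binary(n = 60L, seed = 4L)
  run <- function() {
    withr_seed(77)
    subspace_kmeans(dm, sample_feature_subset(14L), 9L, "mode")
  }
  expect_identical(run(), run())
})
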