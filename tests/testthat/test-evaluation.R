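test_that("accuracy matches the published headline values for both encodings", {
  mn <- metrics_from_confusion(numeric_cm())
  mb <- metrics_from_confusion(binary_cm())
  expect_equal(round_half_up(100 * mn$accuracy, 1), 94.2)
  expect_equal(round_half_up(100 * mb$accuracy, 1), 97.5)
  expect_equal(mn$total, 240)
  expect_equal(mb$total, 240)
})

test_that("per-class metrics follow the row/column conventions", {
  m <- rbind(c(8L, 2L), c(0L, 10L))
  dimnames(m) <- list(predicted = c("a", "b"), actual = c("a", "b"))
  res <- metrics_from_confusion(m)
  expect_equal(res$per_class$precision, c(8 / 10, 1))
  expect_equal(res$per_class$recall, c(1, 10 / 12))
  expect_equal(res$accuracy, 18 / 20)
  ident <- diag(c(3L, 4L, 5L))
  res2 <- metrics_from_confusion(ident)
  expect_equal(res2$accuracy, 1)
  expect_equal(res2$per_class$f, rep(1, 3))
  # class never predicted: precision defined as 0, flagged
  m0 <- rbind(c(5L, 1L), c(0L, 0L))
  expect_warning(res3 <- metrics_from_confusion(m0), "never predicted")
  expect_equal(res3$per_class$precision[2L], 0)
  expect_equal(res3$per_class$f[2L], 0)
  expect_error(metrics_from_confusion(matrix(0, 2, 2)), "empty")
})

test_that("metric ranges hold on random matrices", {
  withr_seed(41)
  for (i in 1:25) {
    m <- matrix(stats::rpois(16L, 3), 4L, 4L)
    if (sum(m) == 0) m[1L, 1L] <- 1L
    res <- suppressWarnings(metrics_from_confusion(m))
    with(res, {
      expect_true(accuracy >= 0 && accuracy <= 1)
      expect_true(all(per_class$precision >= 0 & per_class$precision <= 1))
      expect_true(all(per_class$recall >= 0 & per_class$recall <= 1))
      expect_true(all(per_class$f >= 0 & per_class$f <= 1))
      expect_true(all(per_class$f[per_class$precision * per_class$recall == 0] == 0))
    })
  }
})

test_that("cross-validation partitions every instance exactly once", {
  dm <- smarthome_binary(n = 150L, seed = 44L)
  cv <- cross_validate(dm, folds = 5L, seed = 10L, K = 5L)
  expect_equal(sum(cv$confusion), nrow(dm$x))
  expect_equal(sort(unique(cv$fold)), 1:5)
  expect_length(cv$fold, nrow(dm$x))
  # stratification: each fold holds about 1/5 of the dominant class
  toilet_per_fold <- table(cv$fold[dm$labels == "use-toilet"])
  expect_lte(diff(range(toilet_per_fold)), 1L)
  # separable data scores essentially perfectly
  blobs <- blob_matrix(n_per_class = 25L, n_classes = 3L, L = 5L, seed = 51L)
  cvb <- cross_validate(blobs, folds = 5L, seed = 20L, K = 10L)
  expect_gte(cvb$mean_accuracy, 0.95)
})

test_that("label-shuffled balanced data scores at chance level", {
  dm <- blob_matrix(n_per_class = 30L, n_classes = 4L, L = 4L, seed = 66L)
  withr_seed(67)
  shuffled <- cbce_matrix(dm$x, sample(dm$labels), dm$encoding,
                          classes = dm$classes)
  cv <- cross_validate(shuffled, folds = 5L, seed = 30L, K = 10L)
  p <- 1 / 4
  sigma <- sqrt(p * (1 - p) / nrow(dm$x))
  expect_lt(abs(cv$metrics$accuracy - p), 3 * sigma + 1e-9)
})

test_that("small classes trigger the non-stratified fallback", {
  x <- matrix(sample(0:1, 40L, replace = TRUE), 20L, 2L)
  colnames(x) <- c("a", "b")
  dm <- cbce_matrix(x, c(rep("big", 18L), "rare", "rare"), "binary")
  expect_warning(cross_validate(dm, folds = 5L, seed = 1L, K = 2L),
                 "non-stratified")
})

test_that("Davies-Bouldin behaves at its limits and under symmetry", {
  withr_seed(71)
  tight <- rbind(matrix(stats::rnorm(60L, 0, 0.01), 30L, 2L),
                 matrix(stats::rnorm(60L, 100, 0.01), 30L, 2L))
  g <- rep(c("a", "b"), each = 30L)
  expect_lt(davies_bouldin(tight, g), 0.01)
  overlapping <- rbind(matrix(stats::rnorm(200L), 100L, 2L),
                       matrix(stats::rnorm(200L), 100L, 2L))
  expect_gt(davies_bouldin(overlapping, rep(c("a", "b"), each = 100L)), 1)
  # scale invariance and group-order invariance
  db1 <- davies_bouldin(tight, g)
  expect_equal(as.numeric(davies_bouldin(tight * 7, g)), as.numeric(db1))
  perm <- sample(nrow(tight))
  expect_equal(as.numeric(davies_bouldin(tight[perm, ], g[perm])),
               as.numeric(db1))
  same <- rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 1))
  expect_error(davies_bouldin(same, c("a", "a", "b", "b")), "coincident")
  expect_error(davies_bouldin(tight, rep("a", 60L)), "two groups")
})

test_that("stability declines with ensemble size on a quick probe", {
  dm <- smarthome_binary(n = 120L, seed = 80L)
  tab <- stability_experiment(dm, k_values = c(1L, 20L), repetitions = 12L,
                              seed = 5L)
  expect_equal(tab$K, c(1L, 20L))
  expect_lt(tab$sd_accuracy[2L], tab$sd_accuracy[1L])
  expect_true(all(tab$sd_accuracy >= 0))
})
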