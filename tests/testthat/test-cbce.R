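test_that("base-classifier training is reproducible and structurally sound", {
  dm <- smarthome_binary(n = 100L, seed = 6L)
  withr_seed(12)
  b1 <- train_base_classifier(dm)
  withr_seed(12)
  b2 <- train_base_classifier(dm)
  expect_identical(b1, b2)
  expect_equal(nrow(b1$support), length(b1$clusters))
  expect_true(all(b1$support >= -1 & b1$support <= 1))
})

test_that("separable two-class data yields the identity support pattern", {
  x <- rbind(matrix(c(1L, 0L), 10L, 2L, byrow = TRUE),
             matrix(c(0L, 1L), 10L, 2L, byrow = TRUE))
  colnames(x) <- c("sa", "sb")
  dm <- cbce_matrix(x, rep(c("u", "v"), each = 10L), "binary")
  withr_seed(2)
  cc <- subspace_kmeans(dm, 1:2, 2L, "mode")
  a <- compute_support_matrix(cc)
  expect_equal(sort(apply(a, 1L, max)), c(1, 1))
  expect_equal(sort(apply(a, 1L, min)), c(-1, -1))
  expect_equal(unname(apply(a, 2L, max)), c(1, 1))
})

test_that("support-matrix row invariants hold over many random trainings", {
  dm <- smarthome_binary(n = 90L, seed = 19L)
  for (seed in 1:100) {
    withr_seed(seed)
    bc <- train_base_classifier(dm)
    a <- bc$support
    expect_true(all(a >= -1 & a <= 1))
    expect_true(all(apply(a, 1L, function(r) any(r > -1))))
  }
})

test_that("ensembles train deterministically and record their metadata", {
  dm <- smarthome_binary(n = 120L, seed = 23L)
  f1 <- cbce(dm, K = 5L, seed = 99L)
  f2 <- cbce(dm, K = 5L, seed = 99L)
  expect_identical(f1, f2)
  expect_equal(f1$K, 5L)
  expect_equal(f1$majority_class, "use-toilet")
  expect_equal(f1$centroid_mode, "mode")  # auto-selected for binary data
  test <- smarthome_binary(n = 40L, seed = 71L)
  expect_identical(predict(f1, test), predict(f2, test))
  expect_error(cbce(dm, K = 5L), "seed")
})

test_that("nearest_cluster agrees with an exhaustive scan on random queries", {
  dm <- smarthome_binary(n = 100L, seed = 37L)
  fit <- cbce(dm, K = 4L, seed = 13L)
  withr_seed(55)
  for (q in 1:250) {
    x <- sample(0:1, 14L, replace = TRUE)
    for (bc in fit$classifiers) {
      got <- nearest_cluster(x, bc)
      d <- vapply(bc$clusters, function(cl)
        euclidean_distance(x, cl$centroid), numeric(1))
      expect_equal(got$cluster, which.min(d))
      expect_equal(got$distance, min(d))
    }
  }
})

test_that("excluded clusters contribute exactly zero support", {
  fit <- casestudy_ensemble()
  cs <- class_support(casestudy_instance(), fit)
  expect_equal(unname(cs$support[c("use-toilet", "get-drink", "leave-house")]),
               c(0, 0, 0))
  expect_true(all(cs$support >= 0))
  expect_true(all(cs$support <= fit$K * exp(1)))
  # trace covers one cluster per classifier
  expect_equal(nrow(cs$trace), fit$K)
})

test_that("fusion contributions move the right way with distance", {
  # positive support: closer means stronger; negative support: closer means
  # weaker (more confident exclusion)
  d <- seq(0, 5, by = 0.5)
  pos <- exp(0.8 / (1 + d))
  neg <- exp(-0.8 / (1 + d))
  expect_true(all(diff(pos) < 0))
  expect_true(all(diff(neg) > 0))
  # single classifier, zero support at zero distance contributes e^0 = 1
  expect_equal(exp(0 / (1 + 0)), 1)
})

test_that("prediction falls back to the majority class and breaks ties early", {
  fit <- casestudy_ensemble()
  expect_equal(predict(fit, casestudy_instance()), "prepare-dinner")
  sup <- predict(fit, casestudy_instance(), type = "support")
  expect_equal(colnames(sup), fit$classes)
  # an ensemble trained on a single class always answers that class
  x <- matrix(sample(0:1, 30L, replace = TRUE), 10L, 3L)
  colnames(x) <- paste0("s", 1:3)
  dm1 <- cbce_matrix(x, rep("only", 10L), "binary")
  f1 <- cbce(dm1, K = 3L, seed = 4L)
  expect_true(all(predict(f1, x) == "only"))
})

test_that("synthetic blob training reaches high training-set accuracy", {
  dm <- blob_matrix(n_per_class = 25L, n_classes = 3L, L = 5L, seed = 61L)
  fit <- cbce(dm, K = 30L, seed = 17L)
  expect_gte(mean(predict(fit, dm) == dm$labels), 0.95)
})

test_that("models survive a JSON round trip bit for bit", {
  dm <- smarthome_binary(n = 80L, seed = 29L)
  fit <- cbce(dm, K = 4L, seed = 3L)
  path <- withr::local_tempfile(fileext = ".json")
  save_cbce(fit, path)
  back <- load_cbce(path)
  expect_equal(back$classes, fit$classes)
  expect_equal(back$majority_class, fit$majority_class)
  for (k in seq_len(fit$K)) {
    expect_identical(back$classifiers[[k]]$support,
                     fit$classifiers[[k]]$support)
    expect_identical(back$classifiers[[k]]$clusters,
                     fit$classifiers[[k]]$clusters)
  }
  test <- smarthome_binary(n = 40L, seed = 83L)
  expect_identical(predict(back, test), predict(fit, test))
  expect_identical(predict(back, test, type = "support"),
                   predict(fit, test, type = "support"))
  expect_error(load_cbce(withr::local_tempfile(fileext = ".json",
                                               lines = "{\"a\": 1}")),
               "not a cbce model")
})
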