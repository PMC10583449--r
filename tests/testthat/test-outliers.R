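test_that("LOF scores isolate planted outliers", {
  set.seed(1)
  x <- rbind(matrix(rnorm(200 * 3), 200, 3),
             matrix(rnorm(3 * 3, mean = 8), 3, 3))
  s <- lof_scores(x, n_neighbors = 20)
  expect_true(all(s[201:203] > 3))
  expect_true(max(s[1:200]) < 3)
})

test_that("LOF scores duplicate clusters as ordinary and validates k", {
  xd <- matrix(1, 30, 2)
  expect_equal(lof_scores(xd, n_neighbors = 5), rep(1, 30))
  expect_error(lof_scores(xd[1:5, ], n_neighbors = 5), "smaller")
  expect_error(lof_scores(xd, n_neighbors = 0), ">= 1")
})

test_that("lof_flags standardizes descriptors and thresholds scores", {
  set.seed(2)
  # one wildly scaled column must not mask the outlier after standardizing
  x <- cbind(a = c(rnorm(100), 10), b = 1000 * c(rnorm(100), 10))
  fl <- lof_flags(x, n_neighbors = 15, threshold = 1.5)
  expect_true(fl$flagged[101])
  expect_equal(fl$flagged, fl$scores > 1.5)
})

test_that("group_ttests contrasts flagged vs rest with NA-safe columns", {
  set.seed(3)
  x <- cbind(signal = c(rnorm(40), rnorm(10, mean = 4)),
             noise = rnorm(50),
             constant = rep(2, 50))
  flagged <- c(rep(FALSE, 40), rep(TRUE, 10))
  tt <- group_ttests(x, flagged)
  expect_equal(tt$feature[1], "signal")
  expect_lt(tt$p_value[1], 1e-4)
  expect_true(is.na(tt$p_value[tt$feature == "constant"]))
  expect_equal(tt$mean_flagged[tt$feature == "constant"], 2)
  expect_error(group_ttests(x, rep(FALSE, 50)), "non-empty")
  expect_error(group_ttests(x, rep(TRUE, 50)), "non-empty")
})

test_that("refit_without_outliers retrains on inliers and reports deltas", {
  set.seed(4)
  n <- 150
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 * x[, 1] + rnorm(n, sd = 0.2)
  sp <- split_train_test(n, 0.8, 5)
  # corrupt a few training responses
  bad_local <- 1:5
  y[sp$train_idx[bad_local]] <- y[sp$train_idx[bad_local]] + 20
  flagged <- rep(FALSE, length(sp$train_idx))
  flagged[bad_local] <- TRUE
  res <- refit_without_outliers(x, y, sp, flagged, method = "mlr")
  expect_equal(res$n_removed, 5L)
  expect_equal(nrow(res$refit), 2L)
  # removing the corrupted rows must improve the untouched test partition
  expect_lt(res$delta$rmse, 0)
  expect_gt(res$delta$r2, 0)
  expect_error(refit_without_outliers(x, y, sp, rep(TRUE,
    length(sp$train_idx)), method = "mlr"), "fewer than 2")
})
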