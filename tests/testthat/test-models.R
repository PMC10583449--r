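test_that("split_train_test partitions deterministically", {
  sp <- split_train_test(100, fraction = 0.8, seed = 42)
  expect_equal(length(sp$train_idx), 80L)
  expect_equal(length(sp$test_idx), 20L)
  expect_equal(sort(c(sp$train_idx, sp$test_idx)), 1:100)
  sp2 <- split_train_test(100, fraction = 0.8, seed = 42)
  expect_identical(sp$train_idx, sp2$train_idx)
  sp3 <- split_train_test(100, fraction = 0.8, seed = 43)
  expect_false(identical(sp$train_idx, sp3$train_idx))
})

test_that("evaluate_metrics matches the hand-computed example", {
  m <- evaluate_metrics(c(1, 2, 3), c(1, 1, 3))
  expect_equal(m$mae, 1 / 3, tolerance = 1e-12)
  expect_equal(m$rmse, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(m$r2, 0.5, tolerance = 1e-12)
  expect_warning(m0 <- evaluate_metrics(c(1, 1, 1), c(1, 2, 1)),
                 "constant")
  expect_true(is.na(m0$r2))
  expect_error(evaluate_metrics(1:3, 1:2))
})

test_that("fit_solubility fits both model families with S3 methods", {
  set.seed(1)
  n <- 80
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("d", 1:4)))
  y <- 1 + 2 * x[, 1] - x[, 2] + rnorm(n, sd = 0.1)
  for (method in c("rf", "mlr")) {
    m <- fit_solubility(x, y, method = method, ntree = 60, seed = 5)
    expect_s3_class(m, "solubility_model")
    expect_length(predict(m, x), n)
    expect_length(residuals(m), n)
    expect_output(print(m), toupper(method))
    expect_no_error(summary(m))
  }
  mlr <- fit_solubility(x, y, method = "mlr")
  expect_true(is.numeric(coef(mlr)))
  rf <- fit_solubility(x, y, method = "rf", ntree = 30)
  expect_error(coef(rf), "shap_importance")
})

test_that("fit_solubility is deterministic under its seed", {
  set.seed(2)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("d", 1:4)))
  y <- rowSums(x) + rnorm(50, sd = 0.2)
  m1 <- fit_solubility(x, y, method = "rf", ntree = 40, seed = 7)
  m2 <- fit_solubility(x, y, method = "rf", ntree = 40, seed = 7)
  expect_identical(predict(m1, x), predict(m2, x))
})

test_that("MLR reports standardized coefficients and rejects p >= n", {
  set.seed(3)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 3 * x[, 1] + rnorm(100, sd = 0.01)
  m <- fit_solubility(x, y, method = "mlr")
  b <- coef(m)
  # standardized coefficient of a = 3 * sd(a)
  expect_equal(unname(b["a"]), 3 * sd(x[, 1]), tolerance = 0.02)

  xbig <- matrix(rnorm(10 * 12), 10, 12)
  expect_error(fit_solubility(xbig, rnorm(10), method = "mlr"),
               "rank deficiency")
})

test_that("predict checks and reorders feature names", {
  set.seed(4)
  x <- matrix(rnorm(120), 30, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rnorm(30)
  m <- fit_solubility(x, y, method = "mlr")
  shuffled <- x[, c(3, 1, 4, 2)]
  expect_equal(predict(m, shuffled), predict(m, x))
  wrong <- x
  colnames(wrong) <- paste0("g", 1:4)
  expect_error(predict(m, wrong), "feature mismatch")
})

test_that("evaluate_split reports both partitions", {
  set.seed(6)
  x <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- 2 * x[, 1] + rnorm(100, sd = 0.3)
  sp <- split_train_test(100, 0.8, 1)
  m <- fit_solubility(x[sp$train_idx, ], y[sp$train_idx], method = "mlr")
  tab <- evaluate_split(m, x, y, sp)
  expect_equal(tab$partition, c("train", "test"))
  expect_equal(tab$n, c(80L, 20L))
  expect_true(all(tab$r2 > 0.5))
})
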