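test_that("TreeSHAP satisfies local accuracy on a random forest", {
  set.seed(7)
  n <- 120
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- 2 * x[, 1] - 1.5 * x[, 2] + 0.5 * x[, 3] * x[, 4] +
    rnorm(n, sd = 0.2)
  m <- fit_solubility(x, y, method = "rf", ntree = 40, seed = 3)
  sv <- shap_importance(m)
  pred <- predict(m, sv$x)
  expect_lt(max(abs(sv$base_value + rowSums(sv$phi) - pred)), 1e-8)
  # informative features rank above noise, with the planted signs
  imp <- sv$importance
  expect_setequal(imp$feature[1:2], c("f1", "f2"))
  expect_equal(imp$direction[imp$feature == "f1"], 1)
  expect_equal(imp$direction[imp$feature == "f2"], -1)
})

test_that("TreeSHAP agrees with the brute-force Shapley oracle", {
  set.seed(5)
  n <- 90
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- x[, 1] - 2 * x[, 3] + rnorm(n, sd = 0.1)
  rf <- aquasol:::.with_seed(11, function()
    randomForest::randomForest(x, y, ntree = 5, maxnodes = 8,
                               keep.inbag = TRUE))
  for (k in 1:5) {
    tr <- randomForest::getTree(rf, k)
    ld <- as.integer(tr[, "left daughter"]) - 1L
    rd <- as.integer(tr[, "right daughter"]) - 1L
    var <- as.integer(tr[, "split var"]) - 1L
    split <- as.numeric(tr[, "split point"])
    value <- as.numeric(tr[, "prediction"])
    cover <- aquasol:::cpp_node_cover(ld, rd, var, split, x,
                                      as.numeric(rf$inbag[, k]))
    res <- aquasol:::cpp_tree_shap(ld, rd, var, split, value, cover,
                                   x[1:4, , drop = FALSE])
    for (i in 1:4) {
      phi <- oracle_tree_shapley(ld, rd, var, split, value, cover, x[i, ])
      expect_equal(unname(res$phi[i, ]), phi, tolerance = 1e-10)
    }
  }
})

test_that("per-tree routing matches randomForest's own prediction", {
  set.seed(8)
  x <- matrix(rnorm(300), 75, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rowSums(x) + rnorm(75, sd = 0.1)
  m <- fit_solubility(x, y, method = "rf", ntree = 25, seed = 2)
  preds <- sapply(seq_len(m$ntree), function(k) {
    tr <- randomForest::getTree(m$fit, k)
    aquasol:::cpp_tree_predict(
      as.integer(tr[, 1]) - 1L, as.integer(tr[, 2]) - 1L,
      as.integer(tr[, 3]) - 1L, as.numeric(tr[, 4]),
      as.numeric(tr[, 6]), x)
  })
  expect_equal(unname(rowMeans(preds)), predict(m, x), tolerance = 1e-12)
})

test_that("shap_importance subsamples deterministically and validates", {
  set.seed(9)
  x <- matrix(rnorm(240), 60, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- x[, 1] + rnorm(60, sd = 0.1)
  m <- fit_solubility(x, y, method = "rf", ntree = 20, seed = 1)
  s1 <- shap_importance(m, max_rows = 10, seed = 4)
  s2 <- shap_importance(m, max_rows = 10, seed = 4)
  expect_identical(s1$phi, s2$phi)
  expect_equal(nrow(s1$phi), 10L)

  mlr <- fit_solubility(x, y, method = "mlr")
  expect_error(shap_importance(mlr), "random forest")
})

test_that("coefficient_report ranks standardized coefficients", {
  set.seed(10)
  x <- matrix(rnorm(500), 100, 5, dimnames = list(NULL, paste0("d", 1:5)))
  y <- 4 * x[, 2] - 2 * x[, 4] + rnorm(100, sd = 0.1)
  m <- fit_solubility(x, y, method = "mlr")
  rep <- coefficient_report(m)
  expect_equal(rep$feature[1:2], c("d2", "d4"))
  expect_equal(rep$direction[1:2], c(1, -1))
  expect_equal(nrow(coefficient_report(m, top_k = 3)), 3L)
  rf <- fit_solubility(x, y, method = "rf", ntree = 20)
  expect_error(coefficient_report(rf), "MLR")
})
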