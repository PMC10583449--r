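# Model fitting and evaluation: an 80/20 random split, random forest and
# multiple linear regression on either chemical representation, and the
# MAE/RMSE/R2 metrics reported per partition.

#' Random train/test split
#'
#' Uniform random partition of row indices, deterministic under `seed`.
#' `|train| = round(fraction * n)`.
#'
#' @param n_rows number of rows.
#' @param fraction training share (default 0.8).
#' @param seed integer seed.
#' @return list of class `"split_indices"` with `train_idx`, `test_idx`,
#'   `fraction`, `seed`.
#' @export
split_train_test <- function(n_rows, fraction = 0.8, seed = 42L) {
  stopifnot(n_rows >= 0, fraction >= 0, fraction <= 1)
  n_train <- round(fraction * n_rows)
  train <- .with_seed(seed, function() sort(sample(n_rows, n_train)))
  structure(list(train_idx = train,
                 test_idx = setdiff(seq_len(n_rows), train),
                 fraction = fraction, seed = as.integer(seed)),
            class = "split_indices")
}

#' @export
print.split_indices <- function(x, ...) {
  cat(sprintf("<split_indices> %d train / %d test (fraction %.2f, seed %d)\n",
              length(x$train_idx), length(x$test_idx), x$fraction, x$seed))
  invisible(x)
}

#' Fit a solubility regression model
#'
#' The package's central fitting function: a regression of logS on a
#' feature matrix (molecular descriptors or fingerprint bits) by either
#' random forest (`"rf"`) or multiple linear regression (`"mlr"`).
#'
#' For `"mlr"` the features are standardized internally (zero mean, unit
#' variance on the training data; zero-variance columns are dropped from
#' the fit) and coefficients are reported on the standardized scale, so
#' their magnitudes are comparable across features. `p >= n` without
#' regularization is a rank-deficiency error. For `"rf"` the features are
#' used unscaled; hyperparameters default to 500 trees with unlimited
#' depth and the implementation's default feature subsampling, and are
#' held constant across representation comparisons.
#'
#' @param x numeric feature matrix (rows = molecules).
#' @param y numeric logS vector aligned with the rows of `x`.
#' @param method `"rf"` or `"mlr"`.
#' @param ntree number of random forest trees (default 500).
#' @param seed integer seed for the forest's randomness.
#' @param representation optional label ("descriptors"/"fingerprints"),
#'   carried into printouts.
#' @return object of class `"solubility_model"` with `predict`, `coef`,
#'   `residuals`, `print`, `summary` and `plot` methods.
#' @export
fit_solubility <- function(x, y, method = c("rf", "mlr"), ntree = 500L,
                           seed = 42L, representation = NULL) {
  method <- match.arg(method)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stopifnot(nrow(x) == length(y), is.numeric(y))
  if (nrow(x) < 2L) stop("need at least 2 training rows", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))

  fit <- switch(method,
    rf = .fit_rf(x, y, ntree, seed),
    mlr = .fit_mlr(x, y))
  obj <- c(fit, list(method = method, feature_names = colnames(x),
                     n = nrow(x), p = ncol(x), x = x, y = y, seed = seed,
                     representation = representation))
  class(obj) <- "solubility_model"
  obj
}

.fit_rf <- function(x, y, ntree, seed) {
  rf <- .with_seed(seed, function()
    randomForest::randomForest(x, y, ntree = ntree, keep.inbag = TRUE))
  list(fit = rf, ntree = ntree)
}

.fit_mlr <- function(x, y) {
  mu <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  use <- s > 0
  xs <- scale(x[, use, drop = FALSE], center = mu[use], scale = s[use])
  if (ncol(xs) >= nrow(xs))
    stop("rank deficiency: p >= n for unregularized linear regression",
         call. = FALSE)
  df <- data.frame(y = y, xs, check.names = FALSE)
  lmfit <- stats::lm(y ~ ., data = df)
  # columns aliased with earlier ones get NA coefficients; drop them and
  # refit so prediction is well-defined
  aliased <- is.na(stats::coef(lmfit)[-1L])
  if (any(aliased)) {
    use[which(use)[aliased]] <- FALSE
    xs <- xs[, !aliased, drop = FALSE]
    df <- data.frame(y = y, xs, check.names = FALSE)
    lmfit <- stats::lm(y ~ ., data = df)
  }
  list(fit = lmfit, center = mu, scale = s, used = use)
}

#' @export
predict.solubility_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (!identical(colnames(x), object$feature_names)) {
    if (is.null(colnames(x)) && ncol(x) == object$p)
      colnames(x) <- object$feature_names
    else if (all(object$feature_names %in% colnames(x)))
      x <- x[, object$feature_names, drop = FALSE]
    else stop("feature mismatch between model and newdata", call. = FALSE)
  }
  if (object$method == "rf") {
    unname(stats::predict(object$fit, x))
  } else {
    use <- object$used
    xs <- scale(x[, use, drop = FALSE], center = object$center[use],
                scale = object$scale[use])
    unname(stats::predict(object$fit,
                          newdata = as.data.frame(xs, check.names = FALSE)))
  }
}

#' @export
coef.solubility_model <- function(object, ...) {
  if (object$method != "mlr")
    stop("coefficients are defined for the MLR model; use shap_importance()",
         " for the random forest", call. = FALSE)
  stats::coef(object$fit)
}

#' @export
residuals.solubility_model <- function(object, ...) {
  if (object$method == "rf") object$y - stats::predict(object$fit)
  else stats::residuals(object$fit)
}

#' @export
print.solubility_model <- function(x, ...) {
  cat(sprintf("<solubility_model> %s on %d molecules x %d features%s\n",
              toupper(x$method), x$n, x$p,
              if (!is.null(x$representation))
                paste0(" (", x$representation, ")") else ""))
  invisible(x)
}

#' @export
summary.solubility_model <- function(object, ...) {
  yhat <- if (object$method == "rf") stats::predict(object$fit)
          else stats::fitted(object$fit)
  m <- evaluate_metrics(object$y, yhat, partition = "train")
  cat(sprintf("%s solubility model, %d molecules, %d features\n",
              toupper(object$method), object$n, object$p))
  cat(sprintf("  training fit%s: R2 = %.3f, RMSE = %.3f, MAE = %.3f\n",
              if (object$method == "rf") " (out-of-bag)" else "",
              m$r2, m$rmse, m$mae))
  invisible(m)
}

#' @export
plot.solubility_model <- function(x, newdata = NULL, newy = NULL, ...) {
  if (is.null(newdata)) {
    yhat <- if (x$method == "rf") stats::predict(x$fit) else stats::fitted(x$fit)
    y <- x$y
    lab <- "training"
  } else {
    yhat <- predict(x, newdata)
    y <- newy
    lab <- "test"
  }
  graphics::plot(y, yhat, xlab = "observed logS", ylab = "predicted logS",
                 main = sprintf("%s (%s)", toupper(x$method), lab), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(NULL)
}

#' Regression metrics for a partition
#'
#' `MAE = mean |yhat - y|`, `RMSE = sqrt(mean (yhat - y)^2)`,
#' `R2 = 1 - SSres/SStot`. With constant observed values R2 is undefined
#' and reported as NA with a warning.
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @param partition label, e.g. "train" or "test".
#' @return object of class `"model_metrics"`: list `r2`, `rmse`, `mae`,
#'   `partition`, `n`.
#' @examples
#' evaluate_metrics(c(1, 2, 3), c(1, 1, 3))
#' @export
evaluate_metrics <- function(y, yhat, partition = "test") {
  stopifnot(length(y) == length(yhat), length(y) > 0)
  err <- yhat - y
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot == 0) {
    warning("constant observed values: R2 undefined", call. = FALSE)
    NA_real_
  } else 1 - sum(err^2) / sstot
  structure(list(r2 = r2, rmse = rmse, mae = mae, partition = partition,
                 n = length(y)), class = "model_metrics")
}

#' @export
print.model_metrics <- function(x, ...) {
  cat(sprintf("%s (n=%d): R2 = %s, RMSE = %.4f, MAE = %.4f\n",
              x$partition, x$n,
              if (is.na(x$r2)) "NA" else sprintf("%.4f", x$r2),
              x$rmse, x$mae))
  invisible(x)
}

#' Evaluate a fitted model on both partitions
#'
#' Computes the train/test metric pair reported per (model,
#' representation) combination.
#'
#' @param model a `solubility_model`.
#' @param x full feature matrix.
#' @param y full logS vector.
#' @param split a `split_indices`.
#' @return data.frame with one row per partition: `partition, n, r2, rmse,
#'   mae`.
#' @export
evaluate_split <- function(model, x, y, split) {
  stopifnot(inherits(split, "split_indices"))
  rows <- list(train = split$train_idx, test = split$test_idx)
  out <- lapply(names(rows), function(part) {
    idx <- rows[[part]]
    m <- evaluate_metrics(y[idx], predict(model, x[idx, , drop = FALSE]),
                          partition = part)
    data.frame(partition = part, n = m$n, r2 = m$r2, rmse = m$rmse,
               mae = m$mae, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
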