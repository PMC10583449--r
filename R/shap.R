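# Model interpretation: exact TreeSHAP attributions for the random forest
# and standardized-coefficient reports for the linear model. Both report a
# ranked feature table with a direction of effect, so the two model
# families can be read side by side.

#' SHAP values for a random forest solubility model
#'
#' Exact path-dependent TreeSHAP over every tree of the forest, using the
#' in-bag counts stored at fit time to weight the training rows when
#' computing per-node covers. For each explained row the local-accuracy
#' identity `base_value + rowSums(phi) == predict(model, x)` holds to
#' floating-point precision.
#'
#' @param model a `solubility_model` fitted with `method = "rf"`.
#' @param x rows to explain; defaults to the training matrix. If it has
#'   more than `max_rows` rows a deterministic subsample (under `seed`) is
#'   explained instead.
#' @param max_rows cap on the number of explained rows (default 2000).
#' @param seed seed for the subsample.
#' @return object of class `"shap_values"`: list with `phi` (rows x
#'   features matrix of attributions), `base_value`, `x` (the explained
#'   rows), `importance` (data.frame ranked by mean |SHAP| with a
#'   `direction` column, the sign of the correlation between feature value
#'   and its SHAP value).
#' @export
shap_importance <- function(model, x = NULL, max_rows = 2000L, seed = 1L) {
  stopifnot(inherits(model, "solubility_model"))
  if (model$method != "rf")
    stop("shap_importance() explains the random forest; use coef() / ",
         "coefficient_report() for the MLR model", call. = FALSE)
  xtrain <- model$x
  if (is.null(x)) x <- xtrain
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x)) && ncol(x) == model$p)
    colnames(x) <- model$feature_names
  stopifnot(identical(colnames(x), model$feature_names))
  if (nrow(x) > max_rows) {
    keep <- .with_seed(seed, function() sort(sample(nrow(x), max_rows)))
    x <- x[keep, , drop = FALSE]
  }

  rf <- model$fit
  inbag <- rf$inbag
  ntree <- rf$ntree
  phi <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  base <- 0
  for (k in seq_len(ntree)) {
    tr <- randomForest::getTree(rf, k, labelVar = FALSE)
    ld <- as.integer(tr[, "left daughter"]) - 1L   # 0-based; leaf -> -1
    rd <- as.integer(tr[, "right daughter"]) - 1L
    var <- as.integer(tr[, "split var"]) - 1L
    split <- as.numeric(tr[, "split point"])
    value <- as.numeric(tr[, "prediction"])
    cover <- cpp_node_cover(ld, rd, var, split, xtrain,
                            as.numeric(inbag[, k]))
    res <- cpp_tree_shap(ld, rd, var, split, value, cover, x)
    phi <- phi + res$phi
    base <- base + res$base
  }
  phi <- phi / ntree
  base <- base / ntree

  mean_abs <- colMeans(abs(phi))
  direction <- vapply(seq_len(ncol(phi)), function(j) {
    if (stats::sd(x[, j]) == 0 || stats::sd(phi[, j]) == 0) return(0)
    sign(stats::cor(x[, j], phi[, j]))
  }, numeric(1))
  ord <- order(mean_abs, decreasing = TRUE)
  importance <- data.frame(feature = colnames(phi)[ord],
                           mean_abs_shap = unname(mean_abs[ord]),
                           direction = direction[ord],
                           stringsAsFactors = FALSE)
  structure(list(phi = phi, base_value = base, x = x,
                 importance = importance),
            class = "shap_values")
}

#' @export
print.shap_values <- function(x, n = 10L, ...) {
  cat(sprintf("<shap_values> %d rows x %d features, base value %.4f\n",
              nrow(x$phi), ncol(x$phi), x$base_value))
  print(utils::head(x$importance, n))
  invisible(x)
}

#' @export
plot.shap_values <- function(x, n = 15L, ...) {
  imp <- utils::head(x$importance, n)
  graphics::barplot(rev(imp$mean_abs_shap), names.arg = rev(imp$feature),
                    horiz = TRUE, las = 1, xlab = "mean |SHAP|",
                    main = "SHAP feature importance", ...)
  invisible(NULL)
}

#' Ranked coefficient report for the linear model
#'
#' Because `fit_solubility(..., method = "mlr")` standardizes features
#' internally, coefficient magnitudes are directly comparable; this ranks
#' them by |coefficient| with the sign as the direction of effect.
#'
#' @param model a `solubility_model` fitted with `method = "mlr"`.
#' @param top_k number of rows to return (default all).
#' @return data.frame `feature, coefficient, direction` ranked by
#'   |coefficient|, excluding the intercept.
#' @export
coefficient_report <- function(model, top_k = NULL) {
  stopifnot(inherits(model, "solubility_model"))
  if (model$method != "mlr")
    stop("coefficient_report() is for the MLR model; use shap_importance()",
         " for the random forest", call. = FALSE)
  b <- stats::coef(model$fit)
  b <- b[names(b) != "(Intercept)"]
  b[is.na(b)] <- 0
  names(b) <- gsub("^`|`$", "", names(b))
  ord <- order(abs(b), decreasing = TRUE)
  out <- data.frame(feature = names(b)[ord], coefficient = unname(b[ord]),
                    direction = sign(unname(b[ord])),
                    stringsAsFactors = FALSE)
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}

# Brute-force Shapley values of a single tree by subset enumeration, used
# as an independent oracle in the test suite. Conditional expectation of a
# feature subset S follows the cover-proportion recursion: at a split on a
# feature outside S, descend both children weighted by cover.
.shapley_oracle_tree <- function(ld, rd, var, split, value, cover, xrow) {
  p <- length(xrow)
  expvalue <- function(node, inS) {
    if (ld[node] < 0L) return(value[node])
    f <- var[node] + 1L
    l <- ld[node] + 1L; r <- rd[node] + 1L
    if (inS[f]) {
      if (xrow[f] <= split[node]) expvalue(l, inS) else expvalue(r, inS)
    } else {
      (cover[l] * expvalue(l, inS) + cover[r] * expvalue(r, inS)) /
        cover[node]
    }
  }
  phi <- numeric(p)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  for (j in seq_len(p)) {
    for (s in seq_len(nrow(subsets))) {
      inS <- as.logical(subsets[s, ])
      if (inS[j]) next
      k <- sum(inS)
      w <- factorial(k) * factorial(p - k - 1) / factorial(p)
      withj <- inS; withj[j] <- TRUE
      phi[j] <- phi[j] +
        w * (expvalue(1L, withj) - expvalue(1L, inS))
    }
  }
  phi
}

# 1-based node indexing convenience for the oracle: convert a getTree
# matrix into the 0-based arrays used by the C++ routines.
.tree_arrays <- function(rf, k) {
  tr <- randomForest::getTree(rf, k, labelVar = FALSE)
  list(ld = as.integer(tr[, "left daughter"]) - 1L,
       rd = as.integer(tr[, "right daughter"]) - 1L,
       var = as.integer(tr[, "split var"]) - 1L,
       split = as.numeric(tr[, "split point"]),
       value = as.numeric(tr[, "prediction"]))
}
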