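# Outlier diagnostics: local outlier factor (LOF) on the training-set
# representation, Welch t-tests contrasting flagged vs unflagged molecules
# per feature, rare-bit ratios for fingerprint rows, and a refit that
# quantifies how much the flagged molecules were distorting the model.

#' Local outlier factor scores
#'
#' Classic LOF (density-based, k-nearest-neighbour) computed from scratch
#' on a numeric matrix with Euclidean distances. For each point, reach-
#' ability distances against its k nearest neighbours give a local
#' reachability density; the LOF score is the mean ratio of the neigh-
#' bours' densities to the point's own. Scores near 1 mean the point sits
#' at the same density as its neighbourhood; scores well above 1 flag
#' isolated points.
#'
#' Ties at the k-th neighbour distance are all included (standard LOF
#' definition), and duplicated points with zero neighbourhood distance get
#' infinite density; the ratio of two infinite densities is taken as 1 so
#' clusters of exact duplicates are scored as perfectly ordinary.
#'
#' @param x numeric matrix (rows = molecules). For descriptor inputs,
#'   standardize columns beforehand (see [lof_flags()]).
#' @param n_neighbors neighbourhood size k (default 20); must be smaller
#'   than the number of rows.
#' @return numeric vector of LOF scores, one per row.
#' @export
lof_scores <- function(x, n_neighbors = 20L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  k <- as.integer(n_neighbors)
  if (k < 1L) stop("n_neighbors must be >= 1", call. = FALSE)
  if (k >= n)
    stop(sprintf("n_neighbors (%d) must be smaller than the number of rows (%d)",
                 k, n), call. = FALSE)

  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  # k-distance and neighbourhood (including ties at the k-th distance)
  kdist <- numeric(n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    kd <- sort(di, partial = k)[k]
    kdist[i] <- kd
    nbrs[[i]] <- which(di <= kd)
  }
  # local reachability density
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    nb <- nbrs[[i]]
    reach <- pmax(kdist[nb], d[i, nb])
    m <- mean(reach)
    lrd[i] <- if (m == 0) Inf else 1 / m
  }
  # LOF = mean neighbour density / own density
  scores <- numeric(n)
  for (i in seq_len(n)) {
    nb <- nbrs[[i]]
    ratio <- lrd[nb] / lrd[i]
    ratio[is.nan(ratio)] <- 1  # Inf/Inf: duplicate clusters
    scores[i] <- mean(ratio)
  }
  scores
}

#' Flag outliers in the training partition by LOF
#'
#' Standardizes descriptor columns (zero-variance columns are left
#' untouched at zero), computes LOF scores on the training rows only, and
#' flags rows whose score exceeds `threshold`. Fingerprint bit matrices
#' should be passed raw (`standardize = FALSE`), since 0/1 columns are
#' already on a common scale.
#'
#' @param x numeric feature matrix for the training partition.
#' @param n_neighbors LOF neighbourhood size (default 20).
#' @param threshold LOF score above which a row is flagged (default 1.5).
#' @param standardize center/scale the columns first (default TRUE; use
#'   FALSE for binary fingerprints).
#' @return object of class `"lof_result"`: list with `scores`, `flagged`
#'   (logical), `threshold`, `n_neighbors`.
#' @export
lof_flags <- function(x, n_neighbors = 20L, threshold = 1.5,
                      standardize = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (standardize) {
    s <- apply(x, 2, stats::sd)
    s[s == 0] <- 1
    x <- scale(x, center = TRUE, scale = s)
  }
  scores <- lof_scores(x, n_neighbors = n_neighbors)
  structure(list(scores = scores, flagged = scores > threshold,
                 threshold = threshold,
                 n_neighbors = as.integer(n_neighbors)),
            class = "lof_result")
}

#' @export
print.lof_result <- function(x, ...) {
  cat(sprintf("<lof_result> %d/%d rows flagged (k = %d, threshold %.2f)\n",
              sum(x$flagged), length(x$flagged), x$n_neighbors, x$threshold))
  invisible(x)
}

#' Per-feature Welch t-tests: flagged vs unflagged molecules
#'
#' For every feature column, a two-sample Welch t-test contrasting the
#' flagged group against the rest. Features that are constant within both
#' groups (or have too few observations) get NA statistics rather than an
#' error.
#'
#' @param x numeric feature matrix.
#' @param flagged logical vector, one entry per row.
#' @return data.frame `feature, mean_flagged, mean_rest, t_statistic,
#'   p_value` sorted by p-value (NAs last).
#' @export
group_ttests <- function(x, flagged) {
  x <- as.matrix(x)
  stopifnot(is.logical(flagged), length(flagged) == nrow(x))
  if (!any(flagged) || all(flagged))
    stop("both groups must be non-empty for a two-sample test",
         call. = FALSE)
  res <- lapply(seq_len(ncol(x)), function(j) {
    a <- x[flagged, j]
    b <- x[!flagged, j]
    tt <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
    data.frame(feature = colnames(x)[j],
               mean_flagged = mean(a), mean_rest = mean(b),
               t_statistic = if (is.null(tt)) NA_real_
                             else unname(tt$statistic),
               p_value = if (is.null(tt)) NA_real_ else tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$t_statistic[is.nan(out$t_statistic)] <- NA_real_
  out$p_value[is.nan(out$p_value)] <- NA_real_
  out <- out[order(out$p_value, na.last = TRUE), ]
  rownames(out) <- NULL
  out
}

#' Refit without flagged outliers and report the metric change
#'
#' Retrains the same model on the unflagged training rows only, then
#' evaluates both the original and the refitted model on the untouched
#' test partition, reporting the metric deltas (refit minus original).
#'
#' @param x full feature matrix.
#' @param y full logS vector.
#' @param split a `split_indices` over the rows of `x`.
#' @param flagged logical over the *training* rows (same order as
#'   `split$train_idx`).
#' @param method,ntree,seed passed to [fit_solubility()].
#' @return list with `original` and `refit` metric data.frames (per
#'   partition; refit's "train" partition is the inlier rows it saw),
#'   `delta` (test-partition refit minus original for r2/rmse/mae),
#'   `n_removed`, and the two models.
#' @export
refit_without_outliers <- function(x, y, split, flagged,
                                   method = c("rf", "mlr"), ntree = 500L,
                                   seed = 42L) {
  method <- match.arg(method)
  stopifnot(inherits(split, "split_indices"),
            length(flagged) == length(split$train_idx))
  x <- as.matrix(x)
  tr <- split$train_idx
  te <- split$test_idx
  keep <- tr[!flagged]
  if (length(keep) < 2L)
    stop("removing the flagged rows leaves fewer than 2 training rows",
         call. = FALSE)

  orig <- fit_solubility(x[tr, , drop = FALSE], y[tr], method = method,
                         ntree = ntree, seed = seed)
  refit <- fit_solubility(x[keep, , drop = FALSE], y[keep], method = method,
                          ntree = ntree, seed = seed)

  eval_on <- function(model, train_rows) {
    rbind(
      data.frame(partition = "train",
                 n = length(train_rows),
                 as.data.frame(unclass(evaluate_metrics(
                   y[train_rows],
                   predict(model, x[train_rows, , drop = FALSE]),
                   "train"))[c("r2", "rmse", "mae")]),
                 stringsAsFactors = FALSE),
      data.frame(partition = "test",
                 n = length(te),
                 as.data.frame(unclass(evaluate_metrics(
                   y[te], predict(model, x[te, , drop = FALSE]),
                   "test"))[c("r2", "rmse", "mae")]),
                 stringsAsFactors = FALSE))
  }
  m_orig <- eval_on(orig, tr)
  m_refit <- eval_on(refit, keep)
  d_o <- m_orig[m_orig$partition == "test", c("r2", "rmse", "mae")]
  d_r <- m_refit[m_refit$partition == "test", c("r2", "rmse", "mae")]
  list(original = m_orig, refit = m_refit,
       delta = as.list(d_r - d_o),
       n_removed = sum(flagged),
       model_original = orig, model_refit = refit)
}
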