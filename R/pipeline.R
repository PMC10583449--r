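# End-to-end orchestration: a run configuration object that round-trips
# through a flat key=value file, and run_pipeline(), which executes
# curate -> profile -> featurize -> train -> interpret -> diagnose and
# writes every report table (tagged with the config hash) into a run
# directory. evaluate_blind() scores fitted models on held-out molecules
# after asserting training/blind disjointness.

# keys of a run configuration, in serialization order, with their types
.config_template <- function() {
  list(
    split_fraction = 0.8, split_seed = 42L,
    conflict_tolerance = 0.01,
    variance_threshold = 0.1, correlation_cutoff = 0.95,
    excluded_descriptors = "ESOL_logS",
    fp_radius = 2L, fp_bits = 2048L,
    lasso_alpha_grid = c(1e-5, 1e-4, 1e-3, 1e-2, 0.1, 1, 10),
    lasso_alpha = 0.001,
    rf_ntree = 500L, rf_seed = 42L,
    lof_neighbors = 20L, lof_threshold = 1.5,
    rare_threshold = 100L,
    shap_max_rows = 2000L, shap_seed = 1L,
    top_fragments = 10L,
    output_dir = "solubility_run"
  )
}

#' Create a run configuration
#'
#' All tunable quantities of the pipeline in one object: split fraction
#' and seed, curation tolerance, descriptor-cascade thresholds,
#' fingerprint radius/width, LASSO grid and chosen penalty, random-forest
#' hyperparameters and seed, LOF parameters, rare-bit threshold, SHAP
#' sample size and seed, and the output directory. Every stochastic stage
#' has an explicit seed. Defaults are the package's documented choices.
#'
#' @param ... named overrides of the default fields (unknown names are an
#'   error).
#' @return object of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- .config_template()
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    stop("unknown config fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (k in names(dots)) {
    v <- dots[[k]]
    mode <- storage.mode(cfg[[k]])
    storage.mode(v) <- if (mode == "integer") "integer" else mode
    cfg[[k]] <- v
  }
  stopifnot(cfg$split_fraction > 0, cfg$split_fraction < 1,
            cfg$fp_bits >= 2, cfg$rf_ntree >= 1,
            cfg$variance_threshold >= 0,
            cfg$correlation_cutoff > 0, cfg$correlation_cutoff <= 1)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> hash", config_hash(x), "\n")
  for (line in .config_lines(x)) cat(" ", line, "\n")
  invisible(x)
}

.config_lines <- function(config) {
  vapply(names(.config_template()), function(k)
    paste0(k, " = ", paste(as.character(config[[k]]), collapse = ",")),
    "")
}

#' Write / read a run configuration
#'
#' Flat `key = value` text format (vector values comma-separated). The
#' round trip `read_run_config(write_run_config(cfg, path))` returns a
#' configuration identical to `cfg`.
#'
#' @param config a `run_config`.
#' @param path text file path.
#' @return `path` invisibly (write); a `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  writeLines(.config_lines(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  tmpl <- .config_template()
  cfg <- list()
  for (line in lines) {
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    k <- trimws(kv[1])
    if (!k %in% names(tmpl))
      stop("unknown config key in file: ", k, call. = FALSE)
    raw <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(raw, ",", fixed = TRUE)[[1]])
    cfg[[k]] <- if (is.character(tmpl[[k]])) parts
                else if (is.integer(tmpl[[k]])) as.integer(parts)
                else as.numeric(parts)
  }
  do.call(run_config, cfg)
}

#' Hash of a run configuration
#'
#' Deterministic 8-hex-digit digest of the serialized configuration,
#' stamped on every emitted table so any output file can be traced to the
#' exact settings that produced it.
#'
#' @param config a `run_config`.
#' @return character scalar, eight hex digits.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "run_config"))
  txt <- paste(.config_lines(config), collapse = "\n")
  # polynomial rolling hash mod 2^31 - 1; all intermediates < 2^36, exact
  # in doubles
  h <- 17
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# ---- orchestration ----------------------------------------------------------

#' Run the full solubility study
#'
#' Executes the whole pipeline on a raw molecule table: curation ->
#' dataset profile -> descriptor engine + pruning cascade -> Morgan
#' fingerprints + LASSO bit selection -> a shared random train/test split
#' -> four models (RF and MLR on each representation) with per-partition
#' metrics -> SHAP and coefficient importance reports -> LOF outlier
#' diagnostics with per-feature Welch t-tests, rare-bit ratios, and a
#' refit without the flagged molecules -> fragment Gibbs-energy table for
#' the top SHAP-ranked fingerprint bits. All tables are written into
#' `config$output_dir`, each carrying the config hash, and a timestamped
#' log records the hash, the seeds, and row/column counts after every
#' stage. Any stage failure aborts with the stage name in the error.
#'
#' @param records raw molecule data.frame (`smiles`, `logS`, optional
#'   `source`) or a CSV path readable by [read_molecule_table()].
#' @param config a [run_config()].
#' @return object of class `"pipeline_run"`: the config and its hash, the
#'   run directory, curated dataset, profile, split, fitted models (named
#'   list), metrics table, importance reports, outlier diagnostics, bit
#'   selection and fragment thermodynamics.
#' @export
run_pipeline <- function(records, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(records) && length(records) == 1L)
    records <- read_molecule_table(records)
  hash <- config_hash(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$output_dir, "log.txt")
  cat(sprintf("[%s] run start, config hash %s\n",
              format(Sys.time()), hash), file = logfile)
  log_line <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time()), sprintf(fmt, ...))
    cat(line, "\n", file = logfile, append = TRUE, sep = "")
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  stamp <- function(df) {
    df$config_hash <- hash
    df
  }
  emit <- function(df, name) {
    utils::write.csv(stamp(df), file.path(config$output_dir, name),
                     row.names = FALSE)
  }
  log_line("seeds: split %d, rf %d, shap %d", config$split_seed,
           config$rf_seed, config$shap_seed)

  # -- curate ---------------------------------------------------------------
  curated <- stage("curate", curate(records, config$conflict_tolerance))
  stage("curate", write_curated_dataset(
    curated, file.path(config$output_dir, "curated.csv")))
  log_line("curate: %d input rows -> %d molecules",
           curated$provenance$inputs, curated$provenance$kept)
  smiles <- curated$records$smiles
  y <- curated$records$logS
  n <- length(smiles)
  if (n < 10L)
    stop("stage 'curate' failed: fewer than 10 curated molecules",
         call. = FALSE)

  profile <- stage("profile", profile_dataset(curated))
  jsonlite::write_json(c(profile, list(config_hash = hash)),
                       file.path(config$output_dir, "profile.json"),
                       auto_unbox = TRUE)
  log_line("profile: mean MW %.1f, carbon range [%d, %d]",
           profile$mw_mean, profile$carbon_range[1], profile$carbon_range[2])

  mols <- stage("parse", parse_molecules(smiles, strict = TRUE))

  # -- featurize ------------------------------------------------------------
  dm <- stage("descriptors", {
    full <- compute_descriptors(mols)
    descriptor_cascade(full,
                       variance_threshold = config$variance_threshold,
                       correlation_cutoff = config$correlation_cutoff,
                       exclude = config$excluded_descriptors)
  })
  stage("descriptors", write_descriptor_matrix(
    dm, file.path(config$output_dir, "descriptors.csv")))
  for (i in seq_len(nrow(dm$stage_log)))
    log_line("descriptors %s: %d -> %d columns", dm$stage_log$stage[i],
             dm$stage_log$before[i], dm$stage_log$after[i])
  xd <- as.matrix(dm$values)

  fp <- stage("fingerprints",
              morgan_fingerprints(mols, radius = config$fp_radius,
                                  n_bits = config$fp_bits))
  log_line("fingerprints: %d molecules x %d bits, %d bits observed",
           nrow(fp$bits), ncol(fp$bits), sum(colSums(fp$bits) > 0))

  # -- split + bit selection ------------------------------------------------
  split <- split_train_test(n, config$split_fraction, config$split_seed)
  tr <- split$train_idx
  log_line("split: %d train / %d test (seed %d)", length(tr),
           length(split$test_idx), config$split_seed)

  sel <- stage("lasso", lasso_select(fp$bits[tr, , drop = FALSE], y[tr],
                                     alpha_grid = config$lasso_alpha_grid,
                                     chosen_alpha = config$lasso_alpha))
  log_line("lasso: %d bits selected at alpha %g",
           length(sel$selected_bit_ids), sel$chosen_alpha)
  sel_cols <- sel$selected_bit_ids + 1L
  # the MLR needs p < n(train); keep the largest-|coefficient| bits if not
  mlr_cols <- sel_cols
  if (length(mlr_cols) >= length(tr)) {
    keep <- order(abs(sel$coefficients),
                  decreasing = TRUE)[seq_len(length(tr) - 2L)]
    mlr_cols <- sel_cols[sort(keep)]
    log_line("lasso: truncated to %d bits for the linear model",
             length(mlr_cols))
  }
  xf <- fp$bits[, sel_cols, drop = FALSE]
  xf_mlr <- fp$bits[, mlr_cols, drop = FALSE]
  emit(data.frame(alpha = as.numeric(names(sel$n_selected)),
                  n_selected = as.integer(sel$n_selected)),
       "lasso_path.csv")

  # -- train + metrics ------------------------------------------------------
  fit_one <- function(x, method, rep)
    fit_solubility(x[tr, , drop = FALSE], y[tr], method = method,
                   ntree = config$rf_ntree, seed = config$rf_seed,
                   representation = rep)
  models <- stage("train", list(
    rf_descriptors = fit_one(xd, "rf", "descriptors"),
    mlr_descriptors = fit_one(xd, "mlr", "descriptors"),
    rf_fingerprints = fit_one(xf, "rf", "fingerprints"),
    mlr_fingerprints = fit_one(xf_mlr, "mlr", "fingerprints")))

  metrics <- stage("metrics", do.call(rbind, lapply(names(models),
    function(nm) {
      x <- if (nm == "mlr_fingerprints") xf_mlr
           else if (nm == "rf_fingerprints") xf else xd
      out <- evaluate_split(models[[nm]], x, y, split)
      cbind(data.frame(model = sub("_.*", "", nm),
                       representation = sub("^[^_]*_", "", nm),
                       stringsAsFactors = FALSE), out)
    })))
  emit(metrics, "metrics.csv")
  for (i in seq_len(nrow(metrics)))
    log_line("metrics %s/%s %s: R2 %.3f RMSE %.3f MAE %.3f",
             metrics$model[i], metrics$representation[i],
             metrics$partition[i], metrics$r2[i], metrics$rmse[i],
             metrics$mae[i])

  # -- interpret ------------------------------------------------------------
  shap_d <- stage("interpret", shap_importance(
    models$rf_descriptors, max_rows = config$shap_max_rows,
    seed = config$shap_seed))
  shap_f <- stage("interpret", shap_importance(
    models$rf_fingerprints, max_rows = config$shap_max_rows,
    seed = config$shap_seed))
  coef_d <- coefficient_report(models$mlr_descriptors)
  coef_f <- coefficient_report(models$mlr_fingerprints)
  emit(shap_d$importance, "shap_descriptors.csv")
  emit(shap_f$importance, "shap_fingerprints.csv")
  emit(coef_d, "coefficients_descriptors.csv")
  emit(coef_f, "coefficients_fingerprints.csv")
  log_line("interpret: top descriptor %s, top bit %s",
           shap_d$importance$feature[1], shap_f$importance$feature[1])

  # -- outlier diagnostics --------------------------------------------------
  diag <- stage("outliers", {
    lof_d <- lof_flags(xd[tr, , drop = FALSE],
                       n_neighbors = config$lof_neighbors,
                       threshold = config$lof_threshold,
                       standardize = TRUE)
    lof_f <- lof_flags(fp$bits[tr, , drop = FALSE],
                       n_neighbors = config$lof_neighbors,
                       threshold = config$lof_threshold,
                       standardize = FALSE)
    tt <- if (any(lof_d$flagged) && !all(lof_d$flagged))
      group_ttests(xd[tr, , drop = FALSE], lof_d$flagged) else NULL
    counts <- bit_frequency_counts(fp$bits)
    ratios <- apply(fp$bits[tr, , drop = FALSE], 1, rare_feature_ratio,
                    counts = counts, rare_threshold = config$rare_threshold)
    refit <- if (any(lof_d$flagged) && sum(!lof_d$flagged) >= 2)
      refit_without_outliers(xd, y, split, lof_d$flagged, method = "rf",
                             ntree = config$rf_ntree,
                             seed = config$rf_seed) else NULL
    list(lof_descriptors = lof_d, lof_fingerprints = lof_f, ttests = tt,
         rare_ratios = ratios, refit = refit)
  })
  emit(data.frame(row = tr,
                  lof_descriptors = diag$lof_descriptors$scores,
                  flagged_descriptors = diag$lof_descriptors$flagged,
                  lof_fingerprints = diag$lof_fingerprints$scores,
                  flagged_fingerprints = diag$lof_fingerprints$flagged,
                  rare_ratio = diag$rare_ratios),
       "outliers.csv")
  if (!is.null(diag$ttests)) emit(diag$ttests, "outlier_ttests.csv")
  if (!is.null(diag$refit))
    jsonlite::write_json(c(diag$refit["delta"],
                           n_removed = diag$refit$n_removed,
                           config_hash = hash),
                         file.path(config$output_dir, "refit_delta.json"),
                         auto_unbox = TRUE, digits = NA)
  log_line("outliers: %d flagged (descriptors), %d flagged (fingerprints)",
           sum(diag$lof_descriptors$flagged),
           sum(diag$lof_fingerprints$flagged))
  fl <- diag$lof_fingerprints$flagged
  if (any(fl) && !all(fl))
    log_line("rare-bit ratio: %.3f flagged vs %.3f unflagged",
             mean(diag$rare_ratios[fl]), mean(diag$rare_ratios[!fl]))

  # -- fragment thermodynamics ----------------------------------------------
  thermo <- stage("fragments", {
    top_bits <- utils::head(shap_f$importance$feature, config$top_fragments)
    ids <- as.integer(sub("^bit", "", top_bits))
    atlas <- bit_atlas(mols, radius = config$fp_radius,
                       n_bits = config$fp_bits)
    frags <- vapply(ids, function(b) {
      a <- atlas[[as.character(b)]]
      if (is.null(a)) NA_character_ else a$fragment[1]
    }, "")
    ok <- !is.na(frags)
    if (!any(ok)) NULL
    else fragment_thermo_table(stats::setNames(frags[ok], top_bits[ok]))
  })
  if (!is.null(thermo)) emit(thermo, "fragment_thermo.csv")

  log_line("run complete")
  structure(list(config = config, config_hash = hash,
                 output_dir = config$output_dir,
                 curated = curated, profile = profile, split = split,
                 descriptors = dm, selection = sel, models = models,
                 metrics = metrics,
                 importance = list(shap_descriptors = shap_d,
                                   shap_fingerprints = shap_f,
                                   coefficients_descriptors = coef_d,
                                   coefficients_fingerprints = coef_f),
                 diagnostics = diag, fragment_thermo = thermo,
                 fp_config = list(radius = config$fp_radius,
                                  n_bits = config$fp_bits,
                                  selected_bits = sel_cols,
                                  mlr_bits = mlr_cols)),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %s (hash %s): %d molecules, %d models\n",
              x$output_dir, x$config_hash, nrow(x$curated$records),
              length(x$models)))
  print(x$metrics[x$metrics$partition == "test", ])
  invisible(x)
}

#' Blind-set evaluation
#'
#' Scores the fitted models of a [run_pipeline()] result on molecules that
#' were never part of the study. Disjointness is asserted first: any
#' canonical-SMILES overlap between the blind table and the curated
#' training data is an error. Features for the blind molecules are
#' computed with the run's own configuration (descriptor engine restricted
#' to the surviving cascade columns; fingerprint bits restricted to the
#' model's selected bits).
#'
#' @param run a `pipeline_run`.
#' @param blind data.frame with columns `name`, `smiles` and `logS`
#'   (observed intrinsic solubility).
#' @return object of class `"blind_result"`: list with `table` (per
#'   molecule: name, canonical smiles, observed, per-model prediction and
#'   absolute error) and `mean_abs_error` (named per model).
#' @export
evaluate_blind <- function(run, blind) {
  stopifnot(inherits(run, "pipeline_run"), is.data.frame(blind),
            all(c("name", "smiles", "logS") %in% names(blind)))
  canon <- canonicalize_smiles(blind$smiles, strict = TRUE)
  overlap <- intersect(canon, run$curated$records$smiles)
  if (length(overlap))
    stop("blind set overlaps the training data: ",
         paste(utils::head(overlap, 5), collapse = ", "), call. = FALSE)

  mols <- parse_molecules(canon, strict = TRUE)
  full <- compute_descriptors(mols)
  fp <- morgan_fingerprints(mols, radius = run$fp_config$radius,
                            n_bits = run$fp_config$n_bits)
  feats <- list(
    rf_descriptors = as.matrix(full$values[
      run$models$rf_descriptors$feature_names]),
    mlr_descriptors = as.matrix(full$values[
      run$models$mlr_descriptors$feature_names]),
    rf_fingerprints = fp$bits[, run$fp_config$selected_bits, drop = FALSE],
    mlr_fingerprints = fp$bits[, run$fp_config$mlr_bits, drop = FALSE])

  tab <- data.frame(name = blind$name, smiles = canon,
                    observed = blind$logS, stringsAsFactors = FALSE)
  mae <- numeric(0)
  for (nm in names(run$models)) {
    pred <- predict(run$models[[nm]], feats[[nm]])
    tab[[paste0("pred_", nm)]] <- pred
    tab[[paste0("abserr_", nm)]] <- abs(pred - blind$logS)
    mae[nm] <- mean(abs(pred - blind$logS))
  }
  structure(list(table = tab, mean_abs_error = mae),
            class = "blind_result")
}

#' @export
print.blind_result <- function(x, ...) {
  cat(sprintf("<blind_result> %d molecules\n", nrow(x$table)))
  print(round(x$mean_abs_error, 4))
  invisible(x)
}
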