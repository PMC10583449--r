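# The 2D molecular-descriptor engine and the pruning cascade.
#
# The engine computes constitutional counts, topological indices,
# Moreau-Broto autocorrelations (plain and centered) over atomic
# properties, electrotopological-style atom-type counts, and OpenBabel bulk
# properties (SlogP, molar refractivity, TPSA, hydrogen-bond counts). All
# descriptors are 2D: nothing depends on coordinates. The cascade then
# prunes the matrix the way solubility QSPR studies do: non-numeric and
# incomplete columns out first, then low-variance columns, then one of each
# highly correlated pair, then named leakage columns (the engine's own
# quick logS estimate).

.autocorr_weights <- c("Z", "m", "se", "p", "i", "v")
.autocorr_maxlag <- 7L

# ---- descriptor matrix container ------------------------------------------

.new_descriptor_matrix <- function(values, stage_log = NULL) {
  if (is.null(stage_log))
    stage_log <- data.frame(stage = "compute", before = ncol(values),
                            after = ncol(values), removed = 0L,
                            stringsAsFactors = FALSE)
  structure(list(values = values, stage_log = stage_log,
                 removed = list()), class = "descriptor_matrix")
}

.log_stage <- function(dm, stage, keep) {
  before <- ncol(dm$values)
  dropped <- colnames(dm$values)[!keep]
  dm$values <- dm$values[, keep, drop = FALSE]
  dm$stage_log <- rbind(dm$stage_log,
                        data.frame(stage = stage, before = before,
                                   after = ncol(dm$values),
                                   removed = length(dropped),
                                   stringsAsFactors = FALSE))
  dm$removed[[stage]] <- dropped
  dm
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("<descriptor_matrix> %d molecules x %d descriptors\n",
              nrow(x$values), ncol(x$values)))
  print(x$stage_log, row.names = FALSE)
  invisible(x)
}

#' @export
dim.descriptor_matrix <- function(x) dim(x$values)

#' Extract the numeric feature table of a descriptor matrix
#' @param x a `descriptor_matrix`.
#' @return the values table (data.frame).
#' @export
descriptor_values <- function(x) {
  stopifnot(inherits(x, "descriptor_matrix"))
  x$values
}

# ---- the engine ------------------------------------------------------------

#' Compute the 2D molecular descriptor matrix
#'
#' One row per molecule, one column per descriptor of the package's 2D
#' engine. Columns include non-numeric screens (e.g. the rule-of-five
#' flag) and may contain NA where a computation fails; both are removed by
#' [drop_non_numeric()]. The engine also emits `ESOL_logS`, a quick
#' regression estimate of logS itself, which [descriptor_cascade()]
#' excludes by default to prevent target leakage.
#'
#' @param molecules a `mol_set` or character vector of SMILES.
#' @return a `descriptor_matrix`.
#' @export
compute_descriptors <- function(molecules) {
  ms <- parse_molecules(molecules, strict = FALSE)
  n <- length(ms$smiles)
  if (n == 0L) stop("empty molecule list", call. = FALSE)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- if (ms$ok[i]) .descriptor_row(ms$graph[[i]])
                 else .descriptor_row(NULL)
  }
  vals <- as.data.frame(do.call(rbind, rows))

  # batched SMARTS atom-type counts
  at <- .atom_type_counts(ms)
  vals <- cbind(vals, at)

  # OpenBabel bulk properties
  ob <- .openbabel_props(ms)
  vals <- cbind(vals, ob)

  # quick logS estimate (leakage column) and boolean screens
  rb <- vals$nRotBond
  ap <- ifelse(vals$nHeavy > 0, vals$nAromAtom / vals$nHeavy, 0)
  vals$ESOL_logS <- 0.16 - 0.63 * vals$SlogP - 0.0062 * vals$MW +
    0.066 * rb - 0.74 * ap
  vals$RuleOf5 <- vals$MW <= 500 & vals$SlogP <= 5 & vals$HBD <= 5 &
    vals$HBA1 <= 10

  .new_descriptor_matrix(vals)
}

# one numeric row of graph-derived descriptors; g = NULL gives all-NA
.descriptor_row <- function(g) {
  names_out <- .graph_descriptor_names()
  if (is.null(g)) {
    return(stats::setNames(rep(NA_real_, length(names_out)), names_out))
  }
  out <- numeric(0)
  elem <- g$elem
  n <- g$n
  nb <- nrow(g$bonds)
  nh_total <- sum(g$nH)
  mass <- .element_prop(elem, "mass")
  mw <- sum(mass) + nh_total * 1.008

  counts <- c(
    nHeavy = n, nHydrogen = nh_total, nAtomTotal = n + nh_total,
    nC = sum(elem == "C"), nN = sum(elem == "N"), nO = sum(elem == "O"),
    nS = sum(elem == "S"), nP = sum(elem == "P"), nF = sum(elem == "F"),
    nCl = sum(elem == "Cl"), nBr = sum(elem == "Br"), nI = sum(elem == "I"),
    nHalogen = sum(elem %in% c("F", "Cl", "Br", "I")),
    nHetero = sum(elem != "C"),
    nAromAtom = sum(g$aromatic), nRingAtom = sum(g$in_ring),
    MW = mw, AMW = mw / max(1, n + nh_total))

  ords <- if (nb) g$bonds[, 3] else numeric(0)
  arom <- g$arom_bond
  ncomp <- 1L  # molecules are connected (mixtures are rejected upstream)
  bondc <- c(
    nBonds = nb,
    nBondsS = sum(ords == 1 & !arom), nBondsD = sum(ords == 2 & !arom),
    nBondsT = sum(ords == 3), nBondsA = sum(arom),
    nRing = max(0L, nb - n + ncomp),
    nAromRing = g$n_aromatic_rings,
    fracCsp3 = {
      nc <- sum(elem == "C")
      if (nc == 0) NA_real_ else {
        sp3 <- vapply(seq_len(n), function(v) {
          elem[v] == "C" && !g$aromatic[v] &&
            all(g$bonds[g$adj[[v]], 3] == 1)
        }, TRUE)
        sum(sp3) / nc
      }
    })

  topo <- .topological_indices(g)
  autoc <- .autocorrelations(g)
  c(counts, bondc, topo, autoc)
}

.graph_descriptor_names <- function() {
  c("nHeavy", "nHydrogen", "nAtomTotal", "nC", "nN", "nO", "nS", "nP",
    "nF", "nCl", "nBr", "nI", "nHalogen", "nHetero", "nAromAtom",
    "nRingAtom", "MW", "AMW",
    "nBonds", "nBondsS", "nBondsD", "nBondsT", "nBondsA", "nRing",
    "nAromRing", "fracCsp3",
    .topo_names(),
    as.vector(t(outer(c("ATS", "ATSC"),
                      paste0(rep(0:.autocorr_maxlag, each = length(.autocorr_weights)),
                             .autocorr_weights), paste0))))
}

.topo_names <- function() {
  c("Wiener", "Harary", "Diameter", "Radius", "MeanEcc", "Zagreb1",
    "Zagreb2", "Platt", "Chi0", "Chi1", "Chi2", "Chi3", "Chi0v", "Chi1v",
    "Kappa1", "Kappa2", "Kappa3", "BalabanJ")
}

.topological_indices <- function(g) {
  n <- g$n
  deg <- g$degree
  out <- stats::setNames(rep(NA_real_, length(.topo_names())), .topo_names())
  if (n == 1L) {
    out[] <- 0
    out["Kappa1"] <- out["Kappa2"] <- out["Kappa3"] <- NA_real_
    return(out)
  }
  D <- .graph_distances(g)
  finite <- is.finite(D) & D > 0
  out["Wiener"] <- sum(D[finite]) / 2
  out["Harary"] <- sum(1 / D[finite]) / 2
  ecc <- apply(ifelse(is.finite(D), D, NA), 1, max, na.rm = TRUE)
  out["Diameter"] <- max(ecc); out["Radius"] <- min(ecc)
  out["MeanEcc"] <- mean(ecc)
  out["Zagreb1"] <- sum(deg^2)
  e_deg <- cbind(deg[g$bonds[, 1]], deg[g$bonds[, 2]])
  out["Zagreb2"] <- sum(e_deg[, 1] * e_deg[, 2])
  out["Platt"] <- sum(e_deg[, 1] + e_deg[, 2] - 2)
  out["Chi0"] <- sum(1 / sqrt(deg[deg > 0]))
  out["Chi1"] <- sum(1 / sqrt(e_deg[, 1] * e_deg[, 2]))
  pc <- .path_counts(g)
  chi_path <- function(paths) {
    if (!length(paths)) return(0)
    sum(vapply(paths, function(p) 1 / sqrt(prod(deg[p])), 1))
  }
  out["Chi2"] <- chi_path(pc$p2_paths)
  out["Chi3"] <- chi_path(pc$p3_paths)
  dv <- .valence_delta(g)
  if (all(is.finite(dv)) && all(dv > 0)) {
    out["Chi0v"] <- sum(1 / sqrt(dv))
    out["Chi1v"] <- sum(1 / sqrt(dv[g$bonds[, 1]] * dv[g$bonds[, 2]]))
  }
  A <- n; P1 <- nrow(g$bonds); P2 <- pc$p2; P3 <- pc$p3
  out["Kappa1"] <- if (P1 > 0) A * (A - 1)^2 / P1^2 else NA_real_
  out["Kappa2"] <- if (P2 > 0) (A - 1) * (A - 2)^2 / P2^2 else NA_real_
  out["Kappa3"] <- if (P3 > 0) {
    if (A %% 2 == 1) (A - 1) * (A - 3)^2 / P3^2
    else (A - 3) * (A - 2)^2 / P3^2
  } else NA_real_
  mu <- P1 - A + 1L
  s <- rowSums(ifelse(is.finite(D), D, 0))
  out["BalabanJ"] <- if (P1 > 0)
    P1 / (mu + 1) * sum(1 / sqrt(s[g$bonds[, 1]] * s[g$bonds[, 2]]))
    else 0
  out
}

# Kier-Hall valence delta
.valence_delta <- function(g) {
  zv <- .element_prop(g$elem, "zv")
  z <- .element_prop(g$elem, "Z")
  dv <- ifelse(z > 10, (zv - g$nH) / (z - zv - 1), zv - g$nH)
  dv
}

.autocorrelations <- function(g) {
  lags <- 0:.autocorr_maxlag
  props <- list(
    Z = .element_prop(g$elem, "Z"),
    m = .element_prop(g$elem, "mass"),
    se = .element_prop(g$elem, "en_sanderson"),
    p = .element_prop(g$elem, "polarizability"),
    i = .element_prop(g$elem, "ionization"),
    v = .element_vdw_volume(g$elem))
  D <- if (g$n > 1L) .graph_distances(g) else matrix(0, 1, 1)
  out <- numeric(0)
  for (d in lags) {
    if (d == 0L) {
      pair_i <- pair_j <- seq_len(g$n)
    } else {
      idx <- which(D == d & upper.tri(D), arr.ind = TRUE)
      pair_i <- idx[, 1]; pair_j <- idx[, 2]
    }
    for (w in .autocorr_weights) {
      x <- props[[w]]
      ats <- if (length(pair_i)) sum(x[pair_i] * x[pair_j]) else 0
      xc <- x - mean(x)
      atsc <- if (length(pair_i)) sum(xc[pair_i] * xc[pair_j]) else 0
      out[paste0("ATS", d, w)] <- ats
      out[paste0("ATSC", d, w)] <- atsc
    }
  }
  # reorder to the documented name order (all ATS then interleaved is fine;
  # keep stable order as generated)
  nm <- .graph_descriptor_names()
  nm <- nm[grepl("^ATSC?[0-9]", nm)]
  out[nm]
}

# electrotopological-style atom-type and fragment counts, batched SMARTS
.atom_type_counts <- function(ms) {
  pats <- c(NsCH3 = "[CX4H3]", NssCH2 = "[CX4H2]", NsssCH = "[CX4H1]",
            NssssC = "[CX4H0]", NaaCH = "[cH]", NaaNH = "[nH]",
            NsOH = "[OX2H;!$([OX2H][CX3]=[OX1])]",
            NdO = "[OX1]", NsNH2 = "[NX3H2]",
            NsF = "[F]", NsCl = "[Cl]", NsBr = "[Br]",
            nCarbonyl = "[CX3]=[OX1]",
            nCOOH = "[CX3](=[OX1])[OX2H1]",
            nEster = "[CX3](=[OX1])[OX2][#6]",
            nEther = "[OX2]([#6])[#6]",
            nRotBond = "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]")
  out <- matrix(NA_real_, length(ms$smiles), length(pats),
                dimnames = list(NULL, names(pats)))
  for (j in seq_along(pats)) out[, j] <- count_smarts(ms, pats[[j]])
  as.data.frame(out)
}

.openbabel_props <- function(ms) {
  cols <- c(SlogP = "logP", SMR = "MR", TPSA = "TPSA", HBD = "HBD",
            HBA1 = "HBA1", HBA2 = "HBA2")
  out <- matrix(NA_real_, length(ms$smiles), length(cols),
                dimnames = list(NULL, names(cols)))
  if (any(ms$ok)) {
    p <- ChemmineOB::prop_OB(.obmols(ms))
    for (j in seq_along(cols)) out[ms$ok, j] <- p[[cols[[j]]]]
  }
  as.data.frame(out)
}

# ---- the pruning cascade ---------------------------------------------------

#' Drop non-numeric and incomplete descriptor columns
#'
#' Retains only columns in which every value is a finite real number:
#' categorical/boolean screens and any descriptor with a failed (NA/NaN/Inf)
#' computation are removed, and the stage is appended to the log.
#'
#' @param dm a `descriptor_matrix`.
#' @return the pruned `descriptor_matrix`.
#' @export
drop_non_numeric <- function(dm) {
  stopifnot(inherits(dm, "descriptor_matrix"))
  keep <- vapply(dm$values, function(col)
    is.numeric(col) && all(is.finite(col)), TRUE)
  if (!any(keep)) stop("all descriptor columns dropped", call. = FALSE)
  .log_stage(dm, "drop_non_numeric", keep)
}

#' Remove low-variance descriptors
#'
#' Drops columns whose sample variance, computed on the raw (unscaled)
#' values, is below `threshold`.
#'
#' @param dm a `descriptor_matrix` (numeric columns only).
#' @param threshold variance threshold (>= 0); default 0.1.
#' @return the pruned `descriptor_matrix`.
#' @export
low_variance_filter <- function(dm, threshold = 0.1) {
  stopifnot(inherits(dm, "descriptor_matrix"))
  if (threshold < 0) stop("variance threshold must be >= 0", call. = FALSE)
  v <- vapply(dm$values, function(col) stats::var(as.numeric(col)), 1)
  keep <- !is.na(v) & v >= threshold
  .log_stage(dm, "low_variance_filter", keep)
}

#' Prune pairwise-correlated descriptors
#'
#' Greedy scan in column order: for every pair with `|Pearson r| > cutoff`
#' the later column is dropped, so the earlier column in the engine's
#' canonical order is kept and the result contains no offending pair.
#'
#' @param dm a `descriptor_matrix` (numeric columns only).
#' @param cutoff absolute Pearson correlation cutoff in (0, 1]; default 0.95.
#' @return the pruned `descriptor_matrix`.
#' @export
pairwise_correlation_prune <- function(dm, cutoff = 0.95) {
  stopifnot(inherits(dm, "descriptor_matrix"))
  if (!(cutoff > 0 && cutoff <= 1))
    stop("correlation cutoff must lie in (0, 1]", call. = FALSE)
  x <- as.matrix(dm$values)
  p <- ncol(x)
  keep <- rep(TRUE, p)
  if (p > 1L) {
    cm <- abs(suppressWarnings(stats::cor(x)))
    cm[is.na(cm)] <- 0
    for (j in 2:p) {
      prior <- which(keep[seq_len(j - 1L)])
      if (any(cm[prior, j] > cutoff)) keep[j] <- FALSE
    }
  }
  .log_stage(dm, "pairwise_correlation_prune", keep)
}

#' Exclude descriptors by name
#'
#' Removes the listed columns if present (absent names are noted, not
#' errors). Used to drop leakage features such as the engine's own quick
#' logS estimate before modelling.
#'
#' @param dm a `descriptor_matrix`.
#' @param names character vector of column names to remove.
#' @return the pruned `descriptor_matrix`.
#' @export
exclude_named <- function(dm, names = "ESOL_logS") {
  stopifnot(inherits(dm, "descriptor_matrix"))
  absent <- setdiff(names, colnames(dm$values))
  if (length(absent))
    message("exclude_named: not present: ", paste(absent, collapse = ", "))
  keep <- !colnames(dm$values) %in% names
  .log_stage(dm, "exclude_named", keep)
}

#' Run the full descriptor pruning cascade
#'
#' Applies, in order: [drop_non_numeric()], [low_variance_filter()],
#' [pairwise_correlation_prune()], [exclude_named()]. The stage log records
#' the column count before and after every stage.
#'
#' @param dm a `descriptor_matrix` from [compute_descriptors()].
#' @param variance_threshold variance cutoff (default 0.1).
#' @param correlation_cutoff absolute pairwise correlation cutoff
#'   (default 0.95).
#' @param exclude names removed at the end (default the engine's
#'   `ESOL_logS` leakage column).
#' @return the pruned `descriptor_matrix`.
#' @export
descriptor_cascade <- function(dm, variance_threshold = 0.1,
                               correlation_cutoff = 0.95,
                               exclude = "ESOL_logS") {
  dm <- drop_non_numeric(dm)
  dm <- low_variance_filter(dm, variance_threshold)
  dm <- pairwise_correlation_prune(dm, correlation_cutoff)
  exclude_named(dm, exclude)
}

#' Write a descriptor matrix with its stage log
#'
#' CSV of the values plus a JSON sidecar of the stage log.
#'
#' @param dm a `descriptor_matrix`.
#' @param path output CSV path; the log goes to `<path>.stages.json`.
#' @return `path`, invisibly.
#' @export
write_descriptor_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "descriptor_matrix"))
  utils::write.csv(dm$values, path, row.names = FALSE)
  jsonlite::write_json(dm$stage_log, paste0(path, ".stages.json"),
                       dataframe = "rows")
  invisible(path)
}
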