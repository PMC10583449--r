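# Morgan (ECFP4) circular fingerprints with a bit-to-substructure atlas.
#
# Implemented directly on the heavy-atom graph so that every folded bit can
# be traced back to the (center atom, radius) environments that set it --
# the property the interpretation stage relies on. Atom invariants follow
# the ECFP recipe (element, heavy degree, hydrogen count, charge, ring
# membership, aromaticity); neighbour updates hash sorted
# (bond order, invariant) pairs, so the result is independent of atom
# numbering and SMILES spelling. Aromatic bonds carry their own bond label,
# making the hash independent of the kekulization OpenBabel happened to
# choose.

.HASH_MOD <- 2147483647  # 2^31 - 1; all arithmetic stays exact in doubles

.hash_mix <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% .HASH_MOD) + 1) %% .HASH_MOD
  h
}

.initial_invariants <- function(g) {
  z <- .element_prop(g$elem, "Z")
  z[is.na(z)] <- 0
  vapply(seq_len(g$n), function(a)
    .hash_mix(c(z[a], g$degree[a], g$nH[a], g$charge[a] + 16,
                as.integer(g$in_ring[a]), as.integer(g$aromatic[a]))),
    1)
}

# ECFP bond label: 1/2/3 for single/double/triple, 4 for aromatic
.bond_labels <- function(g) {
  if (!nrow(g$bonds)) return(numeric(0))
  ifelse(g$arom_bond, 4, g$bonds[, 3])
}

# all circular environments of a graph up to `radius`:
# data.frame(atom, radius, id)
.morgan_environments <- function(g, radius = 2L) {
  inv <- .initial_invariants(g)
  labels <- .bond_labels(g)
  env <- data.frame(atom = seq_len(g$n), radius = 0L, id = inv)
  for (r in seq_len(radius)) {
    new_inv <- numeric(g$n)
    for (a in seq_len(g$n)) {
      ks <- g$adj[[a]]
      if (length(ks)) {
        nbr <- ifelse(g$bonds[ks, 1] == a, g$bonds[ks, 2], g$bonds[ks, 1])
        ord <- order(labels[ks], inv[nbr])
        items <- as.vector(rbind(labels[ks][ord], inv[nbr][ord]))
      } else items <- numeric(0)
      new_inv[a] <- .hash_mix(c(r, inv[a], items))
    }
    inv <- new_inv
    env <- rbind(env, data.frame(atom = seq_len(g$n), radius = r, id = inv))
  }
  env
}

.bits_from_env <- function(env, n_bits) sort(unique(env$id %% n_bits))

#' Morgan (ECFP4) fingerprints
#'
#' Circular-environment hashing of every atom neighbourhood up to `radius`
#' bonds (ECFP4 = radius 2, diameter 4), folded into `n_bits` binary
#' features. Deterministic, and invariant to atom numbering and SMILES
#' spelling.
#'
#' @param molecules a `mol_set` or character vector of SMILES (all must
#'   parse).
#' @param radius maximum environment radius in bonds (default 2).
#' @param n_bits folded fingerprint length (default 2048).
#' @return object of class `"fingerprint_matrix"`: list with `bits` (an
#'   n x n_bits 0/1 integer matrix, columns `bit0...`), `radius`, `n_bits`.
#' @export
morgan_fingerprints <- function(molecules, radius = 2L, n_bits = 2048L) {
  ms <- parse_molecules(molecules, strict = FALSE)
  if (any(!ms$ok))
    stop("invalid molecules at positions: ",
         paste(utils::head(which(!ms$ok), 5L), collapse = ", "),
         call. = FALSE)
  n <- length(ms$smiles)
  bits <- matrix(0L, n, n_bits,
                 dimnames = list(NULL, paste0("bit", seq_len(n_bits) - 1L)))
  for (i in seq_len(n)) {
    env <- .morgan_environments(ms$graph[[i]], radius)
    bits[i, .bits_from_env(env, n_bits) + 1L] <- 1L
  }
  structure(list(bits = bits, radius = as.integer(radius),
                 n_bits = as.integer(n_bits)),
            class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf("<fingerprint_matrix> %d molecules x %d bits (radius %d), %.1f bits set/molecule\n",
              nrow(x$bits), x$n_bits, x$radius, mean(rowSums(x$bits))))
  invisible(x)
}

#' Map a fingerprint bit back to its substructures
#'
#' Returns every circular environment of `molecule` that folds to `bit_id`:
#' the center atom index, the environment radius, and the fragment SMILES
#' of the induced subgraph (open valences hydrogen-capped by the SMILES
#' convention). Erroring when the bit is not set guards against reading a
#' substructure into a bit the molecule does not exhibit.
#'
#' @param molecule a single SMILES string or 1-molecule `mol_set`.
#' @param bit_id folded bit index in `0:(n_bits-1)`.
#' @param radius,n_bits fingerprint configuration (must match the matrix
#'   the bit came from).
#' @return data.frame `center_atom, radius, fragment` (one row per
#'   environment).
#' @export
bit_to_substructure <- function(molecule, bit_id, radius = 2L,
                                n_bits = 2048L) {
  ms <- parse_molecules(molecule, strict = TRUE)
  stopifnot(length(ms$smiles) == 1L, bit_id >= 0, bit_id < n_bits)
  g <- ms$graph[[1L]]
  env <- .morgan_environments(g, radius)
  hit <- env[env$id %% n_bits == bit_id, , drop = FALSE]
  if (!nrow(hit))
    stop("bit ", bit_id, " is not set for this molecule", call. = FALSE)
  D <- .graph_distances(g)
  frags <- vapply(seq_len(nrow(hit)), function(k) {
    atoms <- which(D[hit$atom[k], ] <= hit$radius[k])
    .fragment_smiles(ms, 1L, atoms)
  }, "")
  data.frame(center_atom = hit$atom, radius = hit$radius,
             fragment = frags, stringsAsFactors = FALSE)
}

#' Build a bit atlas over a molecule collection
#'
#' For each fingerprint bit observed in the collection, records example
#' environments (molecule index, center atom, radius, fragment SMILES).
#' Used to attach chemistry to the bits that the models and SHAP rank as
#' important.
#'
#' @param molecules a `mol_set` or character vector of SMILES.
#' @param radius,n_bits fingerprint configuration.
#' @param max_examples examples kept per bit (distinct fragments are
#'   preferred).
#' @return named list (names = bit ids as characters) of data.frames
#'   `molecule, center_atom, radius, fragment`.
#' @export
bit_atlas <- function(molecules, radius = 2L, n_bits = 2048L,
                      max_examples = 5L) {
  ms <- parse_molecules(molecules, strict = FALSE)
  atlas <- new.env(parent = emptyenv())
  for (i in which(ms$ok)) {
    g <- ms$graph[[i]]
    env <- .morgan_environments(g, radius)
    env$bit <- env$id %% n_bits
    D <- .graph_distances(g)
    # keep the smallest-radius environment per (bit) in this molecule
    env <- env[order(env$bit, env$radius), , drop = FALSE]
    env <- env[!duplicated(env$bit), , drop = FALSE]
    for (k in seq_len(nrow(env))) {
      key <- as.character(env$bit[k])
      cur <- if (!is.null(atlas[[key]])) atlas[[key]] else NULL
      if (!is.null(cur) && nrow(cur) >= max_examples) next
      atoms <- which(D[env$atom[k], ] <= env$radius[k])
      frag <- .fragment_smiles(ms, i, atoms)
      if (!is.null(cur) && frag %in% cur$fragment) next
      row <- data.frame(molecule = i, center_atom = env$atom[k],
                        radius = env$radius[k], fragment = frag,
                        stringsAsFactors = FALSE)
      atlas[[key]] <- if (is.null(cur)) row else rbind(cur, row)
    }
  }
  out <- as.list(atlas)
  out[order(as.integer(names(out)))]
}

# fragment SMILES of an induced heavy-atom subgraph, via OpenBabel; open
# valences become implicit hydrogens (hydrogen capping)
.fragment_smiles <- function(ms, i, atoms) {
  g <- ms$graph[[i]]
  if (length(atoms) == 1L) {
    a <- atoms[1L]
    return(.atom_token(g$elem[a], g$charge[a]))
  }
  sdf <- ms$sdf[[i]]
  ab <- ChemmineR::atomblock(sdf)
  orig <- g$orig_idx[atoms]
  sub_ab <- ab[orig, , drop = FALSE]
  bmask <- g$bonds[, 1] %in% atoms & g$bonds[, 2] %in% atoms
  bsub <- g$bonds[bmask, , drop = FALSE]
  bb <- matrix(0, nrow(bsub), length(.bondblock_cols),
               dimnames = list(NULL, .bondblock_cols))
  bb[, 1] <- match(bsub[, 1], atoms)
  bb[, 2] <- match(bsub[, 2], atoms)
  bb[, 3] <- bsub[, 3]
  hdr <- c(Molecule_Name = "fragment", Source = "aquasol", Comment = "",
           Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                 length(atoms), nrow(bb)))
  frag <- methods::new("SDF", header = hdr, atomblock = sub_ab,
                       bondblock = bb, datablock = character(0))
  out <- ChemmineR::sdf2smiles(
    methods::new("SDFset", SDF = list(frag), ID = "fragment"))
  strsplit(as.character(out), "\t", fixed = TRUE)[[1]][1]
}

.atom_token <- function(elem, charge) {
  if (charge == 0) {
    if (elem %in% c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")) elem
    else paste0("[", elem, "]")
  } else {
    sign <- if (charge > 0) "+" else "-"
    mag <- abs(charge)
    paste0("[", elem, sign, if (mag > 1) mag else "", "]")
  }
}

#' Select informative fingerprint bits by LASSO
#'
#' L1-penalized linear regression of logS on the raw 0/1 bits (they share a
#' scale, so no standardization; an intercept is fitted) across a grid of
#' penalty strengths alpha; the selected bits are those with nonzero
#' coefficients at `chosen_alpha`.
#'
#' @param x a `fingerprint_matrix` or 0/1 matrix (training partition).
#' @param y logS vector aligned with the rows of `x`.
#' @param alpha_grid penalty grid; default the decade grid
#'   `1e-5 ... 10`.
#' @param chosen_alpha penalty actually used for selection (default 0.001).
#' @return object of class `"bit_selection"`: `alpha_grid`,
#'   `n_selected` (per grid value), `chosen_alpha`, `selected_bit_ids`
#'   (0-based), `coefficients` (named, nonzero at chosen alpha).
#' @export
lasso_select <- function(x, y,
                         alpha_grid = c(1e-5, 1e-4, 1e-3, 1e-2, 0.1, 1, 10),
                         chosen_alpha = 0.001) {
  bits <- if (inherits(x, "fingerprint_matrix")) x$bits else as.matrix(x)
  stopifnot(nrow(bits) == length(y))
  if (stats::var(y) == 0)
    stop("degenerate response: y is constant", call. = FALSE)
  if (!chosen_alpha %in% alpha_grid)
    alpha_grid <- sort(c(alpha_grid, chosen_alpha))
  grid <- sort(unique(alpha_grid), decreasing = TRUE)
  fit <- glmnet::glmnet(bits, y, family = "gaussian", alpha = 1,
                        lambda = grid, standardize = FALSE,
                        intercept = TRUE, thresh = 1e-6, maxit = 1e6)
  cf <- as.matrix(stats::coef(fit))  # (p+1) x length(grid)
  nz <- colSums(cf[-1L, , drop = FALSE] != 0)
  j <- which.min(abs(grid - chosen_alpha))
  sel <- which(cf[-1L, j] != 0)
  structure(list(alpha_grid = grid, n_selected = stats::setNames(nz, grid),
                 chosen_alpha = chosen_alpha,
                 selected_bit_ids = sel - 1L,
                 coefficients = stats::setNames(cf[-1L, j][sel],
                                                rownames(cf)[-1L][sel])),
            class = "bit_selection")
}

#' @export
print.bit_selection <- function(x, ...) {
  cat(sprintf("<bit_selection> %d bits at alpha = %g\n",
              length(x$selected_bit_ids), x$chosen_alpha))
  print(x$n_selected)
  invisible(x)
}

#' Per-bit occurrence counts
#'
#' Number of molecules in which each bit is set; the sum over bits equals
#' the total number of set entries.
#'
#' @param x a `fingerprint_matrix` or 0/1 matrix.
#' @return named integer vector over bits.
#' @export
bit_frequency_counts <- function(x) {
  bits <- if (inherits(x, "fingerprint_matrix")) x$bits else as.matrix(x)
  colSums(bits)
}

#' Rare-feature ratio of a fingerprint
#'
#' Fraction of a molecule's set bits whose dataset-wide occurrence count is
#' below `rare_threshold`. An empty fingerprint (no set bits) yields 0 with
#' a warning.
#'
#' @param row a single 0/1 fingerprint vector.
#' @param counts per-bit occurrence counts over the reference dataset
#'   ([bit_frequency_counts()] of the full dataset).
#' @param rare_threshold a bit is "rare" when its count is strictly below
#'   this (default 100).
#' @return ratio in `[0, 1]`.
#' @export
rare_feature_ratio <- function(row, counts, rare_threshold = 100) {
  stopifnot(length(row) == length(counts))
  set <- which(row != 0)
  if (!length(set)) {
    warning("empty fingerprint: rare-feature ratio defined as 0",
            call. = FALSE)
    return(0)
  }
  mean(counts[set] < rare_threshold)
}

#' Write a fingerprint matrix to CSV
#' @param x a `fingerprint_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(x, path) {
  stopifnot(inherits(x, "fingerprint_matrix"))
  utils::write.csv(as.data.frame(x$bits), path, row.names = FALSE)
  invisible(path)
}
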