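# Synthetic molecule tables with a planted, known structure-logS
# relationship. The generator emulates the statistical shape of merged
# experimental solubility collections of low molecular weight organics
# (1-12 carbons, branched alkyl and benzene scaffolds, common polar and
# halogen substituents) with an additive functional-group model plus
# Gaussian measurement noise. The planted model is a test oracle for the
# downstream pipeline, not solubility physics.

# run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, fun) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}

#' Planted structure-logS model
#'
#' An additive model over functional-group counts used to label synthetic
#' molecules: `logS = intercept + sum(coefficient * count) + N(0, noise_sd)`.
#' Default coefficients encode the qualitative directions seen in aqueous
#' solubility data: hydrophobic bulk (carbons, halogens, aromatic rings)
#' lowers logS, hydrogen-bonding groups (hydroxyl, carboxyl, amine) raise
#' it; the noise level matches typical inter-laboratory scatter of
#' solubility measurements (about 0.3 log units).
#'
#' @param intercept baseline logS (log10 mol/L).
#' @param coefficients named numeric vector over the features of
#'   [count_functional_groups()].
#' @param noise_sd Gaussian measurement noise, log units (>= 0).
#' @param seed integer seed controlling the noise draw.
#' @return object of class `"planted_model"`.
#' @export
planted_model <- function(intercept = 0.5,
                          coefficients = c(n_carbon = -0.55,
                                           n_oh = 1.2,
                                           n_cooh = 1.0,
                                           n_nh2 = 0.9,
                                           n_halogen = -0.6,
                                           n_aromatic_ring = -0.6),
                          noise_sd = 0.3,
                          seed = 1L) {
  stopifnot(noise_sd >= 0,
            all(names(coefficients) %in% .group_features))
  full <- stats::setNames(numeric(length(.group_features)), .group_features)
  full[names(coefficients)] <- coefficients
  structure(list(intercept = intercept, coefficients = full,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "planted_model")
}

#' @export
print.planted_model <- function(x, ...) {
  cat("<planted_model> logS =", x$intercept, "+",
      paste(sprintf("%+.2f*%s", x$coefficients, names(x$coefficients)),
            collapse = " "),
      sprintf("+ N(0, %.2f), seed %d\n", x$noise_sd, x$seed))
  invisible(x)
}

# substituent grammar: token, carbon cost, sampling weight
.substituents <- data.frame(
  token = c("O", "C(=O)O", "N", "F", "Cl", "Br"),
  carbons = c(0L, 1L, 0L, 0L, 0L, 0L),
  weight = c(0.28, 0.14, 0.16, 0.10, 0.22, 0.10),
  stringsAsFactors = FALSE)

# random branched alkane SMILES with nc carbons and substituent tokens
# attached at random positions; each carbon hosts at most 3 branches
.random_aliphatic <- function(nc, subs) {
  parent <- integer(nc)
  slots <- rep(3L, nc)  # free heavy-attachment slots beyond the parent bond
  for (i in seq_len(nc)[-1]) {
    open <- which(slots[seq_len(i - 1L)] > 0L)
    p <- if (length(open) == 1L) open else sample(open, 1L)
    parent[i] <- p
    slots[p] <- slots[p] - 1L
  }
  children <- lapply(seq_len(nc), function(i) which(parent == i))
  decor <- vector("list", nc)
  for (s in subs) {
    open <- which(slots > 0L)
    if (!length(open)) break
    at <- if (length(open) == 1L) open else sample(open, 1L)
    decor[[at]] <- c(decor[[at]], s)
    slots[at] <- slots[at] - 1L
  }
  emit <- function(i) {
    br <- c(vapply(children[[i]], emit, ""), unlist(decor[[i]]))
    if (!length(br)) return("C")
    paste0("C", paste0("(", br, ")", collapse = ""))
  }
  emit(1L)
}

# benzene core with substituents/alkyl tail on ring positions 2..6
.random_aromatic <- function(tail_carbons, subs) {
  pos_tokens <- rep("", 5L)
  if (tail_carbons > 0L)
    pos_tokens[1L] <- .random_aliphatic(tail_carbons, character(0))
  open <- which(!nzchar(pos_tokens))
  subs <- subs[seq_len(min(length(subs), length(open)))]
  if (length(subs)) {
    at <- if (length(open) == 1L) open else sample(open, length(subs))
    pos_tokens[at] <- unlist(subs)
  }
  mid <- vapply(pos_tokens[1:4], function(t)
    if (nzchar(t)) paste0("c(", t, ")") else "c", "")
  tail6 <- pos_tokens[5L]
  paste0("c1", paste(mid, collapse = ""), "c1", tail6)
}

.random_molecule <- function(max_carbons) {
  aromatic <- max_carbons >= 6L && stats::runif(1) < 0.35
  n_subs <- sample(0:3, 1L, prob = c(0.25, 0.40, 0.25, 0.10))
  budget <- max_carbons
  if (aromatic) budget <- budget - 6L
  subs <- character(0)
  for (k in seq_len(n_subs)) {
    j <- sample(nrow(.substituents), 1L, prob = .substituents$weight)
    if (.substituents$carbons[j] > budget) next
    subs <- c(subs, .substituents$token[j])
    budget <- budget - .substituents$carbons[j]
  }
  if (aromatic) {
    tail_nc <- sample(0:min(budget, 4L), 1L)
    .random_aromatic(tail_nc, as.list(subs))
  } else {
    nc <- sample(seq_len(max(1L, min(budget, max_carbons))), 1L)
    .random_aliphatic(nc, subs)
  }
}

#' Generate random valid molecules
#'
#' Draws molecules from a fragment grammar (branched alkyl chains and
#' benzene rings decorated with OH, COOH, NH2 and halogen substituents), so
#' every output is a valid SMILES by construction. Outputs are unique under
#' canonical SMILES and deterministic for a given seed; carbon counts stay
#' within `[1, max_carbons]`.
#'
#' @param n number of molecules.
#' @param max_carbons maximum carbon count per molecule (>= 1).
#' @param seed integer seed.
#' @return character vector of `n` SMILES strings.
#' @export
generate_molecules <- function(n, max_carbons = 12L, seed = 1L) {
  stopifnot(n >= 0, max_carbons >= 1)
  if (n == 0L) return(character(0))
  .with_seed(seed, function() {
    out <- character(0)
    seen <- character(0)
    for (round in 1:60) {
      need <- n - length(out)
      if (need <= 0L) break
      cand <- vapply(seq_len(ceiling(need * 1.5) + 10L),
                     function(i) .random_molecule(max_carbons), "")
      canon <- canonicalize_smiles(cand, strict = TRUE)
      fresh <- !duplicated(canon) & !canon %in% seen
      out <- c(out, cand[fresh])
      seen <- c(seen, canon[fresh])
    }
    if (length(out) < n)
      stop("grammar space exhausted: could only generate ", length(out),
           " unique molecules with max_carbons = ", max_carbons,
           call. = FALSE)
    out[seq_len(n)]
  })
}

#' Label molecules with the planted logS model
#'
#' Computes functional-group counts by substructure matching on each parsed
#' molecule and assigns
#' `logS = intercept + sum(coef * count) + N(0, noise_sd)`, with the noise
#' drawn under `model$seed` (deterministic).
#'
#' @param smiles character vector of SMILES (all must parse).
#' @param model a [planted_model()].
#' @return data.frame `smiles, logS, source`; attribute `group_counts`
#'   carries the true design matrix, attribute `logS_true` the noiseless
#'   response (both for recovery tests).
#' @export
assign_logS <- function(smiles, model = planted_model()) {
  stopifnot(inherits(model, "planted_model"))
  counts <- count_functional_groups(smiles)
  if (anyNA(counts))
    stop("unparseable SMILES passed to assign_logS", call. = FALSE)
  mu <- model$intercept +
    as.numeric(counts %*% model$coefficients[colnames(counts)])
  eps <- .with_seed(model$seed, function()
    stats::rnorm(length(smiles), 0, model$noise_sd))
  out <- data.frame(smiles = smiles, logS = mu + eps,
                    source = "synthetic", stringsAsFactors = FALSE)
  attr(out, "group_counts") <- counts
  attr(out, "logS_true") <- mu
  out
}

#' Inject duplicate and conflicting records
#'
#' Exercises the curation rules: appends `n_exact` verbatim copies of
#' randomly chosen rows and `n_conflict` re-measurements of other randomly
#' chosen rows offset by `conflict_offset` log units (which must exceed the
#' curation tolerance, so those molecules are dropped as conflicts). The
#' exact-copy and conflict rows are drawn from disjoint molecules, so
#' [curate()] on the result reports exactly `n_exact` collapsed rows and
#' `n_conflict` conflict-dropped molecules.
#'
#' @param records data.frame with `smiles` and `logS` columns; SMILES must
#'   be unique molecules.
#' @param n_exact number of exact duplicate rows to add.
#' @param n_conflict number of conflicting re-measurements to add.
#' @param seed integer seed.
#' @param conflict_offset logS offset of the conflicting re-measurements.
#' @return the augmented data.frame (rows appended, order shuffled
#'   deterministically).
#' @export
inject_duplicates <- function(records, n_exact, n_conflict, seed = 1L,
                              conflict_offset = 1.0) {
  stopifnot(n_exact >= 0, n_conflict >= 0,
            n_exact + n_conflict <= nrow(records))
  if (n_exact + n_conflict == 0L) return(records)
  .with_seed(seed, function() {
    pick <- sample(nrow(records), n_exact + n_conflict)
    exact <- pick[seq_len(n_exact)]
    confl <- pick[n_exact + seq_len(n_conflict)]
    extra <- records[c(exact, confl), , drop = FALSE]
    if (n_conflict > 0L) {
      ii <- n_exact + seq_len(n_conflict)
      extra$logS[ii] <- extra$logS[ii] + conflict_offset
    }
    out <- rbind(records, extra)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a full synthetic solubility table
#'
#' Convenience wrapper: generate unique molecules, label them with the
#' planted model, and optionally inject duplicates/conflicts so the
#' curation stage has work to do. The same seed always reproduces the
#' identical table.
#'
#' @param n number of distinct molecules.
#' @param max_carbons carbon budget per molecule.
#' @param model a [planted_model()]; its seed is re-derived from `seed`.
#' @param n_exact,n_conflict duplicate/conflict rows to inject.
#' @param seed master seed for generation, labelling and injection.
#' @return list of class `"solubility_simulation"` with elements `table`
#'   (the molecule records data.frame), `model`, `group_counts`,
#'   `logS_true`.
#' @export
simulate_solubility_table <- function(n, max_carbons = 12L,
                                      model = planted_model(),
                                      n_exact = 0L, n_conflict = 0L,
                                      seed = 1L) {
  model$seed <- as.integer(seed) + 1L
  smiles <- generate_molecules(n, max_carbons, seed = seed)
  labelled <- assign_logS(smiles, model)
  tab <- inject_duplicates(labelled, n_exact, n_conflict,
                           seed = seed + 2L)
  structure(list(table = tab, model = model,
                 group_counts = attr(labelled, "group_counts"),
                 logS_true = attr(labelled, "logS_true"),
                 seed = as.integer(seed)),
            class = "solubility_simulation")
}

#' Write a simulation to disk
#'
#' Emits the molecule table in the CSV schema [read_molecule_table()]
#' expects, plus a JSON sidecar with the planted model (for recovery tests
#' only; the pipeline itself never reads it).
#'
#' @param sim a `"solubility_simulation"`.
#' @param path output CSV path; the sidecar goes to `<path>.model.json`.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  stopifnot(inherits(sim, "solubility_simulation"))
  utils::write.csv(sim$table, path, row.names = FALSE)
  jsonlite::write_json(
    list(intercept = sim$model$intercept,
         coefficients = as.list(sim$model$coefficients),
         noise_sd = sim$model$noise_sd, seed = sim$model$seed),
    paste0(path, ".model.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
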