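# SMILES handling and the internal molecular-graph representation.
#
# Parsing, canonicalization and SMARTS matching are delegated to OpenBabel
# (through ChemmineR/ChemmineOB); on top of the parsed connection table this
# file builds a light heavy-atom graph (element, charge, implicit hydrogen
# count, ring/aromatic flags, bond orders) that the descriptor engine and
# the Morgan fingerprinter consume.

#' Canonicalize SMILES strings
#'
#' Maps every spelling of a molecule to a single canonical SMILES string
#' (OpenBabel canonical form, aromaticity perceived), so that "OCC" and
#' "CCO", or "C1=CC=CC=C1" and "c1ccccc1", compare equal. Canonicalization
#' is a fixed point: applying it to its own output returns the same string.
#'
#' @param smiles character vector of SMILES strings.
#' @param strict if TRUE (default) an unparseable SMILES is an error
#'   carrying the offending string; if FALSE it yields NA, letting callers
#'   route failures into a provenance report.
#' @return character vector of canonical SMILES, same length as the input.
#' @examples
#' canonicalize_smiles(c("OCC", "CCO"))
#' @export
canonicalize_smiles <- function(smiles, strict = TRUE) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  if (n == 0L) return(character(0))
  out <- rep(NA_character_, n)
  blank <- !nzchar(trimws(smiles)) | is.na(smiles)
  idx <- which(!blank)
  if (length(idx)) {
    ids <- paste0("aq", idx)
    src <- paste(paste(smiles[idx], ids), collapse = "\n")
    res <- ChemmineOB::convertFormat("SMI", "CAN", source = src)
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    got_id <- vapply(parts, function(p) trimws(p[2]), "")
    got_smi <- vapply(parts, `[`, "", 1L)
    out[match(got_id, ids)] <- got_smi
  }
  if (strict && anyNA(out)) {
    bad <- smiles[is.na(out)]
    stop("unparseable SMILES: ", paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L),
         call. = FALSE)
  }
  out
}

#' Parse molecules into an internal molecule set
#'
#' Parses SMILES via OpenBabel and keeps, per molecule, both the SDF
#' connection table (for SMARTS matching and format export) and a
#' heavy-atom graph with element symbols, formal charges, implicit
#' hydrogen counts, ring membership and aromaticity flags. All downstream
#' featurization runs off this object so each molecule is parsed once.
#'
#' @param smiles character vector of SMILES.
#' @param strict passed to [canonicalize_smiles()]; with `strict = FALSE`
#'   unparseable entries are retained as failed slots (`ok(ms)` is FALSE).
#' @return an object of class `"mol_set"`.
#' @export
parse_molecules <- function(smiles, strict = TRUE) {
  if (inherits(smiles, "mol_set")) return(smiles)
  stopifnot(is.character(smiles))
  canonical <- canonicalize_smiles(smiles, strict = strict)
  ok <- !is.na(canonical)
  sdfs <- vector("list", length(smiles))
  graphs <- vector("list", length(smiles))
  # ChemmineR's SDF reader cannot represent single-atom molecules (methane,
  # water, ...); their connection tables are built directly instead.
  single <- ok & grepl("^([A-IK-Za-ik-z][a-z]?|\\[[^]]+\\])$", canonical)
  multi <- which(ok & !single)
  if (length(multi)) {
    ids <- paste0("aq", multi)
    sdfset <- ChemmineR::smiles2sdf(stats::setNames(smiles[multi], ids))
    for (j in seq_along(ids)) {
      i <- multi[j]
      sdfs[[i]] <- sdfset[[j]]
      graphs[[i]] <- .build_graph(sdfset[[j]])
    }
  }
  for (i in which(single)) {
    sdfs[[i]] <- .single_atom_sdf(canonical[i])
    graphs[[i]] <- .build_graph(sdfs[[i]])
  }
  structure(list(smiles = smiles, canonical = canonical, ok = ok,
                 sdf = sdfs, graph = graphs),
            class = "mol_set")
}

#' @export
print.mol_set <- function(x, ...) {
  cat(sprintf("<mol_set> %d molecules (%d parsed)\n",
              length(x$smiles), sum(x$ok)))
  invisible(x)
}

#' @export
length.mol_set <- function(x) length(x$smiles)

#' @export
`[.mol_set` <- function(x, i) {
  structure(list(smiles = x$smiles[i], canonical = x$canonical[i],
                 ok = x$ok[i], sdf = x$sdf[i], graph = x$graph[i]),
            class = "mol_set")
}

# SDFset over the parsed molecules, used for batched SMARTS queries
.mol_sdfset <- function(ms) {
  idx <- which(ms$ok)
  if (!length(idx)) stop("no valid molecules in set", call. = FALSE)
  sdfl <- ms$sdf[idx]
  ids <- paste0("aq", idx)
  methods::new("SDFset", SDF = sdfl, ID = ids)
}

.atomblock_cols <- c("C1", "C2", "C3", "C5", "C6", "C7", "C8", "C9", "C10",
                     "C11", "C12", "C13", "C14", "C15", "C16")
.bondblock_cols <- paste0("C", 1:7)

# hand-built SDF for a single-atom molecule, e.g. "C", "O", "[NH4+]"
.single_atom_sdf <- function(canonical) {
  token <- gsub("^\\[|\\]$", "", canonical)
  elem <- regmatches(token, regexpr("^[A-Za-z][a-z]?", token))
  elem <- paste0(toupper(substr(elem, 1, 1)), substring(elem, 2))
  chg_m <- regmatches(token, regexpr("[+-][0-9]*$", token))
  charge <- 0L
  if (length(chg_m) && nzchar(chg_m)) {
    k <- sub("^[+-]", "", chg_m)
    charge <- (if (k == "") 1L else as.integer(k)) *
      (if (substr(chg_m, 1, 1) == "+") 1L else -1L)
  }
  code <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `-1` = 5, `-2` = 6,
            `-3` = 7)[as.character(charge)]
  ab <- matrix(0, 1, length(.atomblock_cols),
               dimnames = list(paste0(elem, "_1"), .atomblock_cols))
  ab[1, "C6"] <- code
  bb <- matrix(numeric(0), 0, length(.bondblock_cols),
               dimnames = list(NULL, .bondblock_cols))
  methods::new("SDF",
               header = c(Molecule_Name = canonical, Source = "aquasol",
                          Comment = "",
                          Counts_Line = "  1  0  0  0  0  0  0  0  0  0999 V2000"),
               atomblock = ab, bondblock = bb, datablock = character(0))
}

# MOL-block charge codes -> formal charge
.charge_from_code <- function(code) {
  map <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
           `6` = -2, `7` = -3)
  unname(map[as.character(code)])
}

# default valence (for implicit-H inference) given element and charge;
# S and P pick the smallest standard valence that covers the bond sum
.implicit_h <- function(elem, charge, bondsum) {
  n <- length(elem)
  nh <- integer(n)
  for (i in seq_len(n)) {
    e <- elem[i]
    if (!e %in% .element_table$symbol || e == "H") next
    v <- .element_table[e, "valence"] + charge[i]
    if (e == "S") v <- min(c(2, 4, 6)[c(2, 4, 6) >= bondsum[i]], 6) + charge[i]
    if (e == "P") v <- min(c(3, 5)[c(3, 5) >= bondsum[i]], 5)
    nh[i] <- max(0, round(v - bondsum[i]))
  }
  nh
}

# Heavy-atom graph from a ChemmineR SDF object. Explicit hydrogens in the
# connection table are folded into the neighbouring heavy atom's H count.
.build_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  natoms <- length(elem)
  charge <- .charge_from_code(if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, natoms))
  if (is.null(dim(bb)) && length(bb)) bb <- matrix(bb, nrow = 1)
  bonds <- if (length(bb)) cbind(a = bb[, 1], b = bb[, 2], order = bb[, 3])
           else matrix(numeric(0), 0, 3, dimnames = list(NULL, c("a", "b", "order")))

  heavy <- elem != "H"
  new_idx <- cumsum(heavy)
  exp_h <- integer(natoms)
  keep <- rep(TRUE, nrow(bonds))
  for (k in seq_len(nrow(bonds))) {
    a <- bonds[k, 1]; b <- bonds[k, 2]
    if (!heavy[a] || !heavy[b]) {
      keep[k] <- FALSE
      if (heavy[a]) exp_h[a] <- exp_h[a] + 1L
      if (heavy[b]) exp_h[b] <- exp_h[b] + 1L
    }
  }
  bonds <- bonds[keep, , drop = FALSE]
  bonds[, 1] <- new_idx[bonds[, 1]]
  bonds[, 2] <- new_idx[bonds[, 2]]
  elem <- elem[heavy]; charge <- charge[heavy]; exp_h <- exp_h[heavy]
  n <- length(elem)

  bondsum <- numeric(n); degree <- integer(n)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds[k, 1]; b <- bonds[k, 2]; o <- bonds[k, 3]
    bondsum[a] <- bondsum[a] + o; bondsum[b] <- bondsum[b] + o
    degree[a] <- degree[a] + 1L; degree[b] <- degree[b] + 1L
    adj[[a]] <- c(adj[[a]], k); adj[[b]] <- c(adj[[b]], k)
  }
  nh <- .implicit_h(elem, charge, bondsum + exp_h) + exp_h

  rng <- .perceive_rings(sdf, new_idx, n)
  arom_bond <- logical(nrow(bonds))
  if (length(rng$aromatic_rings)) {
    for (ring in rng$aromatic_rings) {
      inr <- seq_len(nrow(bonds))[bonds[, 1] %in% ring & bonds[, 2] %in% ring]
      arom_bond[inr] <- TRUE
    }
  }

  list(n = n, elem = elem, charge = charge, nH = nh, degree = degree,
       orig_idx = which(heavy),
       bondsum = bondsum, in_ring = rng$in_ring, aromatic = rng$aromatic_atom,
       n_rings = rng$n_rings, n_aromatic_rings = rng$n_aromatic_rings,
       bonds = bonds, arom_bond = arom_bond, adj = adj)
}

# ring perception via ChemmineR; aromatic ring count restricted to rings of
# size <= 6 so fused-system envelope cycles are not double counted
.perceive_rings <- function(sdf, new_idx, n_heavy) {
  in_ring <- logical(n_heavy)
  aromatic_atom <- logical(n_heavy)
  aromatic_rings <- list()
  n_arom <- 0L
  rl <- tryCatch(ChemmineR::rings(sdf, upper = 14, type = "all", arom = TRUE),
                 error = function(e) NULL)
  rings <- if (is.null(rl)) list() else rl$RINGS
  aflag <- if (is.null(rl)) logical(0) else rl$AROMATIC
  for (j in seq_along(rings)) {
    at <- as.integer(sub("^.*_", "", rings[[j]]))
    at <- new_idx[at]
    in_ring[at] <- TRUE
    if (isTRUE(aflag[[j]])) {
      aromatic_atom[at] <- TRUE
      if (length(at) <= 6) {
        n_arom <- n_arom + 1L
        aromatic_rings[[length(aromatic_rings) + 1L]] <- at
      }
    }
  }
  # ring count = cyclomatic number of the heavy graph (computed later from
  # bonds); store the all-rings-derived quantities here
  list(in_ring = in_ring, aromatic_atom = aromatic_atom,
       n_rings = length(rings), n_aromatic_rings = n_arom,
       aromatic_rings = aromatic_rings)
}

#' Count SMARTS pattern occurrences per molecule
#'
#' Unique substructure match counts via OpenBabel SMARTS. Failed (unparsed)
#' molecules yield NA.
#'
#' @param molecules a `mol_set` or character vector of SMILES.
#' @param smarts a single SMARTS pattern.
#' @return integer vector of match counts, one per molecule.
#' @export
count_smarts <- function(molecules, smarts) {
  ms <- parse_molecules(molecules, strict = FALSE)
  out <- rep(NA_integer_, length(ms$smiles))
  if (!any(ms$ok)) return(out)
  obm <- .obmols(ms)
  hits <- ChemmineOB::smartsSearch_OB(obm, smarts, uniqueMatches = TRUE)
  out[ms$ok] <- as.integer(hits)
  out
}

# OBMol references for the valid molecules of a set (parsed from canonical
# SMILES, bypassing the SDF text representation, which cannot express
# single-atom molecules)
.obmols <- function(ms) {
  idx <- which(ms$ok)
  src <- paste(ms$canonical[idx], collapse = "\n")
  ChemmineOB::forEachMol("SMILES", src, function(mol) mol)
}

# functional-group feature names used by the planted synthetic model
.group_features <- c("n_carbon", "n_oh", "n_cooh", "n_nh2", "n_halogen",
                     "n_aromatic_ring")

#' Count the functional groups of the planted solubility model
#'
#' Computes, per molecule: carbon atoms, non-carboxyl hydroxyl groups,
#' carboxylic acids, primary amines, halogen atoms, and aromatic rings.
#' Counts are obtained by substructure matching on the parsed molecule, not
#' from any generator bookkeeping, so they are valid for arbitrary input.
#'
#' @param molecules a `mol_set` or character vector of SMILES.
#' @return integer matrix, one row per molecule, columns
#'   `n_carbon, n_oh, n_cooh, n_nh2, n_halogen, n_aromatic_ring`.
#' @export
count_functional_groups <- function(molecules) {
  ms <- parse_molecules(molecules, strict = FALSE)
  n <- length(ms$smiles)
  out <- matrix(NA_integer_, n, length(.group_features),
                dimnames = list(NULL, .group_features))
  out[, "n_oh"] <- count_smarts(ms, "[OX2H;!$([OX2H][CX3]=[OX1])]")
  out[, "n_cooh"] <- count_smarts(ms, "[CX3](=[OX1])[OX2H1]")
  out[, "n_nh2"] <- count_smarts(ms, "[NX3H2]")
  out[, "n_halogen"] <- count_smarts(ms, "[F,Cl,Br,I]")
  for (i in which(ms$ok)) {
    g <- ms$graph[[i]]
    out[i, "n_carbon"] <- sum(g$elem == "C")
    out[i, "n_aromatic_ring"] <- g$n_aromatic_rings
  }
  out
}

#' Molecular weight and carbon count
#'
#' Molecular weight (g/mol, implicit hydrogens included) and carbon atom
#' count derived from the parsed structure.
#'
#' @param molecules a `mol_set` or character vector of SMILES.
#' @return data.frame with columns `mw` and `n_carbon`.
#' @export
molecule_basics <- function(molecules) {
  ms <- parse_molecules(molecules, strict = FALSE)
  n <- length(ms$smiles)
  mw <- rep(NA_real_, n); nc <- rep(NA_integer_, n)
  for (i in which(ms$ok)) {
    g <- ms$graph[[i]]
    mass <- .element_prop(g$elem, "mass")
    mw[i] <- sum(mass, na.rm = FALSE) + sum(g$nH) * 1.008
    nc[i] <- sum(g$elem == "C")
  }
  data.frame(mw = mw, n_carbon = nc)
}

# Hill formula of a graph (implicit hydrogens included)
.graph_formula <- function(g) {
  counts <- table(g$elem)
  counts <- as.list(counts)
  h <- sum(g$nH) + (if (!is.null(counts$H)) counts$H else 0)
  counts$H <- NULL
  elems <- names(counts)
  ord <- c("C", setdiff(sort(elems, method = "radix"), "C"))
  ord <- ord[ord %in% elems]
  parts <- vapply(ord, function(e) {
    k <- counts[[e]]
    paste0(e, if (k > 1) k else "")
  }, "")
  if (h > 0) {
    hpart <- paste0("H", if (h > 1) h else "")
    if ("C" %in% elems) parts <- append(parts, hpart, after = 1L)
    else parts <- c(parts, hpart)  # no-carbon: alphabetical-ish, H appended
  }
  paste(parts, collapse = "")
}
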