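# Reading molecule tables and curating merged solubility sources.
#
# The curation rule mirrors how merged literature collections are cleaned:
# per molecule (canonical SMILES), repeated measurements that agree within a
# tolerance are collapsed to their mean, molecules whose measurements
# disagree beyond it are dropped entirely, and every input row is accounted
# for in a provenance report.

#' Read a molecule table from CSV
#'
#' Reads a CSV of molecules with configurable column names. Rows whose logS
#' cell does not parse as a finite number are returned in a `bad_rows`
#' attribute rather than silently dropped.
#'
#' @param path path to a CSV file (RFC-4180, header row).
#' @param column_map named character vector mapping the canonical names
#'   `smiles`, `logS` and (optionally) `source` to the file's column names.
#' @return data.frame with columns `smiles`, `logS`, `source`; attribute
#'   `bad_rows` holds the offending rows (original row numbers in
#'   `row.names`).
#' @export
read_molecule_table <- function(path,
                                column_map = c(smiles = "smiles",
                                               logS = "logS",
                                               source = "source")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0L) stop("empty molecule table: ", path, call. = FALSE)
  for (key in c("smiles", "logS")) {
    if (!column_map[[key]] %in% names(raw))
      stop("mapped column '", column_map[[key]], "' (", key,
           ") not present in ", path, call. = FALSE)
  }
  out <- data.frame(
    smiles = trimws(raw[[column_map[["smiles"]]]]),
    logS = suppressWarnings(as.numeric(raw[[column_map[["logS"]]]])),
    source = if (!is.na(column_map["source"]) &&
                 column_map[["source"]] %in% names(raw))
               raw[[column_map[["source"]]]] else NA_character_,
    stringsAsFactors = FALSE)
  bad <- !is.finite(out$logS)
  res <- out[!bad, , drop = FALSE]
  attr(res, "bad_rows") <- out[bad, , drop = FALSE]
  res
}

#' Curate a merged molecule table
#'
#' Canonicalizes SMILES, rejects salts/mixtures (SMILES containing "."),
#' groups records by canonical SMILES (stereochemistry retained), and per
#' group keeps one record with the mean logS when all measurements agree
#' within `conflict_tolerance` log units, or drops the molecule entirely
#' when they disagree. The returned provenance satisfies the conservation
#' identity `inputs = kept + collapsed + conflict rows + parse failures +
#' mixtures`.
#'
#' @param records data.frame with columns `smiles`, `logS` and optionally
#'   `source` (as from [read_molecule_table()]).
#' @param conflict_tolerance maximum spread (max minus min, log units)
#'   within which repeated measurements of one molecule count as one
#'   measure; default 0.01.
#' @return an object of class `"curated_dataset"`: a list with `records`
#'   (data.frame `smiles` (canonical), `logS`, `source`, `mw`, `n_carbon`)
#'   and `provenance` (named counts).
#' @examples
#' x <- data.frame(smiles = c("CCO", "OCC", "CO"), logS = c(-0.1, -0.1, 0.5))
#' curate(x)
#' @export
curate <- function(records, conflict_tolerance = 0.01) {
  stopifnot(is.data.frame(records),
            all(c("smiles", "logS") %in% names(records)),
            conflict_tolerance >= 0)
  n_in <- nrow(records)
  if (!"source" %in% names(records))
    records$source <- rep(NA_character_, n_in)
  if (n_in == 0L) {
    recs <- data.frame(smiles = character(0), logS = numeric(0),
                       source = character(0), mw = numeric(0),
                       n_carbon = integer(0), stringsAsFactors = FALSE)
    prov <- c(inputs = 0L, kept = 0L, collapsed = 0L,
              conflict_rows = 0L, conflict_molecules = 0L,
              parse_failures = 0L, mixtures = 0L)
    return(structure(list(records = recs, provenance = as.list(prov),
                          conflict_tolerance = conflict_tolerance),
                     class = "curated_dataset"))
  }
  mixture <- grepl(".", records$smiles, fixed = TRUE)
  canon <- rep(NA_character_, n_in)
  canon[!mixture] <- canonicalize_smiles(records$smiles[!mixture],
                                         strict = FALSE)
  failed <- !mixture & is.na(canon)
  usable <- !mixture & !failed

  kept_smiles <- character(0); kept_logs <- numeric(0)
  kept_source <- character(0)
  n_collapsed <- 0L; n_conflict_rows <- 0L; n_conflict_mol <- 0L
  if (any(usable)) {
    grp <- split(which(usable), canon[usable])
    # deterministic, order-insensitive output: sort by canonical SMILES
    # (radix = C byte order, independent of the session's collation locale)
    for (smi in sort(names(grp), method = "radix")) {
      rows <- grp[[smi]]
      vals <- records$logS[rows]
      if (max(vals) - min(vals) <= conflict_tolerance) {
        kept_smiles <- c(kept_smiles, smi)
        kept_logs <- c(kept_logs, mean(vals))
        src <- unique(records$source[rows])
        kept_source <- c(kept_source, paste(src[!is.na(src)], collapse = ";"))
        n_collapsed <- n_collapsed + length(rows) - 1L
      } else {
        n_conflict_rows <- n_conflict_rows + length(rows)
        n_conflict_mol <- n_conflict_mol + 1L
      }
    }
  }
  basics <- if (length(kept_smiles)) molecule_basics(kept_smiles)
            else data.frame(mw = numeric(0), n_carbon = integer(0))
  recs <- data.frame(smiles = kept_smiles, logS = kept_logs,
                     source = kept_source, mw = basics$mw,
                     n_carbon = basics$n_carbon, stringsAsFactors = FALSE)
  if (any(recs$n_carbon < 1 | recs$n_carbon > 12, na.rm = TRUE))
    warning("curated set extends beyond the 1-12 carbon range typical of ",
            "low molecular weight organics", call. = FALSE)
  prov <- list(inputs = n_in, kept = nrow(recs), collapsed = n_collapsed,
               conflict_rows = n_conflict_rows,
               conflict_molecules = n_conflict_mol,
               parse_failures = sum(failed), mixtures = sum(mixture))
  structure(list(records = recs, provenance = prov,
                 conflict_tolerance = conflict_tolerance),
            class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(paste0("<curated_dataset> %d molecules kept of %d input rows\n",
                     "  collapsed duplicates: %d rows; conflicts: %d molecules",
                     " (%d rows); parse failures: %d; mixtures: %d\n"),
              p$kept, p$inputs, p$collapsed, p$conflict_molecules,
              p$conflict_rows, p$parse_failures, p$mixtures))
  invisible(x)
}

#' Profile a curated dataset
#'
#' Summary of a curated dataset in the terms used to characterize merged
#' solubility collections: molecular weight distribution, counts of
#' compounds containing nitrogen, sulfur, halogens, hydroxyl groups and
#' aromatic rings, and the carbon-count range.
#'
#' @param dataset a `curated_dataset` (or a data.frame with a `smiles`
#'   column).
#' @param mw_breaks breakpoints for the molecular weight histogram.
#' @return list with `n`, `mw_mean`, `mw_bins` (named counts),
#'   `species_counts` (compounds containing N, S, halogen, OH, aromatic),
#'   `carbon_range` (min, max).
#' @export
profile_dataset <- function(dataset,
                            mw_breaks = c(0, 100, 150, 200, 250, 300, Inf)) {
  records <- if (inherits(dataset, "curated_dataset")) dataset$records
             else dataset
  if (NROW(records) == 0L) stop("empty dataset", call. = FALSE)
  ms <- parse_molecules(records$smiles, strict = FALSE)
  basics <- molecule_basics(ms)
  nN <- count_smarts(ms, "[#7]")
  nS <- count_smarts(ms, "[#16]")
  nHal <- count_smarts(ms, "[F,Cl,Br,I]")
  nOH <- count_smarts(ms, "[OX2H]")
  nArom <- vapply(seq_along(ms$smiles), function(i)
    if (ms$ok[i]) ms$graph[[i]]$n_aromatic_rings else NA_integer_, 1L)
  bins <- table(cut(basics$mw, breaks = mw_breaks, right = FALSE))
  list(n = nrow(records),
       mw_mean = mean(basics$mw, na.rm = TRUE),
       mw_bins = c(bins),
       species_counts = c(nitrogen = sum(nN > 0, na.rm = TRUE),
                          sulfur = sum(nS > 0, na.rm = TRUE),
                          halogen = sum(nHal > 0, na.rm = TRUE),
                          hydroxyl = sum(nOH > 0, na.rm = TRUE),
                          aromatic = sum(nArom > 0, na.rm = TRUE)),
       carbon_range = range(basics$n_carbon, na.rm = TRUE))
}

#' Write a curated dataset to disk
#'
#' Emits the curated CSV (`smiles, logS, source, mw, n_carbon`) and a JSON
#' provenance sidecar next to it.
#'
#' @param dataset a `curated_dataset`.
#' @param path output CSV path; the provenance report is written to the
#'   same path with extension `.provenance.json`.
#' @return `path`, invisibly.
#' @export
write_curated_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "curated_dataset"))
  utils::write.csv(dataset$records, path, row.names = FALSE)
  side <- sub("\\.csv$", "", path)
  jsonlite::write_json(dataset$provenance,
                       paste0(side, ".provenance.json"), auto_unbox = TRUE)
  invisible(path)
}
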