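# Element property tables used by the descriptor engine and the fragment
# thermodynamics. Restricted to the elements that occur in low molecular
# weight organics (the dataset this package targets); anything else yields
# NA properties and the affected descriptor columns are dropped by the
# pruning cascade.

.element_table <- data.frame(
  symbol = c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
  Z      = c(1, 6, 7, 8, 9, 15, 16, 17, 35, 53),
  # standard atomic weights (g/mol)
  mass   = c(1.008, 12.011, 14.007, 15.999, 18.998, 30.974, 32.06,
             35.45, 79.904, 126.904),
  # Sanderson electronegativity
  en_sanderson = c(2.592, 2.746, 3.194, 3.654, 4.000, 2.515, 2.957,
                   3.475, 3.219, 2.778),
  # atomic (element-additive) polarizability, angstrom^3
  polarizability = c(0.667, 1.760, 1.100, 0.802, 0.557, 3.630, 2.900,
                     2.180, 3.050, 5.350),
  # first ionization energy, eV
  ionization = c(13.598, 11.260, 14.534, 13.618, 17.423, 10.487,
                 10.360, 12.968, 11.814, 10.451),
  # van der Waals radius, angstrom (Bondi)
  vdw_radius = c(1.20, 1.70, 1.55, 1.52, 1.47, 1.80, 1.80, 1.75,
                 1.85, 1.98),
  # default valence used to infer implicit hydrogen counts
  valence = c(1, 4, 3, 2, 1, 3, 2, 1, 1, 1),
  # count of valence electrons (for Kier-Hall valence deltas)
  zv     = c(1, 4, 5, 6, 7, 5, 6, 7, 7, 7),
  stringsAsFactors = FALSE
)
rownames(.element_table) <- .element_table$symbol

.element_prop <- function(symbols, prop) {
  out <- .element_table[symbols, prop]
  unname(out)
}

# van der Waals volume from the radius, angstrom^3
.element_vdw_volume <- function(symbols) {
  r <- .element_prop(symbols, "vdw_radius")
  4 / 3 * pi * r^3
}

#' Summed atomic polarizability of a molecular formula
#'
#' Element-additive molecular polarizability: the sum over all atoms
#' (hydrogens included) of tabulated atomic polarizabilities in
#' angstrom^3. This is the alpha input of the fragment hydration
#' Gibbs-energy model, see [gibbs_energy()].
#'
#' @param formula a Hill-notation molecular formula string, e.g. "C2H6O".
#' @return numeric scalar, angstrom^3; NA if the formula contains an
#'   element outside the supported organic subset.
#' @examples
#' polarizability_from_formula("CH4")   # C + 4 H
#' @export
polarizability_from_formula <- function(formula) {
  counts <- .parse_formula(formula)
  if (any(!names(counts) %in% .element_table$symbol)) return(NA_real_)
  sum(.element_prop(names(counts), "polarizability") * counts)
}

# "C8H9NO2" -> c(C = 8, H = 9, N = 1, O = 2)
.parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  toks <- toks[nzchar(toks)]
  elems <- sub("[0-9]*$", "", toks)
  n <- as.integer(sub("^[A-Za-z]+", "", toks))
  n[is.na(n)] <- 1L
  tapply(n, elems, sum)
}
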