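# Per-fragment hydration thermodynamics: a linear free-energy estimate of
# the Gibbs energy of dissolution at 298 K from three physically
# interpretable quantities of a substructure -- its molecular
# polarizability and its hydrogen-bond donor/acceptor counts.

#' Gibbs energy of dissolution from fragment properties
#'
#' Linear free-energy relation
#' \deqn{\Delta G_{298} = -0.5 - 1.37\,\alpha + 3.84\,\Sigma C_a
#'       - 2.97\,\Sigma C_d}
#' with \eqn{\alpha} the molecular polarizability (cubic angstroms),
#' \eqn{\Sigma C_a} the hydrogen-bond acceptor count and \eqn{\Sigma C_d}
#' the donor count. More negative values indicate a more favourable
#' (solubilizing) contribution: polarizability and donor capacity drive
#' dissolution, acceptor sites oppose it under this parameterization.
#'
#' @param alpha molecular polarizability in cubic angstroms
#'   (non-negative).
#' @param ca hydrogen-bond acceptor count (non-negative).
#' @param cd hydrogen-bond donor count (non-negative).
#' @return Gibbs energy estimate (vectorized over the inputs).
#' @examples
#' gibbs_energy(0, 0, 0)    # -0.5
#' gibbs_energy(10, 1, 1)   # -13.33
#' @export
gibbs_energy <- function(alpha, ca, cd) {
  stopifnot(is.numeric(alpha), is.numeric(ca), is.numeric(cd))
  if (any(alpha < 0, na.rm = TRUE) || any(ca < 0, na.rm = TRUE) ||
      any(cd < 0, na.rm = TRUE))
    stop("alpha, ca and cd must be non-negative", call. = FALSE)
  b <- gibbs_coefficients()
  unname(b["intercept"] + b["alpha"] * alpha + b["ca"] * ca +
           b["cd"] * cd)
}

#' Coefficients of the Gibbs-energy relation
#'
#' The fixed coefficients of [gibbs_energy()], with the reported standard
#' errors attached as the `"se"` attribute. The uncertainties are carried
#' as metadata only and are not propagated into the energy estimate.
#'
#' @return named numeric vector `intercept, alpha, ca, cd` with attribute
#'   `se`.
#' @export
gibbs_coefficients <- function() {
  structure(c(intercept = -0.5, alpha = -1.37, ca = 3.84, cd = -2.97),
            se = c(intercept = 1.6, alpha = 0.06, ca = 0.25, cd = 0.26))
}

#' Physical properties of substructure fragments
#'
#' For each fragment (given as SMILES, e.g. from [bit_atlas()]), computes
#' the hydrogen-capped molecular formula, additive polarizability from the
#' per-element table (see [polarizability_from_formula()]), hydrogen-bond
#' acceptor count (nitrogen and oxygen atoms) and donor count (nitrogen or
#' oxygen atoms bearing at least one hydrogen), plus the resulting
#' [gibbs_energy()].
#'
#' Fragments are treated as hydrogen-capped molecules: open valences in
#' the parent molecule become hydrogens, so the polarizability includes
#' the caps.
#'
#' @param fragments character vector of fragment SMILES.
#' @return data.frame `fragment, formula, alpha, ca, cd, gibbs` with one
#'   row per fragment; unparseable fragments get NA property values.
#' @export
fragment_properties <- function(fragments) {
  stopifnot(is.character(fragments), length(fragments) > 0)
  ms <- parse_molecules(fragments, strict = FALSE)
  out <- data.frame(fragment = fragments, formula = NA_character_,
                    alpha = NA_real_, ca = NA_integer_, cd = NA_integer_,
                    gibbs = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(fragments)) {
    if (!ms$ok[i]) next
    g <- ms$graph[[i]]
    no <- g$elem %in% c("N", "O")
    out$formula[i] <- .graph_formula(g)
    out$alpha[i] <- polarizability_from_formula(out$formula[i])
    out$ca[i] <- sum(no)
    out$cd[i] <- sum(no & g$nH > 0)
    out$gibbs[i] <- gibbs_energy(out$alpha[i], out$ca[i], out$cd[i])
  }
  out
}

#' Fragment thermodynamics table for influential substructures
#'
#' Combines a bit atlas (or any named list/vector of fragment SMILES) with
#' the per-fragment Gibbs-energy estimate into a ranked table: the most
#' negative (most solubilizing) fragments first. Intended to be fed the
#' fragments behind the top SHAP-ranked fingerprint bits.
#'
#' @param fragments character vector of fragment SMILES; names (e.g. bit
#'   labels) are preserved in a `label` column.
#' @return data.frame `label, fragment, formula, alpha, ca, cd, gibbs`
#'   sorted by `gibbs` ascending (NAs last).
#' @export
fragment_thermo_table <- function(fragments) {
  labels <- if (!is.null(names(fragments))) names(fragments)
            else as.character(seq_along(fragments))
  props <- fragment_properties(unname(as.character(fragments)))
  out <- cbind(data.frame(label = labels, stringsAsFactors = FALSE), props)
  out <- out[order(out$gibbs, na.last = TRUE), ]
  rownames(out) <- NULL
  out
}
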