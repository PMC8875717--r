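# Hansen solubility parameter screening: Fedors group-contribution
# estimate for the solute, composition-weighted averaging for mixed
# solvents, and the total-parameter mismatch used as a compatibility
# screen (smaller |delta_solvent - delta_solute| suggests better
# miscibility).

#' Total solubility parameter by Fedors group contribution
#'
#' delta = sqrt(sum(count * E) / sum(count * V)) with E in J/mol and V
#' in cm^3/mol, giving MPa^0.5.
#'
#' @param counts named vector of group counts.
#' @param table group-contribution table with columns `group`, `E`, `V`;
#'   defaults to the shipped Fedors constants ([fedors_groups()]).
#' @return The total solubility parameter (MPa^0.5).
#' @examples
#' hsp_from_groups(dha_properties()$hsp_groups)
#' @export
hsp_from_groups <- function(counts, table = fedors_groups()) {
  if (is.null(names(counts)) || length(counts) == 0L)
    stop("'counts' must be a non-empty named vector")
  if (any(counts < 0)) stop("group counts must be non-negative")
  idx <- match(names(counts), table$group)
  if (anyNA(idx))
    stop("unknown group(s): ", paste(names(counts)[is.na(idx)], collapse = ", "))
  E <- sum(counts * table$E[idx])
  V <- sum(counts * table$V[idx])
  if (V <= 0) stop("total molar volume must be positive")
  sqrt(E / V)
}

#' Composition-averaged solubility parameter of a mixed solvent
#'
#' Weighted arithmetic mean of the pure-solvent parameters. The
#' averaging basis is the supplied weight (mass fractions for the study
#' systems, where the two bases coincide at the equimass midpoint).
#'
#' @param deltas pure-solvent total solubility parameters (MPa^0.5).
#' @param fractions non-negative weights summing to 1.
#' @return The mixed-solvent parameter (MPa^0.5).
#' @export
mixed_solvent_delta <- function(deltas, fractions) {
  if (length(deltas) != length(fractions))
    stop("'deltas' and 'fractions' must have the same length")
  if (any(deltas <= 0)) stop("'deltas' must be positive")
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("'fractions' must be non-negative and sum to 1")
  sum(fractions * deltas)
}

#' Solubility-parameter mismatch
#'
#' @param delta_solute,delta_solvent total solubility parameters
#'   (MPa^0.5), both > 0.
#' @return |delta_solvent - delta_solute|.
#' @export
delta_mismatch <- function(delta_solute, delta_solvent) {
  if (any(delta_solute <= 0) || any(delta_solvent <= 0))
    stop("solubility parameters must be positive")
  abs(delta_solvent - delta_solute)
}

#' Solubility-parameter screening table for the study systems
#'
#' Computes the solute's group-contribution parameter and tabulates the
#' mismatch against every pure solvent and every equimass pair.
#'
#' @param solute a [solute_properties] with `hsp_groups`.
#' @param solvent_deltas named vector of solvent parameters; defaults to
#'   [solvent_hsp()].
#' @param delta_solute optional solute parameter (MPa^0.5) overriding
#'   the group-contribution estimate (e.g. a rounded literature value).
#' @return A data.frame with columns `system`, `delta` and `mismatch`,
#'   with the solute's delta as attribute `"delta_solute"`.
#' @export
hsp_screen <- function(solute = dha_properties(),
                       solvent_deltas = solvent_hsp(),
                       delta_solute = NULL) {
  if (is.null(delta_solute) && is.null(solute$hsp_groups))
    stop("solute has no stored group counts")
  ds <- delta_solute %||% hsp_from_groups(solute$hsp_groups)
  nm <- names(solvent_deltas)
  pairs <- utils::combn(seq_along(solvent_deltas), 2)
  mix <- apply(pairs, 2, function(i)
    mixed_solvent_delta(solvent_deltas[i], c(0.5, 0.5)))
  out <- data.frame(
    system = c(nm, apply(pairs, 2, function(i) paste(nm[i], collapse = " + "))),
    delta = c(unname(solvent_deltas), mix))
  out$mismatch <- delta_mismatch(ds, out$delta)
  attr(out, "delta_solute") <- ds
  out
}
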