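# Apparent dissolution thermodynamics by van't Hoff regression of
# ln x on (1/T - 1/Thm), with Thm the harmonic mean experimental
# temperature. The recentring makes the intercept proportional to the
# Gibbs energy of solution at Thm while leaving the slope (hence the
# enthalpy) unchanged.

#' Harmonic mean temperature
#'
#' Thm = n / sum(1/Ti).
#'
#' @param T_K temperatures (K), all > 0.
#' @return The harmonic mean (K).
#' @export
harmonic_mean_T <- function(T_K) {
  if (length(T_K) < 1L || any(T_K <= 0))
    stop("'T_K' must be a non-empty vector of positive temperatures")
  length(T_K) / sum(1 / T_K)
}

#' van't Hoff regression of a solubility dataset
#'
#' Ordinary least squares of ln(x_exp) on (1/T - 1/Thm).
#'
#' @param data a [solubility_dataset] with at least 3 points.
#' @param Thm recentring temperature; defaults to the harmonic mean of
#'   the dataset's temperatures.
#' @return A list with `slope` (K), `intercept` and `Thm` (K).
#' @export
vanthoff_regression <- function(data, Thm = harmonic_mean_T(data$T_K)) {
  stopifnot(inherits(data, "solubility_dataset"))
  if (nrow(data) < 3L) stop("need at least 3 points")
  if (length(unique(data$T_K)) < 2L) stop("degenerate design: all T equal")
  z <- 1 / data$T_K - 1 / Thm
  fit <- stats::lm(log(data$x_exp) ~ z)
  cf <- stats::coef(fit)
  list(slope = unname(cf[2L]), intercept = unname(cf[1L]), Thm = Thm)
}

#' Dissolution thermodynamics from the van't Hoff regression
#'
#' dH = -R * slope; dG = -R * Thm * intercept; dS = (dH - dG)/Thm.
#'
#' @param slope regression slope (K).
#' @param intercept regression intercept.
#' @param Thm harmonic mean temperature (K).
#' @return A list with `dH` (J/mol), `dG` (J/mol), `dS` (J/(mol K)).
#' @export
solution_thermodynamics <- function(slope, intercept, Thm) {
  if (Thm <= 0) stop("'Thm' must be positive")
  dH <- -R_GAS * slope
  dG <- -R_GAS * Thm * intercept
  list(dH = dH, dG = dG, dS = (dH - dG) / Thm)
}

#' Enthalpy and entropy weights of the Gibbs energy of solution
#'
#' deltaH = dH / (dH + Thm dS) and deltaTS = Thm dS / (dH + Thm dS),
#' the fractional enthalpic and entropic contributions (plain ratios,
#' both contributions being positive for these systems).
#'
#' @param dH enthalpy of solution (J/mol).
#' @param dS entropy of solution (J/(mol K)).
#' @param Thm harmonic mean temperature (K).
#' @return A list with `deltaH` and `deltaTS` (summing to 1).
#' @export
enthalpy_entropy_weights <- function(dH, dS, Thm) {
  tot <- abs(dH) + abs(Thm * dS)
  if (tot <= 0) stop("both contributions are zero")
  list(deltaH = abs(dH) / tot, deltaTS = abs(Thm * dS) / tot)
}

#' Full dissolution-thermodynamics summary of a dataset
#'
#' Runs the van't Hoff regression and derives the apparent Gibbs energy,
#' enthalpy and entropy of solution and their weights.
#'
#' @param data a [solubility_dataset].
#' @return An object of class `sle_thermo`: a list with `system`, `Thm`
#'   (K), `slope` (K), `intercept`, `dG_kJ`, `dH_kJ` (kJ/mol), `dS_J`
#'   (J/(mol K)), `deltaH`, `deltaTS`.
#' @examples
#' solution_thermo(terpene_solubility("mono")[["p-cymene"]])
#' @export
solution_thermo <- function(data) {
  reg <- vanthoff_regression(data)
  th <- solution_thermodynamics(reg$slope, reg$intercept, reg$Thm)
  w <- enthalpy_entropy_weights(th$dH, th$dS, reg$Thm)
  structure(list(system = attr(data, "system"), Thm = reg$Thm,
                 slope = reg$slope, intercept = reg$intercept,
                 dG_kJ = th$dG / 1000, dH_kJ = th$dH / 1000, dS_J = th$dS,
                 deltaH = w$deltaH, deltaTS = w$deltaTS),
            class = "sle_thermo")
}

#' @export
print.sle_thermo <- function(x, ...) {
  cat("Dissolution thermodynamics:", x$system, "\n")
  cat(sprintf("  Thm = %.2f K   slope = %.4f K   intercept = %.4f\n",
              x$Thm, x$slope, x$intercept))
  cat(sprintf("  dG = %.4f kJ/mol   dH = %.4f kJ/mol   dS = %.4f J/(mol K)\n",
              x$dG_kJ, x$dH_kJ, x$dS_J))
  cat(sprintf("  deltaH = %.4f   deltaTS = %.4f\n", x$deltaH, x$deltaTS))
  invisible(x)
}

#' Thermodynamics table for several datasets
#'
#' @param datasets a named list of [solubility_dataset] objects.
#' @return A data.frame, one row per system, mirroring the layout
#'   intercept / slope / dG / dH / dS / deltaH / deltaTS.
#' @export
thermo_table <- function(datasets) {
  rows <- lapply(datasets, function(d) {
    th <- solution_thermo(d)
    data.frame(system = th$system, intercept = th$intercept,
               slope = th$slope, dG_kJ = th$dG_kJ, dH_kJ = th$dH_kJ,
               dS_J = th$dS_J, deltaH = th$deltaH, deltaTS = th$deltaTS)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
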