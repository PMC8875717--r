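#' Solute properties of dehydroabietic acid
#'
#' Solid-state constants and composition of dehydroabietic acid
#' (C20H28O2), the tricyclic aromatic resin acid whose solid-liquid
#' equilibrium this package models. The melting temperature and fusion
#' enthalpy come from DSC; two fusion-enthalpy values circulate for this
#' compound (17.19 and 19.17 kJ/mol), so the constant is overridable.
#'
#' @param dHfus fusion enthalpy in J/mol. Default 17190 (DSC value).
#' @return An object of class `solute_properties`: a list with `name`,
#'   `Tm` (melting temperature, K), `dHfus` (J/mol), `M` (molar mass,
#'   g/mol) and `hsp_groups` (named integer vector of Fedors group counts).
#' @examples
#' dha_properties()
#' @export
dha_properties <- function(dHfus = 17190) {
  solute_properties(
    name = "dehydroabietic acid", Tm = 443.22, dHfus = dHfus, M = 300.442,
    hsp_groups = c(CH3 = 4, CH2 = 5, CH = 2, C = 2, COOH = 1,
                   "benzene ring" = 1, ring = 2))
}

#' Construct solute properties
#'
#' @param name solute identifier.
#' @param Tm melting temperature (K), > 0.
#' @param dHfus fusion enthalpy (J/mol), > 0.
#' @param M molar mass (g/mol), > 0.
#' @param hsp_groups optional named vector of functional-group counts used
#'   for group-contribution solubility-parameter estimates.
#' @return An object of class `solute_properties`.
#' @export
solute_properties <- function(name, Tm, dHfus, M, hsp_groups = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(Tm) || length(Tm) != 1L || !is.finite(Tm) || Tm <= 0)
    stop("'Tm' must be a single positive number (K)")
  if (!is.numeric(dHfus) || length(dHfus) != 1L || !is.finite(dHfus) || dHfus <= 0)
    stop("'dHfus' must be a single positive number (J/mol)")
  if (!is.numeric(M) || length(M) != 1L || !is.finite(M) || M <= 0)
    stop("'M' must be a single positive number (g/mol)")
  if (!is.null(hsp_groups)) {
    if (is.null(names(hsp_groups)) || any(hsp_groups < 0))
      stop("'hsp_groups' must be a named vector of non-negative counts")
  }
  structure(list(name = name, Tm = Tm, dHfus = dHfus, M = M,
                 hsp_groups = hsp_groups),
            class = "solute_properties")
}

#' @export
print.solute_properties <- function(x, ...) {
  cat("Solute:", x$name, "\n")
  cat(sprintf("  Tm    = %.2f K\n  dHfus = %.0f J/mol\n  M     = %.3f g/mol\n",
              x$Tm, x$dHfus, x$M))
  if (!is.null(x$hsp_groups)) {
    cat("  groups:", paste(sprintf("%dx %s", x$hsp_groups, names(x$hsp_groups)),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

# Molar masses (g/mol) from molecular formulas; not printed in the source
# data tables, needed for mole-fraction bookkeeping.
.solvent_molar_masses <- c(
  "(-)-alpha-pinene"      = 136.234,  # C10H16
  "p-cymene"              = 134.218,  # C10H14
  "(-)-beta-caryophyllene" = 204.351  # C15H24
)

#' Molar masses of the terpene solvents
#'
#' @return Named numeric vector of molar masses (g/mol) for
#'   (-)-alpha-pinene, p-cymene and (-)-beta-caryophyllene.
#' @export
solvent_molar_masses <- function() .solvent_molar_masses

# Experimental mole-fraction solubility of dehydroabietic acid.
# Monosolvent scans: 12 temperatures each, P = 101.3 kPa.
.mono_data <- list(
  "(-)-alpha-pinene" = cbind(
    T_K = c(299.45, 303.55, 307.38, 311.40, 313.58, 318.00,
            322.16, 325.37, 328.40, 330.70, 333.24, 337.83),
    x_exp = c(0.09417, 0.10171, 0.11025, 0.11894, 0.12536, 0.13501,
              0.14751, 0.15607, 0.16499, 0.17197, 0.18171, 0.19733)),
  "p-cymene" = cbind(
    T_K = c(300.60, 305.84, 308.85, 311.54, 314.24, 318.77,
            321.54, 325.29, 328.20, 331.08, 334.75, 336.16),
    x_exp = c(0.17951, 0.18870, 0.19381, 0.19877, 0.20598, 0.21406,
              0.22128, 0.23048, 0.23874, 0.24592, 0.25801, 0.26287)),
  "(-)-beta-caryophyllene" = cbind(
    T_K = c(301.35, 304.60, 309.34, 313.25, 316.65, 319.75,
            323.60, 325.96, 328.53, 331.53, 333.93, 336.86),
    x_exp = c(0.09789, 0.10524, 0.11578, 0.12512, 0.13314, 0.14076,
              0.15004, 0.15626, 0.16307, 0.17201, 0.17997, 0.18976))
)

# Equimass (w1 = 0.5) binary-solvent scans: 12 temperatures each.
.binary_data <- list(
  "p-cymene + (-)-beta-caryophyllene" = cbind(
    T_K = c(295.54, 298.90, 303.24, 308.34, 313.28, 318.45,
            321.90, 325.75, 329.26, 332.24, 334.43, 337.75),
    x_exp = c(0.14409, 0.15020, 0.15784, 0.16867, 0.17961, 0.18941,
              0.19954, 0.21104, 0.22113, 0.22944, 0.23727, 0.24663)),
  "p-cymene + (-)-alpha-pinene" = cbind(
    T_K = c(297.45, 301.84, 303.67, 309.45, 313.55, 318.15,
            320.87, 324.46, 327.47, 330.85, 334.05, 338.75),
    x_exp = c(0.14197, 0.15089, 0.15530, 0.16693, 0.17713, 0.18642,
              0.19347, 0.20403, 0.21218, 0.22095, 0.23113, 0.24673)),
  "(-)-alpha-pinene + (-)-beta-caryophyllene" = cbind(
    T_K = c(295.15, 300.45, 303.57, 307.25, 313.07, 315.99,
            319.63, 323.93, 327.27, 331.14, 335.17, 339.46),
    x_exp = c(0.08338, 0.09577, 0.10417, 0.11507, 0.12970, 0.13747,
              0.14686, 0.15967, 0.16973, 0.18024, 0.19484, 0.20909))
)

# Composition scans: solubility at 9 solvent mass fractions, one
# (near-saturation) temperature per composition.
.scan_data <- list(
  "(-)-alpha-pinene + p-cymene (scan)" = cbind(
    w1 = seq(0.1, 0.9, by = 0.1),
    T_K = c(304.65, 309.45, 311.40, 313.45, 313.55, 314.25, 313.55, 314.95, 318.15),
    x_exp = c(0.18572, 0.18739, 0.18672, 0.18583, 0.17713, 0.17325,
              0.15997, 0.15047, 0.14841)),
  "p-cymene + (-)-beta-caryophyllene (scan)" = cbind(
    w1 = seq(0.1, 0.9, by = 0.1),
    T_K = c(323.50, 316.64, 317.95, 314.70, 313.28, 312.05, 311.20, 312.53, 313.30),
    x_exp = c(0.16368, 0.15576, 0.17055, 0.17427, 0.17961, 0.18090,
              0.18503, 0.19505, 0.20398)),
  "(-)-alpha-pinene + (-)-beta-caryophyllene (scan)" = cbind(
    w1 = seq(0.1, 0.9, by = 0.1),
    T_K = c(311.40, 312.40, 313.30, 315.55, 319.43, 319.75, 322.35, 324.05, 325.85),
    x_exp = c(0.12665, 0.12751, 0.12837, 0.13447, 0.14686, 0.14597,
              0.15191, 0.15619, 0.16078))
)

.split_solvents <- function(system) {
  nm <- sub(" \\(scan\\)$", "", system)
  strsplit(nm, " + ", fixed = TRUE)[[1]]
}

#' Built-in solubility datasets for dehydroabietic acid in terpene solvents
#'
#' The measured solid-liquid equilibrium data this package was validated
#' against: mole-fraction solubility of dehydroabietic acid in three
#' monosolvents (12 temperatures each), three equimass binary solvent
#' mixtures (12 temperatures each), and three solvent-composition scans
#' (9 mass fractions each), all at 101.3 kPa.
#'
#' @param which `"all"`, `"mono"`, `"binary"` or `"scan"`.
#' @return A named list of [solubility_dataset] objects.
#' @examples
#' ds <- terpene_solubility("mono")
#' ds[["p-cymene"]]
#' @export
terpene_solubility <- function(which = c("all", "mono", "binary", "scan")) {
  which <- match.arg(which)
  build <- function(raw) {
    lapply(names(raw), function(nm) {
      m <- as.data.frame(raw[[nm]])
      solvents <- .split_solvents(nm)
      solubility_dataset(
        T_K = m$T_K, x_exp = m$x_exp,
        system = nm,
        solvents = solvents,
        w1 = if ("w1" %in% names(m)) m$w1 else if (length(solvents) == 2L) 0.5 else 1,
        molar_masses = unname(.solvent_molar_masses[solvents]),
        pressure_kPa = 101.3)
    }) |> stats::setNames(names(raw))
  }
  out <- switch(which,
    mono   = build(.mono_data),
    binary = build(.binary_data),
    scan   = build(.scan_data),
    all    = c(build(.mono_data), build(.binary_data), build(.scan_data)))
  out
}

#' Fedors group-contribution constants
#'
#' Per-occurrence cohesive energy E (J/mol) and molar volume V (cm^3/mol)
#' for the functional groups needed to estimate the total Hansen
#' solubility parameter of dehydroabietic acid by the Fedors method.
#' "Ring" is the ring-closure correction and "benzene ring" the aromatic
#' ring treated as one unit; both volume corrections for CH and
#' quaternary C are negative, as usual for Fedors constants.
#'
#' @return A data.frame with columns `group`, `E` (J/mol), `V` (cm^3/mol).
#' @export
fedors_groups <- function() {
  path <- system.file("extdata", "fedors_groups.csv", package = "terpsle",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Total Hansen solubility parameters of the terpene solvents
#'
#' Literature total solubility parameters (MPa^0.5) for the three
#' solvents studied.
#'
#' @return Named numeric vector of delta_t values (MPa^0.5).
#' @export
solvent_hsp <- function() {
  c("(-)-alpha-pinene" = 17.6069,
    "p-cymene" = 18.0516,
    "(-)-beta-caryophyllene" = 17.7463)
}

#' UNIFAC-style subgroup volume and surface constants
#'
#' First-order subgroup van der Waals volume (R) and surface (Q)
#' constants used to build UNIQUAC structural parameters r and q by group
#' contribution, plus the group inventories assumed for dehydroabietic
#' acid and the three solvents.
#'
#' @return A data.frame with columns `group`, `R`, `Q`.
#' @seealso [uniquac_rq()]
#' @export
unifac_rq <- function() {
  path <- system.file("extdata", "unifac_rq.csv", package = "terpsle",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# First-order subgroup inventories for UNIQUAC r/q. The solute and the
# bicyclic terpenes are assigned by inspection of their structures;
# aromatic carbons split into ACH / substituted-or-fused AC.
.unifac_assignments <- list(
  "dehydroabietic acid" = c(CH3 = 4, CH2 = 5, CH = 2, C = 2, COOH = 1,
                            ACH = 3, AC = 3),
  "(-)-alpha-pinene" = c(CH3 = 3, CH2 = 2, CH = 2, C = 1, "CH=C" = 1),
  "p-cymene" = c(CH3 = 2, ACH = 4, ACCH3 = 1, ACCH = 1),
  "(-)-beta-caryophyllene" = c(CH3 = 3, CH2 = 5, CH = 2, C = 1,
                               "CH2=C" = 1, "CH=C" = 1)
)

#' Default UNIQUAC structural parameters for the study compounds
#'
#' @param compound one of `"dehydroabietic acid"`, `"(-)-alpha-pinene"`,
#'   `"p-cymene"`, `"(-)-beta-caryophyllene"`.
#' @return A list with `r` and `q`.
#' @export
compound_rq <- function(compound) {
  if (!compound %in% names(.unifac_assignments))
    stop("no stored group assignment for ", sQuote(compound))
  uniquac_rq(.unifac_assignments[[compound]])
}
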