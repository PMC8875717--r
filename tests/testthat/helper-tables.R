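# Printed calculated-solubility columns and reference values used by
# several test files (alpha-pinene monosolvent block).

tab1_apelblat_col <- c(0.09402, 0.10209, 0.11017, 0.11926, 0.12445, 0.13560,
                       0.14690, 0.15617, 0.16538, 0.17270, 0.18111, 0.19721)

tab4_apelblat_alpha <- c(A = -48.47524, B = 521.07863, C = 7.78171)

tab9_vanthoff <- data.frame(
  solvent = c("(-)-alpha-pinene", "p-cymene", "(-)-beta-caryophyllene"),
  A = c(4.14712, 1.88763, 3.85311),
  B = c(-1952.44054, -1088.87019, -1859.74233))

# Table-2 style reference: solvent total solubility parameters and the
# mismatch against the solute's reported delta of 20.7144 MPa^0.5.
tab2_delta <- c("(-)-alpha-pinene" = 17.6069, "p-cymene" = 18.0516,
                "(-)-beta-caryophyllene" = 17.7463)
tab2_mismatch <- c("(-)-alpha-pinene" = 3.1075, "p-cymene" = 2.6628,
                   "(-)-beta-caryophyllene" = 2.9681,
                   "p-cymene + (-)-beta-caryophyllene" = 2.8154,
                   "p-cymene + (-)-alpha-pinene" = 2.8851,
                   "(-)-alpha-pinene + (-)-beta-caryophyllene" = 3.0378)
tab2_mixed <- c("p-cymene + (-)-beta-caryophyllene" = 17.8990,
                "p-cymene + (-)-alpha-pinene" = 17.8293,
                "(-)-alpha-pinene + (-)-beta-caryophyllene" = 17.6766)

# Finite-difference Gibbs-Duhem residual for a binary gamma model.
gibbs_duhem_resid <- function(gamma_fun, x1 = 0.3, h = 1e-5) {
  lg1 <- function(x) log(gamma_fun(x)$gamma1)
  lg2 <- function(x) log(gamma_fun(x)$gamma2)
  x1 * (lg1(x1 + h) - lg1(x1 - h)) / (2 * h) +
    (1 - x1) * (lg2(x1 + h) - lg2(x1 - h)) / (2 * h)
}
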