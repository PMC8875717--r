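# Forward evaluation of the solubility models. All functions are
# vectorized over temperature and return mole fractions (or activity
# coefficients); parameter estimation lives in fit.R.

#' Gas constant (J/(mol K)) used throughout the package.
#' @export
R_GAS <- 8.314

#' Modified Apelblat solubility
#'
#' ln x = A + B/T + C ln T, the three-parameter empirical
#' solubility-temperature correlation.
#'
#' @param T_K absolute temperature(s), K.
#' @param A,B,C correlation parameters (B in K).
#' @return Mole-fraction solubility (unclipped; callers validate x < 1).
#' @examples
#' apelblat_x(299.45, A = -48.47524, B = 521.07863, C = 7.78171)
#' @export
apelblat_x <- function(T_K, A, B, C) {
  if (any(T_K <= 0)) stop("temperature must be positive")
  exp(A + B / T_K + C * log(T_K))
}

#' van't Hoff solubility
#'
#' ln x = A + B/T; the C = 0 special case of the Apelblat form.
#'
#' @param T_K absolute temperature(s), K.
#' @param A,B parameters (B in K).
#' @return Mole-fraction solubility.
#' @export
vanthoff_x <- function(T_K, A, B) apelblat_x(T_K, A, B, 0)

#' Buchowski lambda-h solubility
#'
#' Solves ln(1 + lambda (1 - x) / x) = lambda h (1/T - 1/Tm) for x in
#' closed form: x = lambda / (exp(lambda h (1/T - 1/Tm)) - 1 + lambda).
#'
#' @param T_K absolute temperature(s), K; must not exceed `Tm`.
#' @param lambda non-ideality parameter, > 0.
#' @param h enthalpy parameter (K).
#' @param Tm solute melting temperature (K).
#' @return Mole-fraction solubility; exactly 1 at `T_K = Tm`.
#' @export
lambdah_x <- function(T_K, lambda, h, Tm) {
  if (any(T_K <= 0)) stop("temperature must be positive")
  if (any(T_K > Tm)) stop("temperature must not exceed the melting point")
  if (lambda <= 0) stop("'lambda' must be positive")
  lambda / (exp(lambda * h * (1 / T_K - 1 / Tm)) - 1 + lambda)
}

#' Ideal solid-liquid equilibrium solubility
#'
#' The simplified Schroeder-van Laar relation with the heat-capacity
#' term neglected: ln(x gamma) = -(dHfus/R)(1/T - 1/Tm); at unit
#' activity coefficient x_ideal = exp(-(dHfus/R)(1/T - 1/Tm)).
#'
#' @param T_K absolute temperature(s), K; must not exceed `solute$Tm`.
#' @param solute a [solute_properties] object.
#' @return Ideal mole-fraction solubility.
#' @export
ideal_solubility <- function(T_K, solute) {
  stopifnot(inherits(solute, "solute_properties"))
  if (any(T_K <= 0)) stop("temperature must be positive")
  if (any(T_K > solute$Tm))
    stop("temperature must not exceed the melting point")
  exp(-(solute$dHfus / R_GAS) * (1 / T_K - 1 / solute$Tm))
}

#' NRTL activity coefficients for a binary mixture
#'
#' Local-composition model with interaction energies dg12, dg21 (J/mol)
#' and non-randomness parameter alpha: tau_ij = dg_ij/(R T),
#' G_ij = exp(-alpha tau_ij); component 1 is the solute.
#'
#' @param x1 mole fraction of component 1 (in `[0, 1]`).
#' @param T_K absolute temperature (K).
#' @param dg12,dg21 interaction energy parameters (J/mol).
#' @param alpha non-randomness parameter, default 0.3.
#' @return A list with `gamma1` and `gamma2`.
#' @export
nrtl_gamma <- function(x1, T_K, dg12, dg21, alpha = 0.3) {
  if (any(T_K <= 0)) stop("temperature must be positive")
  if (any(x1 < 0 | x1 > 1)) stop("'x1' must lie in [0, 1]")
  x2 <- 1 - x1
  tau12 <- dg12 / (R_GAS * T_K)
  tau21 <- dg21 / (R_GAS * T_K)
  G12 <- exp(-alpha * tau12)
  G21 <- exp(-alpha * tau21)
  ln_g1 <- x2^2 * (tau21 * (G21 / (x1 + x2 * G21))^2 +
                   tau12 * G12 / (x2 + x1 * G12)^2)
  ln_g2 <- x1^2 * (tau12 * (G12 / (x2 + x1 * G12))^2 +
                   tau21 * G21 / (x1 + x2 * G21)^2)
  list(gamma1 = exp(ln_g1), gamma2 = exp(ln_g2))
}

#' UNIQUAC structural parameters from subgroup counts
#'
#' r = sum(count * R_k), q = sum(count * Q_k) over the molecule's
#' first-order subgroups.
#'
#' @param counts named vector of subgroup counts.
#' @param table a data.frame with columns `group`, `R`, `Q`; defaults to
#'   the shipped subgroup table ([unifac_rq()]).
#' @return A list with `r` and `q`.
#' @examples
#' uniquac_rq(c(CH3 = 2, CH2 = 4))  # n-hexane
#' @export
uniquac_rq <- function(counts, table = unifac_rq()) {
  if (is.null(names(counts)) || length(counts) == 0L)
    stop("'counts' must be a non-empty named vector")
  if (any(counts < 0)) stop("group counts must be non-negative")
  idx <- match(names(counts), table$group)
  if (anyNA(idx))
    stop("unknown subgroup(s): ",
         paste(names(counts)[is.na(idx)], collapse = ", "))
  list(r = sum(counts * table$R[idx]), q = sum(counts * table$Q[idx]))
}

#' UNIQUAC activity coefficients for a binary mixture
#'
#' Combinatorial + residual activity coefficients with
#' tau_ij = exp(-du_ij/(R T)) and coordination number z; component 1 is
#' the solute.
#'
#' @param x1 mole fraction of component 1, strictly inside (0, 1).
#' @param T_K absolute temperature (K).
#' @param du12,du21 interaction energy parameters (J/mol).
#' @param r,q length-2 vectors of structural volume and surface
#'   parameters for components 1 and 2.
#' @param z coordination number (default 10).
#' @return A list with `gamma1` and `gamma2`.
#' @export
uniquac_gamma <- function(x1, T_K, du12, du21, r, q, z = 10) {
  if (any(T_K <= 0)) stop("temperature must be positive")
  if (length(r) != 2L || length(q) != 2L || any(r <= 0) || any(q <= 0))
    stop("'r' and 'q' must be positive length-2 vectors")
  if (any(x1 <= 0 | x1 >= 1)) stop("'x1' must lie strictly in (0, 1)")
  x <- rbind(x1, 1 - x1)
  phi <- x * r / colSums(x * r)[col(x)]
  theta <- x * q / colSums(x * q)[col(x)]
  l <- (z / 2) * (r - q) - (r - 1)
  tau21 <- exp(-du21 / (R_GAS * T_K))  # tau_21: j = 2 acting on i = 1
  tau12 <- exp(-du12 / (R_GAS * T_K))
  ln_g <- function(i) {
    j <- 3L - i
    tau_ji <- if (i == 1L) tau21 else tau12  # tau_{ji}
    tau_ij <- if (i == 1L) tau12 else tau21
    S_i <- theta[i, ] + theta[j, ] * tau_ji       # sum_k theta_k tau_ki
    S_j <- theta[j, ] + theta[i, ] * tau_ij
    comb <- log(phi[i, ] / x[i, ]) +
      (z / 2) * q[i] * log(theta[i, ] / phi[i, ]) +
      l[i] - (phi[i, ] / x[i, ]) * (x[i, ] * l[i] + x[j, ] * l[j])
    resid <- -q[i] * log(S_i) +
      q[i] * (1 - theta[i, ] / S_i - theta[j, ] * tau_ij / S_j)
    comb + resid
  }
  list(gamma1 = unname(exp(ln_g(1L))), gamma2 = unname(exp(ln_g(2L))))
}

#' Solve the solid-liquid equilibrium for the saturation mole fraction
#'
#' Finds x such that x * gamma1(x, T) = x_ideal(T) by damped fixed-point
#' iteration x <- x_ideal / gamma1(x), where x_ideal is
#' [ideal_solubility()]. Used to turn an activity-coefficient model into
#' a solubility curve.
#'
#' @param gamma1_fun function of (x, T_K) returning the solute activity
#'   coefficient.
#' @param T_K absolute temperature (K, scalar).
#' @param solute a [solute_properties] object.
#' @param tol convergence tolerance on successive iterates (the damped
#'   iteration contracts by at least 1/2, so the final error is of the
#'   same order as the last step).
#' @param max_iter iteration cap.
#' @return The saturation mole fraction.
#' @export
sle_solve_x <- function(gamma1_fun, T_K, solute, tol = 1e-12,
                        max_iter = 2000L) {
  x_id <- ideal_solubility(T_K, solute)
  x <- min(x_id, 0.5)
  for (it in seq_len(max_iter)) {
    g <- gamma1_fun(x, T_K)
    x_new <- x_id / g
    x_new <- min(max(x_new, 1e-12), 1 - 1e-12)
    x_new <- 0.5 * (x + x_new)  # damping stabilizes strongly non-ideal cases
    if (abs(x_new - x) < tol) return(x_new)
    x <- x_new
  }
  stop(sprintf(
    "SLE fixed-point iteration did not converge (last x = %.6g, step = %.3g)",
    x, abs(x_new - x)))
}

#' Modified Wilson mixed-solvent solubility
#'
#' Mixing rule expressing the solubility in a binary solvent from the
#' pure-solvent solubilities at the same temperature:
#' -ln xm = 1 - w1 (1 + ln x1)/(w1 + w2 L12) - w2 (1 + ln x2)/(w2 + w1 L21).
#'
#' @param w1 mass fraction of solvent 1 in the solvent mixture.
#' @param x1_pure,x2_pure solubility in pure solvent 1 and 2 at the same
#'   temperature.
#' @param lam12,lam21 cross parameters.
#' @return Mixed-solvent mole-fraction solubility xm.
#' @export
wilson_xm <- function(w1, x1_pure, x2_pure, lam12, lam21) {
  if (any(w1 < 0 | w1 > 1)) stop("'w1' must lie in [0, 1]")
  if (any(x1_pure <= 0 | x1_pure >= 1) || any(x2_pure <= 0 | x2_pure >= 1))
    stop("pure-solvent solubilities must lie strictly in (0, 1)")
  n <- max(length(w1), length(x1_pure), length(x2_pure))
  w1 <- rep_len(w1, n)
  x1_pure <- rep_len(x1_pure, n)
  x2_pure <- rep_len(x2_pure, n)
  w2 <- 1 - w1
  d1 <- w1 + w2 * lam12
  d2 <- w2 + w1 * lam21
  if (any(abs(d1) < 1e-12 & w1 > 0) || any(abs(d2) < 1e-12 & w2 > 0))
    stop("singular Wilson denominator (w1 + w2*lam12 or w2 + w1*lam21 ~ 0)")
  t1 <- t2 <- numeric(n)
  t1[w1 > 0] <- (w1 * (1 + log(x1_pure)) / d1)[w1 > 0]
  t2[w2 > 0] <- (w2 * (1 + log(x2_pure)) / d2)[w2 > 0]
  exp(-(1 - t1 - t2))
}

#' Wilson-van't Hoff mixed-solvent solubility
#'
#' [wilson_xm()] with the pure-solvent solubilities supplied by van't
#' Hoff curves ln x_i = A_i + B_i/T fitted to the pure-solvent data.
#'
#' @param w1 mass fraction of solvent 1.
#' @param T_K absolute temperature(s), K.
#' @param A1,B1,A2,B2 van't Hoff parameters of the two pure solvents.
#' @param lam12,lam21 cross parameters.
#' @return Mixed-solvent mole-fraction solubility xm.
#' @export
wilson_vanthoff_xm <- function(w1, T_K, A1, B1, A2, B2, lam12, lam21) {
  if (any(T_K <= 0)) stop("temperature must be positive")
  x1 <- vanthoff_x(T_K, A1, B1)
  x2 <- vanthoff_x(T_K, A2, B2)
  wilson_xm(w1, pmin(x1, 1 - 1e-12), pmin(x2, 1 - 1e-12), lam12, lam21)
}
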