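# Nonlinear least-squares estimation of the solubility models and the
# deviation metrics used to judge them. The objective is the sum of
# squared deviations in mole-fraction space (the scale on which RMSD and
# RSS are defined); the two-parameter van't Hoff model is instead fitted
# by ordinary least squares on ln x, the convention under which its
# parameters double as the dissolution-thermodynamics regression.

#' Deviation metrics between experimental and calculated solubility
#'
#' @param x_exp experimental mole fractions (> 0).
#' @param x_cal calculated mole fractions, same length.
#' @return A list with `rd` (signed relative deviations
#'   (x_exp - x_cal)/x_exp), `ard` (mean absolute relative deviation),
#'   `rmsd` (root-mean-square deviation in x) and `rss` (residual sum of
#'   squares in x).
#' @examples
#' deviation_metrics(c(0.1, 0.2), c(0.09, 0.21))
#' @export
deviation_metrics <- function(x_exp, x_cal) {
  if (length(x_exp) != length(x_cal))
    stop("'x_exp' and 'x_cal' must have the same length")
  if (length(x_exp) < 1L) stop("need at least one point")
  if (any(x_exp <= 0)) stop("experimental values must be positive")
  rd <- (x_exp - x_cal) / x_exp
  rss <- sum((x_exp - x_cal)^2)
  list(rd = rd, ard = mean(abs(rd)),
       rmsd = sqrt(rss / length(x_exp)), rss = rss)
}

#' Fitting control options
#'
#' @param tol convergence tolerance passed to the Levenberg-Marquardt
#'   optimizer.
#' @param max_iter maximum optimizer iterations per start.
#' @param sle_tol tolerance of the solid-liquid-equilibrium fixed point
#'   used inside activity-coefficient model fits.
#' @param gamma_grid multistart grid (J/mol) applied with both signs to
#'   each interaction parameter of the NRTL and UNIQUAC models.
#' @param wilson_grid multistart values for each Wilson cross parameter.
#' @return A list of class `sle_control`.
#' @export
sle_control <- function(tol = 1e-12, max_iter = 200L, sle_tol = 1e-12,
                        gamma_grid = c(500, 1000, 3000, 6000),
                        wilson_grid = c(-3, -0.5, 0.5, 1, 3)) {
  structure(list(tol = tol, max_iter = max_iter, sle_tol = sle_tol,
                 gamma_grid = gamma_grid, wilson_grid = wilson_grid),
            class = "sle_control")
}

.sle_models <- c("apelblat", "lambdah", "vanthoff", "nrtl", "uniquac",
                 "wilson", "wilson_vanthoff")

# Vectorized damped fixed point for x*gamma1(x,T) = x_ideal(T) over a
# whole temperature grid at once (scalar interface: sle_solve_x).
.sle_curve <- function(gamma1_fun, T_K, solute, tol = 1e-12,
                       max_iter = 2000L) {
  x_id <- ideal_solubility(T_K, solute)
  x <- pmin(x_id, 0.5)
  for (it in seq_len(max_iter)) {
    x_new <- x_id / gamma1_fun(x, T_K)
    x_new <- pmin(pmax(x_new, 1e-12), 1 - 1e-12)
    x_new <- 0.5 * (x + x_new)
    if (max(abs(x_new - x)) < tol) return(x_new)
    x <- x_new
  }
  stop("SLE fixed-point iteration did not converge on the curve")
}

# Mole-fraction-weighted pseudo-component r/q for a binary solvent
# treated as a single UNIQUAC component.
.pseudo_rq <- function(solvents, w1, molar_masses) {
  rq <- lapply(solvents, compound_rq)
  if (length(solvents) == 1L) return(rq[[1L]])
  n <- c(w1, 1 - w1) / molar_masses
  f <- n / sum(n)
  list(r = f[1L] * rq[[1L]]$r + f[2L] * rq[[2L]]$r,
       q = f[1L] * rq[[1L]]$q + f[2L] * rq[[2L]]$q)
}

#' Fit a solubility model to a dataset
#'
#' Estimates the parameters of one of the implemented
#' solubility-temperature models from a [solubility_dataset] by
#' deterministic multistart Levenberg-Marquardt least squares, and
#' returns a fitted-model object carrying the deviation metrics used to
#' compare models (ARD, RMSD, RSS).
#'
#' Models: `"apelblat"` (ln x = A + B/T + C ln T), `"lambdah"`
#' (Buchowski), `"vanthoff"` (ln x = A + B/T), `"nrtl"` and `"uniquac"`
#' (activity-coefficient models closed with the ideal solid-liquid
#' equilibrium relation, fitted through [sle_solve_x()]), `"wilson"` and
#' `"wilson_vanthoff"` (binary-solvent mixing rules over pure-solvent
#' solubility curves).
#'
#' The default objective is ordinary least squares on ln x
#' (`objective = "logx"`) for `"apelblat"` and `"vanthoff"` — the
#' convention under which the van't Hoff parameters double as the
#' dissolution-thermodynamics regression, and the one these empirical
#' log-linear models are conventionally fitted with — and the residual
#' sum of squares in mole-fraction space (`objective = "x"`, the scale
#' on which RMSD/RSS/AIC are reported) for every other model. Either
#' objective can be forced for any model.
#'
#' @param data a [solubility_dataset] (at least one more point than the
#'   model has parameters).
#' @param model model name, see Details.
#' @param solute a [solute_properties] object; needed by `"lambdah"`,
#'   `"nrtl"` and `"uniquac"`.
#' @param objective `"x"` or `"logx"`; see Details.
#' @param pure_fits for the Wilson-family models: a list of two fitted
#'   models (class `sle_fit`) for the solubility in each pure solvent.
#'   Defaults to fits of the built-in pure-solvent data: Apelblat curves
#'   for `"wilson"`, van't Hoff curves for `"wilson_vanthoff"`.
#' @param rq optional list overriding the UNIQUAC structural parameters:
#'   `list(solute = list(r=, q=), solvent = list(r=, q=))`.
#' @param control a [sle_control()] list.
#' @return An object of class `sle_fit` with components `model`,
#'   `params` (named vector of the free parameters), `fixed` (fixed
#'   context such as alpha, Tm, r/q or pure-solvent parameters),
#'   `x_cal`, `rd`, `ard`, `rmsd`, `rss`, `n`, `k`, `converged`, `data`,
#'   `starts` (per-start RSS trace).
#' @examples
#' ds <- terpene_solubility("mono")[["(-)-alpha-pinene"]]
#' fit <- fit_solubility(ds, "apelblat")
#' summary(fit)
#' @export
fit_solubility <- function(data, model = .sle_models,
                           solute = dha_properties(),
                           objective = NULL, pure_fits = NULL, rq = NULL,
                           control = sle_control()) {
  stopifnot(inherits(data, "solubility_dataset"))
  model <- match.arg(model)
  if (is.null(objective))
    objective <- if (model %in% c("apelblat", "vanthoff")) "logx" else "x"
  objective <- match.arg(objective, c("x", "logx"))
  T_K <- data$T_K
  x_exp <- data$x_exp
  n <- length(x_exp)
  w1 <- if ("w1" %in% names(data)) data$w1 else attr(data, "w1")
  spec <- .model_spec(model, data, solute, pure_fits, rq, control)
  if (n <= length(spec$start[[1L]]))
    stop("need more points than free parameters (n = ", n, ")")

  resid_fun <- function(par) {
    x_cal <- tryCatch(spec$xfun(par, T_K, w1),
                      error = function(e) rep(NA_real_, n))
    if (anyNA(x_cal) || any(x_cal <= 0)) return(rep(1e3, n))
    if (objective == "x") x_exp - x_cal else log(x_exp) - log(x_cal)
  }

  if (!is.null(spec$closed_form)) {
    best <- spec$closed_form(T_K, x_exp, objective)
  } else {
    runs <- lapply(spec$start, function(s) {
      fit <- tryCatch(
        minpack.lm::nls.lm(
          par = s, fn = resid_fun,
          lower = spec$lower, upper = spec$upper,
          control = minpack.lm::nls.lm.control(
            ftol = control$tol, ptol = control$tol,
            maxiter = control$max_iter)),
        error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      list(par = stats::setNames(fit$par, names(s)),
           rss = sum(resid_fun(fit$par)^2),
           converged = fit$info %in% 1:4)
    })
    runs <- Filter(Negate(is.null), runs)
    if (!length(runs)) stop("all optimizer starts failed for model ", model)
    ord <- order(vapply(runs, `[[`, 0, "rss"),
                 vapply(runs, function(r) paste(format(r$par, digits = 12),
                                                collapse = ","), ""))
    best <- runs[[ord[1L]]]
    best$starts <- data.frame(
      start = seq_along(runs),
      rss = vapply(runs, `[[`, 0, "rss"),
      converged = vapply(runs, `[[`, TRUE, "converged"))
  }

  x_cal <- spec$xfun(best$par, T_K, w1)
  dm <- deviation_metrics(x_exp, x_cal)
  structure(list(model = model, params = best$par, fixed = spec$fixed,
                 x_cal = x_cal, rd = dm$rd, ard = dm$ard, rmsd = dm$rmsd,
                 rss = dm$rss, n = n, k = length(best$par),
                 converged = isTRUE(best$converged),
                 objective = objective, data = data, solute = solute,
                 starts = best$starts, xfun = spec$xfun),
            class = "sle_fit")
}

# Per-model definition: start list, bounds, x(par, T, w1) and any fixed
# context. Initialization: Apelblat/van't Hoff from the exact log-space
# OLS solution; lambda-h from the ideal-solution values (lambda = 1,
# h = dHfus/R); activity models from a coarse signed grid.
.model_spec <- function(model, data, solute, pure_fits, rq, control) {
  T_K <- data$T_K; x_exp <- data$x_exp
  switch(model,
    apelblat = {
      ols <- stats::lm(log(x_exp) ~ I(1 / T_K) + log(T_K))
      init <- stats::setNames(as.numeric(stats::coef(ols)), c("A", "B", "C"))
      vh <- stats::lm(log(x_exp) ~ I(1 / T_K))
      init2 <- c(A = unname(stats::coef(vh)[1L]),
                 B = unname(stats::coef(vh)[2L]), C = 0)
      list(start = list(init, init2),
           lower = rep(-Inf, 3), upper = rep(Inf, 3),
           xfun = function(p, T_K, w1) apelblat_x(T_K, p[1L], p[2L], p[3L]),
           fixed = NULL)
    },
    vanthoff = {
      list(start = list(c(A = 0, B = -1000)),
           lower = rep(-Inf, 2), upper = rep(Inf, 2),
           xfun = function(p, T_K, w1) vanthoff_x(T_K, p[1L], p[2L]),
           fixed = NULL,
           closed_form = function(T_K, x_exp, objective) {
             fit <- stats::lm(log(x_exp) ~ I(1 / T_K))
             par <- stats::setNames(as.numeric(stats::coef(fit)), c("A", "B"))
             if (objective == "x") {
               lm_fit <- minpack.lm::nls.lm(
                 par = par,
                 fn = function(p) x_exp - vanthoff_x(T_K, p[1L], p[2L]))
               par <- stats::setNames(lm_fit$par, c("A", "B"))
             }
             list(par = par, converged = TRUE, starts = NULL)
           })
    },
    lambdah = {
      h0 <- solute$dHfus / R_GAS
      starts <- expand.grid(lambda = c(0.2, 0.6, 1, 2),
                            h = c(1000, h0, 5000))
      list(start = lapply(seq_len(nrow(starts)), function(i)
             c(lambda = starts$lambda[i], h = starts$h[i])),
           lower = c(1e-6, 1), upper = c(50, 1e6),
           xfun = function(p, T_K, w1) lambdah_x(T_K, p[1L], p[2L], solute$Tm),
           fixed = list(Tm = solute$Tm))
    },
    nrtl = {
      g <- c(-rev(control$gamma_grid), control$gamma_grid)
      starts <- expand.grid(dg12 = g, dg21 = g)
      list(start = lapply(seq_len(nrow(starts)), function(i)
             c(dg12 = starts$dg12[i], dg21 = starts$dg21[i])),
           lower = c(-5e4, -5e4), upper = c(5e4, 5e4),
           xfun = function(p, T_K, w1)
             .sle_curve(function(x, Tv)
               nrtl_gamma(x, Tv, p[1L], p[2L])$gamma1,
               T_K, solute, tol = control$sle_tol),
           fixed = list(alpha = 0.3, Tm = solute$Tm, dHfus = solute$dHfus))
    },
    uniquac = {
      solvents <- attr(data, "solvents")
      if (is.null(rq)) {
        w1s <- attr(data, "w1")
        rq <- list(solute = compound_rq(solute$name),
                   solvent = .pseudo_rq(solvents,
                                        if (is.na(w1s)) 0.5 else w1s,
                                        attr(data, "molar_masses")))
      }
      rvec <- c(rq$solute$r, rq$solvent$r)
      qvec <- c(rq$solute$q, rq$solvent$q)
      g <- c(-rev(control$gamma_grid), control$gamma_grid)
      starts <- expand.grid(du12 = g, du21 = g)
      list(start = lapply(seq_len(nrow(starts)), function(i)
             c(du12 = starts$du12[i], du21 = starts$du21[i])),
           lower = c(-5e4, -5e4), upper = c(5e4, 5e4),
           xfun = function(p, T_K, w1)
             .sle_curve(function(x, Tv)
               uniquac_gamma(pmin(pmax(x, 1e-10), 1 - 1e-10), Tv,
                             p[1L], p[2L], rvec, qvec)$gamma1,
               T_K, solute, tol = control$sle_tol),
           fixed = list(r = rvec, q = qvec, z = 10,
                        Tm = solute$Tm, dHfus = solute$dHfus))
    },
    wilson = ,
    wilson_vanthoff = {
      solvents <- attr(data, "solvents")
      if (length(solvents) != 2L)
        stop("Wilson-family models need a binary-solvent dataset")
      if (is.null(pure_fits)) {
        mono <- terpene_solubility("mono")
        if (!all(solvents %in% names(mono)))
          stop("no built-in pure-solvent data for ",
               paste(setdiff(solvents, names(mono)), collapse = ", "),
               "; supply 'pure_fits'")
        pure_model <- if (model == "wilson") "apelblat" else "vanthoff"
        pure_fits <- lapply(mono[solvents], fit_solubility,
                            model = pure_model, solute = solute,
                            control = control)
      }
      x_pure <- function(i, T_K)
        pmin(predict(pure_fits[[i]], T_K), 1 - 1e-12)
      starts <- expand.grid(lam12 = control$wilson_grid,
                            lam21 = control$wilson_grid)
      list(start = lapply(seq_len(nrow(starts)), function(i)
             c(lam12 = starts$lam12[i], lam21 = starts$lam21[i])),
           lower = c(-50, -50), upper = c(50, 50),
           xfun = function(p, T_K, w1)
             wilson_xm(w1, x_pure(1L, T_K), x_pure(2L, T_K), p[1L], p[2L]),
           fixed = list(pure_model = pure_fits[[1L]]$model,
                        pure_params = lapply(pure_fits, `[[`, "params")))
    },
    stop("unknown model ", sQuote(model)))
}

#' @export
print.sle_fit <- function(x, ...) {
  cat(sprintf("Solubility fit: %s model on %s (n = %d)\n",
              x$model, attr(x$data, "system"), x$n))
  cat("  parameters:\n")
  print(round(x$params, 5))
  cat(sprintf("  100*ARD = %.5f   10^3*RMSD = %.5f\n",
              100 * x$ard, 1000 * x$rmsd))
  invisible(x)
}

#' @export
summary.sle_fit <- function(object, ...) {
  out <- list(fit = object,
              table = data.frame(T_K = object$data$T_K,
                                 x_exp = object$data$x_exp,
                                 x_cal = object$x_cal,
                                 RD = object$rd))
  class(out) <- "summary.sle_fit"
  out
}

#' @export
print.summary.sle_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  RSS = %.6g   AIC = %.4f   converged: %s\n",
              x$fit$rss, aic_rss(x$fit$rss, x$fit$n, x$fit$k),
              x$fit$converged))
  cat("\nPer-point comparison:\n")
  print(transform(x$table, x_cal = round(x_cal, 5), RD = round(RD, 5)),
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.sle_fit <- function(object, ...) object$params

#' @export
fitted.sle_fit <- function(object, ...) object$x_cal

#' @export
residuals.sle_fit <- function(object, type = c("x", "relative"), ...) {
  type <- match.arg(type)
  if (type == "x") object$data$x_exp - object$x_cal else object$rd
}

#' Predict solubility from a fitted model
#'
#' @param object an `sle_fit` object.
#' @param newdata temperatures (K) as a numeric vector, or a data.frame
#'   with column `T_K` (and `w1` for Wilson-family fits). Defaults to
#'   the fitted temperatures.
#' @param w1 solvent mass fraction(s) for Wilson-family fits; defaults
#'   to the fitted dataset's composition.
#' @param ... unused.
#' @return Predicted mole-fraction solubilities.
#' @export
predict.sle_fit <- function(object, newdata = NULL, w1 = NULL, ...) {
  if (is.null(newdata)) return(object$x_cal)
  if (is.data.frame(newdata)) {
    T_K <- newdata$T_K
    if (is.null(w1) && "w1" %in% names(newdata)) w1 <- newdata$w1
  } else T_K <- as.numeric(newdata)
  if (is.null(w1)) {
    w1 <- attr(object$data, "w1")
    if (is.na(w1)) stop("supply 'w1' for a composition-scan fit")
  }
  object$xfun(object$params, T_K, w1)
}

#' Plot a fitted solubility curve over the data
#'
#' @param x an `sle_fit` object.
#' @param n_grid number of points for the fitted curve.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.sle_fit <- function(x, n_grid = 100L, ...) {
  Tr <- range(x$data$T_K)
  Tg <- seq(Tr[1L], Tr[2L], length.out = n_grid)
  w1 <- attr(x$data, "w1")
  xg <- if (is.na(w1)) NULL else predict(x, Tg)
  plot(x$data$T_K, x$data$x_exp, xlab = "T (K)",
       ylab = "mole-fraction solubility",
       main = sprintf("%s: %s model", attr(x$data, "system"), x$model), ...)
  if (!is.null(xg)) lines(Tg, xg, col = 2)
  invisible(x)
}
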