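# Synthetic solubility data with known ground truth. Noise is
# multiplicative Gaussian (relative error), matching the
# scale-proportional measurement uncertainty of saturation-point
# determinations; draws pushing x outside (0, 1) are resampled.

# Forward curve for a named model from a bare parameter vector.
.model_curve <- function(model, params, T_K, solute, w1 = 0.5,
                         rq = NULL, pure_fits = NULL) {
  switch(model,
    apelblat = apelblat_x(T_K, params[["A"]], params[["B"]], params[["C"]]),
    vanthoff = vanthoff_x(T_K, params[["A"]], params[["B"]]),
    lambdah = lambdah_x(T_K, params[["lambda"]], params[["h"]], solute$Tm),
    nrtl = .sle_curve(function(x, Tv)
      nrtl_gamma(x, Tv, params[["dg12"]], params[["dg21"]])$gamma1,
      T_K, solute),
    uniquac = {
      if (is.null(rq)) stop("supply 'rq' for a UNIQUAC curve")
      .sle_curve(function(x, Tv)
        uniquac_gamma(pmin(pmax(x, 1e-10), 1 - 1e-10), Tv,
                      params[["du12"]], params[["du21"]],
                      c(rq$solute$r, rq$solvent$r),
                      c(rq$solute$q, rq$solvent$q))$gamma1,
        T_K, solute)
    },
    wilson = ,
    wilson_vanthoff = {
      if (is.null(pure_fits)) stop("supply 'pure_fits' for a Wilson curve")
      wilson_xm(w1,
                pmin(predict(pure_fits[[1L]], T_K), 1 - 1e-12),
                pmin(predict(pure_fits[[2L]], T_K), 1 - 1e-12),
                params[["lam12"]], params[["lam21"]])
    },
    stop("unknown model ", sQuote(model)))
}

#' Simulate a solubility dataset from a known model
#'
#' x_i = model(T_i; params) * (1 + eps_i) with eps_i ~ N(0, sigma^2);
#' draws that push x outside (0, 1) are resampled. Deterministic for a
#' fixed seed.
#'
#' @param model model name (see [fit_solubility()]).
#' @param params named vector of the model's true parameters.
#' @param T_grid temperature grid (K), at least one more point than the
#'   model has parameters; default mirrors the study designs (12
#'   temperatures over 295-340 K).
#' @param sigma relative noise standard deviation (>= 0).
#' @param seed integer seed.
#' @param solute a [solute_properties].
#' @param system label for the simulated dataset.
#' @param w1,rq,pure_fits extra context for the UNIQUAC and
#'   Wilson-family curves (see [fit_solubility()]).
#' @return A [solubility_dataset].
#' @examples
#' simulate_solubility("lambdah", c(lambda = 0.63, h = 2847), sigma = 0.005)
#' @export
simulate_solubility <- function(model, params,
                                T_grid = seq(295, 340, length.out = 12),
                                sigma = 0, seed = 1L,
                                solute = dha_properties(),
                                system = paste("simulated", model),
                                w1 = 0.5, rq = NULL, pure_fits = NULL) {
  if (sigma < 0) stop("'sigma' must be non-negative")
  if (any(T_grid <= 0) || any(T_grid > solute$Tm))
    stop("'T_grid' must lie in (0, Tm]")
  k <- length(params)
  if (length(T_grid) < k + 1L)
    stop("grid must have more points than the model has parameters")
  x_true <- .model_curve(model, params, T_grid, solute, w1, rq, pure_fits)
  if (any(x_true <= 0 | x_true >= 1))
    stop("true curve leaves (0, 1) on this grid")
  set.seed(seed)
  x <- x_true
  if (sigma > 0) {
    x <- x_true * (1 + stats::rnorm(length(x_true), 0, sigma))
    bad <- which(x <= 0 | x >= 1)
    tries <- 0L
    while (length(bad) && tries < 1000L) {
      x[bad] <- x_true[bad] * (1 + stats::rnorm(length(bad), 0, sigma))
      bad <- which(x <= 0 | x >= 1)
      tries <- tries + 1L
    }
    if (length(bad)) stop("could not keep simulated values inside (0, 1)")
  }
  solvents <- if (model %in% c("wilson", "wilson_vanthoff"))
    c("solvent 1", "solvent 2") else system
  solubility_dataset(T_grid, x, system = system, solvents = solvents,
                     w1 = if (length(solvents) == 2L) w1 else 1)
}

#' Parameter-recovery study
#'
#' Simulates `n_replicates` noisy datasets from a known model, refits
#' the generating model to each, and summarizes how well the parameters
#' and the deviation metrics are recovered.
#'
#' @inheritParams simulate_solubility
#' @param n_replicates number of simulated datasets.
#' @param ... passed to [fit_solubility()] (e.g. `control`).
#' @return A list with `params` (a data.frame per parameter: true value,
#'   mean estimate, bias, relative RMSE), `ard` (the fitted ARD of each
#'   replicate), `n_failed` (replicates whose fit errored) and
#'   `estimates` (the per-replicate parameter matrix).
#' @export
recovery_study <- function(model, params,
                           T_grid = seq(295, 340, length.out = 12),
                           sigma = 0, n_replicates = 100L, seed = 1L,
                           solute = dha_properties(), ...) {
  if (n_replicates < 1L) stop("need at least one replicate")
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  est <- matrix(NA_real_, n_replicates, length(params),
                dimnames = list(NULL, names(params)))
  ard <- rep(NA_real_, n_replicates)
  failed <- 0L
  for (i in seq_len(n_replicates)) {
    res <- tryCatch({
      ds <- simulate_solubility(model, params, T_grid, sigma,
                                seed = rep_seeds[i], solute = solute)
      fit_solubility(ds, model, solute = solute, ...)
    }, error = function(e) NULL)
    if (is.null(res)) { failed <- failed + 1L; next }
    est[i, ] <- res$params[names(params)]
    ard[i] <- res$ard
  }
  ok <- stats::complete.cases(est)
  ptab <- data.frame(
    parameter = names(params),
    true = unname(params),
    mean_est = colMeans(est[ok, , drop = FALSE]),
    bias = colMeans(est[ok, , drop = FALSE]) - unname(params),
    rel_rmse = sqrt(colMeans(
      (t(t(est[ok, , drop = FALSE]) - unname(params)))^2)) / abs(unname(params)))
  rownames(ptab) <- NULL
  list(params = ptab, ard = ard[ok], n_failed = failed, estimates = est)
}
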