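# Config-driven orchestration: fit every requested model to every
# dataset, rank them by AIC, run the dissolution-thermodynamics and
# solubility-parameter analyses, and (optionally) write the report
# tables as CSV.

.default_models <- function(dataset) {
  if (length(attr(dataset, "solvents")) == 2L)
    c("lambdah", "wilson", "wilson_vanthoff")
  else
    c("apelblat", "lambdah", "nrtl", "uniquac", "vanthoff")
}

#' Run the full solubility analysis
#'
#' Fits the requested models to each dataset, compares them by AIC, and
#' computes the van't Hoff dissolution thermodynamics and the
#' solubility-parameter screen. This reproduces, on the built-in data,
#' every results table of the study the package models.
#'
#' @param config a list with optional fields:
#'   \describe{
#'     \item{datasets}{`"builtin"` (default; all built-in temperature
#'       scans), a named list of [solubility_dataset] objects, or a
#'       character vector of CSV paths readable by [read_solubility()].}
#'     \item{models}{character vector of model names, or a named list
#'       (per dataset). Default: Apelblat, lambda-h, NRTL, UNIQUAC and
#'       van't Hoff for monosolvents; lambda-h and the Wilson variants
#'       for binary solvents.}
#'     \item{solute}{a [solute_properties]; default [dha_properties()].}
#'     \item{control}{a [sle_control()] list.}
#'     \item{k_convention}{AIC parameter-count convention passed to
#'       [compare_models()]; `"free"` (default) or `"reference"`.}
#'     \item{out_dir}{if set, report tables are written there as CSV.}
#'   }
#' @return A list of class `sle_report`: `fits` (nested list), `params`
#'   (per-model parameter/deviation tables), `comparison` (per-dataset
#'   AIC tables), `best` (data.frame of preferred models), `thermo`
#'   (thermodynamics table), `hsp` (solubility-parameter screen).
#' @examples
#' \donttest{
#' rep <- run_analysis(list(datasets = "builtin"))
#' rep$best
#' }
#' @export
run_analysis <- function(config = list()) {
  datasets <- config$datasets %||% "builtin"
  if (identical(datasets, "builtin"))
    datasets <- c(terpene_solubility("mono"), terpene_solubility("binary"))
  else if (is.character(datasets))
    datasets <- stats::setNames(lapply(datasets, read_solubility),
                                basename(datasets))
  if (!length(datasets)) stop("empty dataset list")
  if (!all(vapply(datasets, inherits, TRUE, "solubility_dataset")))
    stop("'datasets' must resolve to solubility_dataset objects")
  solute <- config$solute %||% dha_properties()
  control <- config$control %||% sle_control()
  models <- config$models
  if (is.character(models)) {
    bad <- setdiff(models, .sle_models)
    if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "))
  }

  fits <- lapply(names(datasets), function(nm) {
    ds <- datasets[[nm]]
    ms <- if (is.null(models)) .default_models(ds)
          else if (is.list(models)) models[[nm]] else models
    stats::setNames(lapply(ms, function(m)
      fit_solubility(ds, m, solute = solute, control = control)), ms)
  })
  names(fits) <- names(datasets)

  all_models <- unique(unlist(lapply(fits, names)))
  params <- stats::setNames(lapply(all_models, function(m) {
    rows <- lapply(names(fits), function(nm) {
      f <- fits[[nm]][[m]]
      if (is.null(f)) return(NULL)
      cbind(data.frame(system = nm), as.data.frame(as.list(f$params)),
            data.frame(rmsd_1e3 = 1000 * f$rmsd, ard_100 = 100 * f$ard))
    })
    out <- do.call(rbind, Filter(Negate(is.null), rows))
    rownames(out) <- NULL
    out
  }), all_models)

  k_convention <- config$k_convention %||% "free"
  comparison <- lapply(fits, function(fl)
    if (length(fl) > 1L) compare_models(unname(fl), k_convention) else NULL)
  best <- data.frame(
    system = names(comparison),
    best_model = vapply(comparison, function(cmp)
      if (is.null(cmp)) NA_character_ else cmp$model[1L], ""))
  rownames(best) <- NULL

  thermo <- thermo_table(datasets[vapply(datasets, nrow, 0L) >= 3L])
  hsp <- tryCatch(hsp_screen(solute), error = function(e) NULL)

  out <- structure(list(fits = fits, params = params,
                        comparison = comparison, best = best,
                        thermo = thermo, hsp = hsp),
                   class = "sle_report")
  if (!is.null(config$out_dir)) write_report(out, config$out_dir)
  out
}

#' @export
print.sle_report <- function(x, ...) {
  cat("Solubility analysis report:", length(x$fits), "dataset(s)\n\n")
  cat("Preferred model per system (AIC):\n")
  print(x$best, row.names = FALSE)
  cat("\nDissolution thermodynamics:\n")
  print(transform(x$thermo,
                  intercept = round(intercept, 4), slope = round(slope, 4),
                  dG_kJ = round(dG_kJ, 4), dH_kJ = round(dH_kJ, 4),
                  dS_J = round(dS_J, 4), deltaH = round(deltaH, 4),
                  deltaTS = round(deltaTS, 4)), row.names = FALSE)
  if (!is.null(x$hsp)) {
    cat(sprintf("\nSolubility-parameter screen (solute delta = %.4f MPa^0.5):\n",
                attr(x$hsp, "delta_solute")))
    print(transform(x$hsp, delta = round(delta, 4),
                    mismatch = round(mismatch, 4)), row.names = FALSE)
  }
  invisible(x)
}

#' Write the report tables of an analysis as CSV files
#'
#' @param report an `sle_report` from [run_analysis()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "sle_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in names(report$params))
    utils::write.csv(report$params[[m]],
                     file.path(dir, paste0("params_", m, ".csv")),
                     row.names = FALSE)
  cmp <- Filter(Negate(is.null), report$comparison)
  if (length(cmp)) {
    tab <- do.call(rbind, lapply(names(cmp), function(nm)
      cbind(system = nm, as.data.frame(cmp[[nm]]))))
    utils::write.csv(tab, file.path(dir, "model_comparison.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(report$thermo, file.path(dir, "thermodynamics.csv"),
                   row.names = FALSE)
  if (!is.null(report$hsp))
    utils::write.csv(report$hsp, file.path(dir, "hsp_screen.csv"),
                     row.names = FALSE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
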