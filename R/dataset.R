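#' Construct a solubility dataset
#'
#' A `solubility_dataset` is a data.frame of (temperature, mole-fraction
#' solubility) records for one solvent system, sorted by temperature,
#' carrying the solvent metadata as attributes. Composition scans may
#' additionally vary the solvent mass fraction `w1` per record.
#'
#' @param T_K absolute temperatures (K), all > 0.
#' @param x_exp experimental mole-fraction solubilities, all in (0, 1).
#' @param system label for the solvent system.
#' @param solvents character vector of one or two solvent names.
#' @param w1 mass fraction of the first solvent in the solvent mixture
#'   (scalar, or one value per record for composition scans); must be 1
#'   for monosolvents.
#' @param molar_masses solvent molar masses (g/mol), one per solvent.
#' @param pressure_kPa pressure metadata (kPa).
#' @return A data.frame of class `solubility_dataset` with columns `T_K`,
#'   `x_exp` and, for per-record compositions, `w1`.
#' @examples
#' solubility_dataset(c(300, 310, 320), c(0.10, 0.12, 0.15),
#'                    system = "p-cymene", solvents = "p-cymene",
#'                    molar_masses = 134.218)
#' @export
solubility_dataset <- function(T_K, x_exp, system = "unnamed",
                               solvents = system, w1 = 1,
                               molar_masses = NA_real_,
                               pressure_kPa = 101.3) {
  T_K <- as.numeric(T_K); x_exp <- as.numeric(x_exp)
  if (length(T_K) != length(x_exp))
    stop("'T_K' and 'x_exp' must have the same length")
  if (any(!is.finite(T_K)) || any(T_K <= 0))
    stop("temperatures must be finite and positive (K)")
  if (any(!is.finite(x_exp)) || any(x_exp <= 0) || any(x_exp >= 1))
    stop("mole-fraction solubilities must lie strictly in (0, 1)")
  if (anyDuplicated(T_K) && length(w1) == 1L)
    stop("duplicate temperatures in dataset")
  n_solv <- length(solvents)
  if (n_solv < 1L || n_solv > 2L)
    stop("'solvents' must name one or two solvents")
  if (!length(w1) %in% c(1L, length(T_K)))
    stop("'w1' must be a scalar or one value per record")
  if (any(w1 < 0 | w1 > 1)) stop("'w1' must lie in [0, 1]")
  if (n_solv == 1L && any(w1 != 1))
    stop("'w1' must be 1 for a monosolvent")
  per_point_w <- length(w1) == length(T_K) && length(T_K) > 1L
  df <- if (per_point_w) data.frame(w1 = w1, T_K = T_K, x_exp = x_exp)
        else data.frame(T_K = T_K, x_exp = x_exp)
  ord <- if (per_point_w) order(w1, T_K) else order(T_K)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            system = system, solvents = solvents,
            w1 = if (per_point_w) NA_real_ else w1,
            molar_masses = molar_masses, pressure_kPa = pressure_kPa,
            class = c("solubility_dataset", "data.frame"))
}

#' @export
print.solubility_dataset <- function(x, ...) {
  cat("Solubility dataset:", attr(x, "system"), "\n")
  w1 <- attr(x, "w1")
  if (length(attr(x, "solvents")) == 2L && !is.na(w1))
    cat(sprintf("  binary solvent, w1 = %g (mass fraction of %s)\n",
                w1, attr(x, "solvents")[1L]))
  cat(sprintf("  %d points, T in [%.2f, %.2f] K, P = %g kPa\n",
              nrow(x), min(x$T_K), max(x$T_K), attr(x, "pressure_kPa")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Mole-fraction solubility from weighed masses
#'
#' Converts weighed masses of solute and one or two solvents into the
#' mole fraction of the first component: x1 = n1 / sum(ni) with
#' ni = mi / Mi.
#'
#' @param masses masses (g) of the components, solute first; 2 or 3
#'   components.
#' @param molar_masses molar masses (g/mol), same length as `masses`.
#' @return Mole fraction of component 1.
#' @examples
#' mole_fraction_solubility(c(1, 10), c(300.442, 134.218))
#' @export
mole_fraction_solubility <- function(masses, molar_masses) {
  if (length(masses) != length(molar_masses))
    stop("'masses' and 'molar_masses' must have the same length")
  if (!length(masses) %in% 2:3)
    stop("expected 2 or 3 components (solute plus one or two solvents)")
  if (any(masses < 0)) stop("masses must be non-negative")
  if (any(molar_masses <= 0)) stop("molar masses must be positive")
  if (all(masses == 0)) stop("at least one mass must be positive")
  n <- masses / molar_masses
  n[1L] / sum(n)
}

#' Solvent mass fraction
#'
#' w1 = m1 / (m1 + m2) for a binary solvent mixture.
#'
#' @param m1,m2 masses (g) of the two solvents.
#' @return Mass fraction of solvent 1 in the solvent mixture.
#' @export
solvent_mass_fraction <- function(m1, m2) {
  if (any(c(m1, m2) < 0)) stop("masses must be non-negative")
  if (m1 + m2 <= 0) stop("total solvent mass must be positive")
  m1 / (m1 + m2)
}

#' Read a solubility dataset from a delimited text file
#'
#' Expects a comma-delimited file with a header row and columns `system`,
#' `w1`, `T_K`, `x_exp` (the schema written by [write_solubility()]).
#' Rows violating the dataset invariants are reported with their line
#' numbers.
#'
#' @param path file path.
#' @param solvents,molar_masses optional solvent metadata (taken from the
#'   file's `system` column when the system matches a built-in one).
#' @return A [solubility_dataset].
#' @export
read_solubility <- function(path, solvents = NULL, molar_masses = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  if (nrow(df) == 0L) stop("empty dataset file: ", path)
  need <- c("T_K", "x_exp")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  for (col in intersect(c("T_K", "x_exp", "w1"), names(df))) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]))
    if (length(bad))
      stop("non-numeric ", col, " at data line(s) ",
           paste(bad + 1L, collapse = ", "), " of ", path)
    df[[col]] <- vals
  }
  bad <- which(df$T_K <= 0 | df$x_exp <= 0 | df$x_exp >= 1)
  if (length(bad))
    stop("invalid record(s) at data line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path,
         " (need T_K > 0 and 0 < x_exp < 1)")
  system <- if ("system" %in% names(df)) df$system[1L] else "unnamed"
  if (is.null(solvents)) {
    solvents <- .split_solvents(system)
    mm <- .solvent_molar_masses[solvents]
    if (!anyNA(mm)) molar_masses <- unname(mm)
  }
  w1 <- if ("w1" %in% names(df)) df$w1 else 1
  if (length(unique(w1)) == 1L) w1 <- w1[1L]
  dup <- duplicated(df$T_K)
  if (any(dup) && length(w1) == 1L)
    stop("duplicate temperature(s) at data line(s) ",
         paste(which(dup) + 1L, collapse = ", "), " of ", path)
  solubility_dataset(df$T_K, df$x_exp, system = system, solvents = solvents,
                     w1 = w1, molar_masses = molar_masses)
}

#' Write a solubility dataset to a delimited text file
#'
#' @param dataset a [solubility_dataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_solubility <- function(dataset, path) {
  stopifnot(inherits(dataset, "solubility_dataset"))
  w1 <- if ("w1" %in% names(dataset)) dataset$w1 else attr(dataset, "w1")
  df <- data.frame(system = attr(dataset, "system"), w1 = w1,
                   T_K = dataset$T_K, x_exp = dataset$x_exp)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
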