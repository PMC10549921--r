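#' Physical constants for SPINA thyroid homeostasis calculations
#'
#' Returns the set of kinetic and plasma-protein-binding constants entering
#' the SPINA-GT and SPINA-GD calculations. Defaults are the standard
#' published values; any constant can be overridden by name.
#'
#' @param ... Named overrides for individual constants (e.g. `D_T = 2.75`).
#'
#' @details The constants and their units:
#' \describe{
#'   \item{alpha_T}{dilution factor for thyroxine, 1/L (0.1)}
#'   \item{beta_T}{clearance exponent for T4, 1/s (1.1e-6)}
#'   \item{D_T}{EC50 of TSH at the thyroid, mIU/L (2.75)}
#'   \item{K41}{dissociation constant T4--TBG, L/mol (2e10)}
#'   \item{K42}{dissociation constant T4--TTR, L/mol (2e8)}
#'   \item{alpha_31}{dilution factor for triiodothyronine, 1/L (0.026)}
#'   \item{beta_31}{clearance exponent for T3, 1/s (8e-6)}
#'   \item{K_M1}{dissociation constant of type-1 deiodinase, nmol/L (500)}
#'   \item{K30}{dissociation constant T3--TBG, L/mol (2e9)}
#'   \item{TBG}{standard thyroxine-binding globulin concentration, nmol/L (300)}
#'   \item{TBPA}{standard transthyretin concentration, umol/L (4.5)}
#'   \item{beta_corr}{correction coefficient of the logarithmic model,
#'     dimensionless (0.1345); carried for completeness but not used by
#'     either structure-parameter equation}
#' }
#'
#' @return A named list of class `spina_constants`.
#' @examples
#' spina_constants()
#' spina_constants(TBG = 250)
#' @export
spina_constants <- function(...) {
  defaults <- list(
    alpha_T  = 0.1,
    beta_T   = 1.1e-6,
    D_T      = 2.75,
    K41      = 2e10,
    K42      = 2e8,
    alpha_31 = 0.026,
    beta_31  = 8e-6,
    K_M1     = 500,
    K30      = 2e9,
    TBG      = 300,
    TBPA     = 4.5,
    beta_corr = 0.1345
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown) || is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("unknown or unnamed SPINA constant(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    defaults[names(overrides)] <- overrides
  }
  bad <- vapply(defaults, function(v) !is.numeric(v) || length(v) != 1L ||
                  !is.finite(v) || v <= 0, logical(1))
  if (any(bad)) {
    stop("SPINA constants must be single positive finite numbers; offending: ",
         paste(names(defaults)[bad], collapse = ", "), call. = FALSE)
  }
  structure(defaults, class = "spina_constants")
}

# Dimensionless plasma-binding factor for T4: 1 + K41 [TBG] + K42 [TBPA],
# with TBG in nmol/L and TBPA in umol/L converted to mol/L.
t4_binding_factor <- function(constants = spina_constants()) {
  1 + constants$K41 * constants$TBG * 1e-9 + constants$K42 * constants$TBPA * 1e-6
}

# Dimensionless plasma-binding factor for T3: 1 + K30 [TBG].
t3_binding_factor <- function(constants = spina_constants()) {
  1 + constants$K30 * constants$TBG * 1e-9
}

#' Thyroid secretory capacity SPINA-GT
#'
#' Estimates the maximum rate of T4 release under full TSH stimulation from
#' a pair of serum measurements:
#' \deqn{G_T = \frac{\beta_T (D_T + [TSH]) (1 + K_{41}[TBG] + K_{42}[TBPA]) [fT4]}
#'                  {\alpha_T [TSH]}}
#' All concentration products are evaluated in mol/L so that the binding
#' factor is dimensionless; the result is returned in pmol/s.
#'
#' Vectorised over `tsh` and `ft4`; `NA` inputs propagate to `NA` results.
#'
#' @param tsh Serum thyrotropin, mIU/L (numerically identical to uIU/ml).
#'   Must be strictly positive where non-missing.
#' @param ft4 Serum free thyroxine, pmol/L. Must be non-negative.
#' @param constants A [spina_constants()] object.
#'
#' @return Numeric vector of SPINA-GT values in pmol/s.
#' @examples
#' spina_gt(1.87, 16.84) # ~3.16 pmol/s
#' @seealso [spina_gd()], [add_spina()]
#' @export
spina_gt <- function(tsh, ft4, constants = spina_constants()) {
  stopifnot(inherits(constants, "spina_constants"))
  n <- max(length(tsh), length(ft4))
  tsh <- rep_len(as.numeric(tsh), n)
  ft4 <- rep_len(as.numeric(ft4), n)
  ok <- !is.na(tsh) & !is.na(ft4)
  if (any(tsh[ok] <= 0)) {
    stop("spina_gt() requires tsh > 0 (division by alpha_T * TSH)", call. = FALSE)
  }
  if (any(ft4[ok] < 0)) {
    stop("spina_gt() requires ft4 >= 0", call. = FALSE)
  }
  out <- rep(NA_real_, n)
  # fT4 pmol/L -> mol/L; result mol/s -> pmol/s (the 1e-12 factors cancel)
  out[ok] <- constants$beta_T * (constants$D_T + tsh[ok]) *
    t4_binding_factor(constants) * ft4[ok] / (constants$alpha_T * tsh[ok])
  out
}

#' Sum activity of peripheral deiodinases SPINA-GD
#'
#' Estimates total T3 production capacity from T4:
#' \deqn{G_D = \frac{\beta_{31} (K_{M1} + [fT4]) (1 + K_{30}[TBG]) [fT3]}
#'                  {\alpha_{31} [fT4]}}
#' `K_M1` (nmol/L) and fT4 (pmol/L) are brought to a common molar unit
#' before the sum; the result is returned in nmol/s.
#'
#' Vectorised; `NA` inputs propagate.
#'
#' @param ft4 Serum free thyroxine, pmol/L; strictly positive where present.
#' @param ft3 Serum free triiodothyronine, pmol/L; non-negative.
#' @param constants A [spina_constants()] object.
#'
#' @return Numeric vector of SPINA-GD values in nmol/s.
#' @examples
#' spina_gd(16.84, 4.76) # ~26.1 nmol/s
#' @seealso [spina_gt()], [add_spina()]
#' @export
spina_gd <- function(ft4, ft3, constants = spina_constants()) {
  stopifnot(inherits(constants, "spina_constants"))
  n <- max(length(ft4), length(ft3))
  ft4 <- rep_len(as.numeric(ft4), n)
  ft3 <- rep_len(as.numeric(ft3), n)
  ok <- !is.na(ft4) & !is.na(ft3)
  if (any(ft4[ok] <= 0)) {
    stop("spina_gd() requires ft4 > 0", call. = FALSE)
  }
  if (any(ft3[ok] < 0)) {
    stop("spina_gd() requires ft3 >= 0", call. = FALSE)
  }
  out <- rep(NA_real_, n)
  # common unit: mol/L. K_M1 nmol/L -> 1e-9, fT4/fT3 pmol/L -> 1e-12.
  km1 <- constants$K_M1 * 1e-9
  ft4_mol <- ft4[ok] * 1e-12
  ft3_mol <- ft3[ok] * 1e-12
  gd_mol <- constants$beta_31 * (km1 + ft4_mol) * t3_binding_factor(constants) *
    ft3_mol / (constants$alpha_31 * ft4_mol)
  out[ok] <- gd_mol * 1e9 # mol/s -> nmol/s
  out
}

#' Attach SPINA-GT and SPINA-GD columns to a cohort
#'
#' Data-frame-first wrapper: computes both structure parameters from the
#' hormone columns and appends them. Missing hormone values propagate to
#' missing parameter values without error, so per-endpoint missingness is
#' preserved: `spina_gt` is missing wherever `tsh` or `ft4` is, `spina_gd`
#' wherever `ft4` or `ft3` is.
#'
#' @param cohort A data frame with numeric columns `tsh` (uIU/ml),
#'   `ft4` (pmol/L) and `ft3` (pmol/L).
#' @param constants A [spina_constants()] object.
#'
#' @return The cohort as a tibble with `spina_gt` (pmol/s) and `spina_gd`
#'   (nmol/s) columns added (overwritten if already present).
#' @examples
#' tibble::tibble(tsh = c(1.87, NA), ft4 = 16.84, ft3 = 4.76) |> add_spina()
#' @export
add_spina <- function(cohort, constants = spina_constants()) {
  stopifnot(is.data.frame(cohort))
  need <- c("tsh", "ft4", "ft3")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("add_spina(): cohort lacks column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cohort <- tibble::as_tibble(cohort)
  # guard the vectorised kernels against non-positive denominators row-wise:
  # treat tsh <= 0 or ft4 <= 0 as not computable rather than aborting a
  # whole cohort over one bad record
  tsh <- ifelse(!is.na(cohort$tsh) & cohort$tsh <= 0, NA_real_, cohort$tsh)
  ft4_gt <- ifelse(!is.na(cohort$ft4) & cohort$ft4 < 0, NA_real_, cohort$ft4)
  ft4_gd <- ifelse(!is.na(cohort$ft4) & cohort$ft4 <= 0, NA_real_, cohort$ft4)
  cohort$spina_gt <- spina_gt(tsh, ft4_gt, constants)
  cohort$spina_gd <- spina_gd(ft4_gd, cohort$ft3, constants)
  cohort
}
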