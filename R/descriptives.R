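#' Quartile summary of a numeric vector
#'
#' 25th, 50th and 75th percentiles with linear interpolation between order
#' statistics (the "type 7" convention, the default of most statistical
#' software). Missing values are dropped.
#'
#' @param values Numeric vector with at least one non-missing value.
#' @return A named numeric vector `c(p25, median, p75)`.
#' @examples
#' quartiles(c(1, 2, 3)) # 1.5, 2, 2.5
#' @export
quartiles <- function(values) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (!length(values)) {
    stop("quartiles(): no non-missing values", call. = FALSE)
  }
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(p25 = q[1], median = q[2], p75 = q[3])
}

#' Stratified quartile table for cohort variables
#'
#' Produces the familiar descriptive layout: one row per stratum x variable
#' with n, p25, median and p75.
#'
#' @param cohort A data frame.
#' @param vars Character vector of numeric columns to summarise; defaults to
#'   the exposure plus the seven thyroid endpoints where present.
#' @param by Stratifying column (string) or `NULL` to pool.
#'
#' @return A tibble with columns `stratum`, `variable`, `n`, `p25`,
#'   `median`, `p75`. `n` counts non-missing values per cell.
#' @export
summarise_quartiles <- function(cohort,
                                vars = intersect(
                                  c("ni", "tsh", "ft4", "ft3", "t4", "t3",
                                    "spina_gd", "spina_gt"),
                                  names(cohort)),
                                by = "sex") {
  stopifnot(is.data.frame(cohort), length(vars) >= 1,
            all(vars %in% names(cohort)))
  cohort <- tibble::as_tibble(cohort)
  if (is.null(by)) {
    cohort$.stratum <- "all"
    by <- ".stratum"
  } else if (!by %in% names(cohort)) {
    stop("summarise_quartiles(): no column '", by, "'", call. = FALSE)
  }
  cohort |>
    dplyr::select(dplyr::all_of(c(by, vars))) |>
    tidyr::pivot_longer(dplyr::all_of(vars),
                        names_to = "variable", values_to = "value") |>
    dplyr::group_by(stratum = .data[[by]],
                    variable = factor(.data$variable, levels = vars)) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      p25 = if (n > 0) quartiles(.data$value)[["p25"]] else NA_real_,
      median = if (n > 0) quartiles(.data$value)[["median"]] else NA_real_,
      p75 = if (n > 0) quartiles(.data$value)[["p75"]] else NA_real_,
      .groups = "drop"
    )
}

#' Percentage of values exceeding a threshold
#'
#' The exceedance fraction used to express how much of a population sits
#' above a benchmark dose lower limit: 100 x #\{v > threshold\} / n, with a
#' strict inequality. Missing values are dropped before counting.
#'
#' @param values Numeric vector with at least one non-missing value.
#' @param threshold Finite numeric scalar, same units as `values`.
#' @return Percentage in \[0, 100\].
#' @examples
#' fraction_above(c(1, 2, 3, 4), 2.5) # 50
#' @export
fraction_above <- function(values, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  if (!is.finite(threshold) && !is.infinite(threshold)) {
    stop("fraction_above(): threshold must be numeric", call. = FALSE)
  }
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (!length(values)) {
    stop("fraction_above(): no non-missing values", call. = FALSE)
  }
  100 * mean(values > threshold)
}

#' Spearman rank correlation with confidence interval and p-value
#'
#' Rank correlation on pairwise-complete observations, with average ranks
#' for ties. The two-sided p-value uses the t approximation
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom; the
#' confidence interval uses the Fisher z transform of r with the
#' Fieller-adjusted standard error \eqn{\sqrt{1.06/(n-3)}}, back-transformed.
#'
#' @param x,y Paired numeric vectors; pairs with either value missing are
#'   removed. At least 3 complete pairs are required.
#' @param conf_level Confidence level for the interval (default 0.95).
#'
#' @return A one-row tibble: `r`, `ci_low`, `ci_high`, `p`, `n`.
#' @examples
#' spearman_ci(c(1, 2, 3), c(3, 1, 2)) # r = -0.5
#' @export
spearman_ci <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y), conf_level > 0, conf_level < 1)
  ok <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3) {
    stop("spearman_ci(): fewer than 3 complete pairs", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("spearman_ci(): zero variance in ranks; r undefined", call. = FALSE)
  }
  r <- stats::cor(rx, ry)
  # t approximation for the two-sided p-value
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  # Fisher z interval with Fieller-adjusted SE
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  se <- sqrt(1.06 / (n - 3))
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    r = r,
    ci_low = tanh(z - zcrit * se),
    ci_high = tanh(z + zcrit * se),
    p = p,
    n = n
  )
}

#' Stratified exposure-endpoint Spearman screen
#'
#' Runs [spearman_ci()] between the exposure column and every endpoint
#' column, within each stratum, on pairwise-complete records. This is the
#' screening step that flags which endpoints move with exposure before
#' dose-response modelling.
#'
#' @param cohort A data frame containing `exposure`, the endpoint columns
#'   and the stratum column.
#' @param exposure Exposure column name (default `"ni"`).
#' @param vars Endpoint columns to correlate against; defaults to the seven
#'   thyroid endpoints present in the cohort.
#' @param by Stratum column (string) or `NULL` to pool.
#' @param conf_level Confidence level for the intervals.
#'
#' @return A tibble with `stratum`, `variable`, `r`, `ci_low`, `ci_high`,
#'   `p`, `n`; strata/variables with fewer than 3 complete pairs appear
#'   with `NA` statistics.
#' @export
correlate_exposure <- function(cohort, exposure = "ni",
                               vars = intersect(
                                 c("tsh", "ft4", "ft3", "t4", "t3",
                                   "spina_gt", "spina_gd"),
                                 names(cohort)),
                               by = "sex", conf_level = 0.95) {
  stopifnot(is.data.frame(cohort), exposure %in% names(cohort),
            length(vars) >= 1, all(vars %in% names(cohort)))
  cohort <- tibble::as_tibble(cohort)
  if (is.null(by)) {
    cohort$.stratum <- "all"
    by <- ".stratum"
  } else if (!by %in% names(cohort)) {
    stop("correlate_exposure(): no column '", by, "'", call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    stratum = unique(cohort[[by]]),
    variable = vars
  )
  purrr::pmap_dfr(grid, function(stratum, variable) {
    sub <- cohort[cohort[[by]] == stratum, ]
    res <- tryCatch(
      spearman_ci(sub[[exposure]], sub[[variable]], conf_level),
      error = function(e) tibble::tibble(r = NA_real_, ci_low = NA_real_,
                                         ci_high = NA_real_, p = NA_real_,
                                         n = sum(!is.na(sub[[exposure]]) &
                                                   !is.na(sub[[variable]])))
    )
    dplyr::bind_cols(tibble::tibble(stratum = stratum, variable = variable), res)
  })
}
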