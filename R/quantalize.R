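#' Clinical reference ranges for the thyroid endpoints
#'
#' The seven endpoints of the analysis with their reference intervals:
#' the five serum measurements and the two derived homeostasis parameters.
#' A value inside the closed interval \[low, high\] is classified as
#' in-range (0), outside as out-of-range (1).
#'
#' @param ... Named overrides, each a numeric `c(low, high)` with
#'   `low < high`; names must be endpoint names listed below.
#'
#' @return A tibble with columns `endpoint`, `low`, `high`, `units`.
#'   Endpoints: `tsh` (uIU/ml), `ft4` (pmol/L), `ft3` (pmol/L),
#'   `t4` (nmol/L), `t3` (nmol/L), `spina_gd` (nmol/s), `spina_gt` (pmol/s).
#' @examples
#' reference_ranges()
#' reference_ranges(tsh = c(0.4, 4.0))
#' @export
reference_ranges <- function(...) {
  rr <- tibble::tribble(
    ~endpoint,  ~low,   ~high,  ~units,
    "tsh",      0.270,  4.20,   "uIU/ml",
    "ft4",      12,     22,     "pmol/L",
    "ft3",      3.1,    6.8,    "pmol/L",
    "t4",       66,     181,    "nmol/L",
    "t3",       1.3,    3.1,    "nmol/L",
    "spina_gd", 20,     60,     "nmol/s",
    "spina_gt", 1.4,    8.7,    "pmol/s"
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), rr$endpoint)
    if (length(unknown)) {
      stop("reference_ranges(): unknown endpoint(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (nm in names(overrides)) {
      v <- overrides[[nm]]
      if (!is.numeric(v) || length(v) != 2L || !all(is.finite(v)) || v[1] >= v[2]) {
        stop("reference_ranges(): override for '", nm,
             "' must be c(low, high) with low < high", call. = FALSE)
      }
      rr$low[rr$endpoint == nm] <- v[1]
      rr$high[rr$endpoint == nm] <- v[2]
    }
  }
  rr
}

#' Classify values against a reference interval
#'
#' Quantal coding of a clinical measurement: 0 when the value lies inside
#' the closed interval \[low, high\] (boundaries count as in-range, the
#' usual clinical convention), 1 otherwise. Missing values give missing
#' indicators; non-finite values are rejected.
#'
#' @param value Numeric vector, in the endpoint's units.
#' @param low,high Interval bounds, `low < high`.
#' @return Integer vector of 0/1/NA indicators.
#' @examples
#' classify_quantal(c(1.87, 4.20, 4.21, NA), 0.270, 4.20)
#' @export
classify_quantal <- function(value, low, high) {
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1L,
            length(high) == 1L, is.finite(low), is.finite(high), low < high)
  value <- as.numeric(value)
  if (any(!is.na(value) & !is.finite(value))) {
    stop("classify_quantal(): non-finite value", call. = FALSE)
  }
  out <- as.integer(value < low | value > high)
  out
}

#' Quantalize a cohort: per subject x endpoint in/out-of-range indicators
#'
#' Converts every endpoint column of a cohort into a long table of quantal
#' outcomes. Subjects missing a measurement are excluded from that endpoint
#' only (listwise by endpoint), matching a design where each assay has its
#' own missingness.
#'
#' @param cohort A data frame; must contain the endpoint columns named in
#'   `ranges$endpoint` that are to be quantalized (missing columns are
#'   dropped with a warning), plus any identifier/stratum columns
#'   (`id`, `sex`, `health`, `ni` are carried through when present).
#' @param ranges A [reference_ranges()] tibble (possibly with overrides).
#'
#' @return A long tibble with one row per subject x available endpoint:
#'   carried columns, `endpoint`, `value`, and `out_of_range` (0/1/NA).
#' @examples
#' sim_cohort(n_men = 5, n_women = 5, seed = 1) |>
#'   add_spina() |>
#'   quantalize_cohort()
#' @export
quantalize_cohort <- function(cohort, ranges = reference_ranges()) {
  stopifnot(is.data.frame(cohort), is.data.frame(ranges),
            all(c("endpoint", "low", "high") %in% names(ranges)))
  if (any(ranges$low >= ranges$high)) {
    stop("quantalize_cohort(): each range needs low < high", call. = FALSE)
  }
  cohort <- tibble::as_tibble(cohort)
  present <- intersect(ranges$endpoint, names(cohort))
  if (!length(present)) {
    stop("quantalize_cohort(): no endpoint columns found in cohort",
         call. = FALSE)
  }
  if (length(absent <- setdiff(ranges$endpoint, present))) {
    warning("quantalize_cohort(): endpoint(s) not in cohort, skipped: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  carry <- intersect(c("id", "sex", "health", "ni", "age"), names(cohort))
  long <- cohort |>
    dplyr::select(dplyr::all_of(c(carry, present))) |>
    tidyr::pivot_longer(dplyr::all_of(present),
                        names_to = "endpoint", values_to = "value") |>
    dplyr::left_join(ranges[, c("endpoint", "low", "high")], by = "endpoint")
  # classify per endpoint so each uses its own interval
  long$out_of_range <- NA_integer_
  for (ep in present) {
    i <- long$endpoint == ep
    long$out_of_range[i] <- classify_quantal(
      long$value[i],
      ranges$low[ranges$endpoint == ep],
      ranges$high[ranges$endpoint == ep]
    )
  }
  long |>
    dplyr::select(-dplyr::all_of(c("low", "high"))) |>
    dplyr::mutate(endpoint = factor(.data$endpoint, levels = present))
}

#' Per-stratum in/out-of-range counts
#'
#' Summarises a quantalized cohort into the classic contingency layout:
#' one row per endpoint x stratum with the number of subjects in range,
#' out of range, and missing. `n_in + n_out + n_missing` always equals the
#' stratum size.
#'
#' @param quantal A long tibble from [quantalize_cohort()].
#' @param by Stratifying column name (string), e.g. `"sex"`; `NULL` pools
#'   everyone into a single `"all"` stratum.
#'
#' @return A tibble with `endpoint`, the stratum column, `n_in`, `n_out`,
#'   `n_missing`, `n_total`.
#' @export
quantal_counts <- function(quantal, by = "sex") {
  stopifnot(is.data.frame(quantal),
            all(c("endpoint", "out_of_range") %in% names(quantal)))
  q <- tibble::as_tibble(quantal)
  if (is.null(by)) {
    q$.stratum <- "all"
    by <- ".stratum"
  } else if (!by %in% names(q)) {
    stop("quantal_counts(): no column '", by, "' in quantal table", call. = FALSE)
  }
  out <- q |>
    dplyr::group_by(.data$endpoint, dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_in = sum(.data$out_of_range == 0L, na.rm = TRUE),
      n_out = sum(.data$out_of_range == 1L, na.rm = TRUE),
      n_missing = sum(is.na(.data$out_of_range)),
      n_total = dplyr::n(),
      .groups = "drop"
    )
  names(out)[2] <- if (by == ".stratum") "stratum" else by
  out
}
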