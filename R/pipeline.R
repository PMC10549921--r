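#' Read a cohort CSV
#'
#' Reads the per-subject column contract: `id`, `sex`, `ni` (ug/L)
#' mandatory; `age`, `health`, `tsh` (uIU/ml), `ft4` (pmol/L), `ft3`
#' (pmol/L), `t4` (nmol/L), `t3` (nmol/L) optional. Empty cells are
#' missing values; decimal points only. Sex codes `male`/`m`/`M` and
#' `female`/`f`/`F` (any case) are normalised to `M`/`F`. A named
#' `col_map` lets a differently labelled deposition be read without
#' editing the file.
#'
#' @param path Path to a CSV file with a header row.
#' @param col_map Optional named character vector mapping contract names to
#'   the file's column names, e.g. `c(ni = "Ni_blood_ugL")`.
#'
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path, col_map = NULL) {
  if (!file.exists(path)) {
    stop("read_cohort(): file not found: ", path, call. = FALSE)
  }
  raw <- tryCatch(
    # read as character: "F" in a sex column must not become logical FALSE
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                    colClasses = "character"),
    error = function(e) stop("read_cohort(): malformed CSV (",
                             conditionMessage(e), ")", call. = FALSE)
  )
  if (nrow(raw) == 0) {
    stop("read_cohort(): empty file: ", path, call. = FALSE)
  }
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (!col_map[[nm]] %in% names(raw)) {
        stop("read_cohort(): mapped column '", col_map[[nm]],
             "' not in file", call. = FALSE)
      }
      names(raw)[names(raw) == col_map[[nm]]] <- nm
    }
  }
  mandatory <- c("id", "sex", "ni")
  if (length(miss <- setdiff(mandatory, names(raw)))) {
    stop("read_cohort(): missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  cohort <- tibble::as_tibble(raw)
  sx <- toupper(trimws(as.character(cohort$sex)))
  sx[sx %in% c("MALE", "MAN", "M")] <- "M"
  sx[sx %in% c("FEMALE", "WOMAN", "F")] <- "F"
  if (!all(sx %in% c("M", "F"))) {
    bad <- which(!sx %in% c("M", "F"))[1]
    stop("read_cohort(): unrecognised sex code at row ", bad, ": '",
         cohort$sex[bad], "'", call. = FALSE)
  }
  cohort$sex <- sx
  numeric_cols <- intersect(c("ni", "age", "tsh", "ft4", "ft3", "t4", "t3"),
                            names(cohort))
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(cohort[[cc]]))
    if (any(is.na(v) & !is.na(cohort[[cc]]))) {
      bad <- which(is.na(v) & !is.na(cohort[[cc]]))[1]
      stop("read_cohort(): non-numeric value in column '", cc,
           "' at row ", bad, call. = FALSE)
    }
    cohort[[cc]] <- v
  }
  conc_cols <- intersect(c("ni", "tsh", "ft4", "ft3", "t4", "t3"),
                         names(cohort))
  for (cc in conc_cols) {
    neg <- which(!is.na(cohort[[cc]]) & cohort[[cc]] < 0)
    if (length(neg)) {
      stop("read_cohort(): negative concentration in column '", cc,
           "' at row ", neg[1], call. = FALSE)
    }
  }
  cohort
}

#' Run the full exposure-thyroid analysis pipeline
#'
#' End-to-end orchestration over a cohort: attach SPINA parameters,
#' quantalize against the reference ranges, compute stratified quartile
#' summaries and exposure correlations, and run a model-averaged BMD
#' analysis per endpoint within each stratum. Strata with a single outcome
#' class (or too few complete pairs) are reported as not-estimable rather
#' than dropped.
#'
#' @param cohort A cohort tibble (from [read_cohort()] or [sim_cohort()])
#'   or a path to a cohort CSV.
#' @param endpoints Endpoints to analyse; default the seven thyroid
#'   endpoints.
#' @param ranges Reference ranges ([reference_ranges()], possibly
#'   overridden).
#' @param constants SPINA constants ([spina_constants()]).
#' @param strata Character vector of strata to run: any of `"M"`, `"F"`,
#'   `"all"`, `"healthy"`, `"unhealthy"`. Default `c("M", "F", "all")`.
#' @param bmr Benchmark response (extra risk), default 0.10.
#' @param n_boot Bootstrap iterations per BMD cell, default 200.
#' @param seed Integer master seed; per-cell seeds are derived from it so
#'   the whole report is deterministic.
#' @param run_bmd Set `FALSE` to skip the (slow) BMD stage.
#' @param boot_starts,n_starts Optimiser start counts, passed to [ma_bmd()].
#' @param verbose Log each stage to the console.
#'
#' @return An object of class `thyro_report`: a list of tibbles —
#'   `cohort` (with SPINA columns), `counts` (in/out/missing per endpoint
#'   per sex), `summary` (quartiles per stratum), `correlations`
#'   (Spearman screen), `bmd` (one row per endpoint x stratum), plus
#'   `config` (a provenance list).
#' @export
run_pipeline <- function(cohort,
                         endpoints = c("tsh", "ft4", "ft3", "t4", "t3",
                                       "spina_gt", "spina_gd"),
                         ranges = reference_ranges(),
                         constants = spina_constants(),
                         strata = c("M", "F", "all"),
                         bmr = 0.10, n_boot = 200, seed = 1,
                         run_bmd = TRUE, n_starts = 10, boot_starts = 2,
                         verbose = FALSE) {
  stopifnot(bmr > 0, bmr < 1, n_boot >= 1)
  if (is.character(cohort) && length(cohort) == 1) {
    cohort <- read_cohort(cohort)
  }
  stopifnot(is.data.frame(cohort))
  say <- function(...) if (verbose) message(...)

  say("stage 1/4: SPINA parameters (", nrow(cohort), " subjects)")
  cohort <- add_spina(cohort, constants)

  say("stage 2/4: quantalization")
  use_ranges <- ranges[ranges$endpoint %in% endpoints, ]
  if (length(bad <- setdiff(endpoints, ranges$endpoint))) {
    stop("run_pipeline(): no reference range for endpoint(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  quantal <- quantalize_cohort(cohort, use_ranges)
  counts <- quantal_counts(quantal, by = if ("sex" %in% names(cohort)) "sex" else NULL)

  say("stage 3/4: descriptives and correlations")
  summary_tbl <- dplyr::bind_rows(
    summarise_quartiles(cohort, by = "sex"),
    summarise_quartiles(cohort, by = NULL)
  )
  corr <- dplyr::bind_rows(
    correlate_exposure(cohort, vars = intersect(endpoints, names(cohort)),
                       by = "sex"),
    correlate_exposure(cohort, vars = intersect(endpoints, names(cohort)),
                       by = NULL)
  )

  bmd_tbl <- NULL
  if (run_bmd) {
    say("stage 4/4: benchmark-dose analysis (", length(endpoints),
        " endpoints x ", length(strata), " strata, ", n_boot,
        " bootstrap iterations each)")
    bmd_tbl <- bmd_by_stratum(quantal, strata = strata, bmr = bmr,
                              n_boot = n_boot, seed = seed,
                              n_starts = n_starts, boot_starts = boot_starts,
                              verbose = verbose)
  }

  structure(
    list(
      cohort = cohort,
      counts = counts,
      summary = summary_tbl,
      correlations = corr,
      bmd = bmd_tbl,
      config = list(endpoints = endpoints, ranges = use_ranges,
                    constants = unclass(constants), strata = strata,
                    bmr = bmr, n_boot = n_boot, seed = seed,
                    version = as.character(utils::packageVersion("thyrobmd")))
    ),
    class = "thyro_report"
  )
}

# subject filter for a named stratum
stratum_index <- function(quantal, stratum) {
  switch(stratum,
    "all" = rep(TRUE, nrow(quantal)),
    "M" = ,
    "F" = quantal$sex == stratum,
    "healthy" = ,
    "unhealthy" = {
      if (!"health" %in% names(quantal)) {
        stop("stratum '", stratum, "' needs a 'health' column", call. = FALSE)
      }
      quantal$health == stratum
    },
    stop("unknown stratum: ", stratum, call. = FALSE)
  )
}

#' Stratified model-averaged BMD table
#'
#' Runs [ma_bmd()] for every endpoint within every requested stratum of a
#' quantalized cohort and assembles the classic BMDL/BMDU report table.
#' Cells whose outcomes are all 0 or all 1 (or with fewer than 10 complete
#' pairs) are returned with `estimable = FALSE` instead of being dropped,
#' so degenerate dose-response cells stay visible.
#'
#' @param quantal A long tibble from [quantalize_cohort()] with an `ni`
#'   column carried through.
#' @param strata Stratum labels (see [run_pipeline()]).
#' @param bmr,n_boot,seed,n_starts,boot_starts Passed to [ma_bmd()]; the
#'   per-cell seed is derived deterministically from `seed` and the cell
#'   position.
#' @param keep_fits Keep each cell's full `bmd_ma` object in a list column
#'   (default FALSE; the table of numbers is usually what is wanted).
#' @param verbose Log each cell.
#'
#' @return A tibble with one row per endpoint x stratum: `endpoint`,
#'   `stratum`, `n`, `n_out`, `estimable`, `bmd`, `bmdl`, `bmdu`, `ratio`,
#'   `narrow`, `n_censored`, `unreliable`, `seed` (and `fit` when
#'   `keep_fits = TRUE`).
#' @export
bmd_by_stratum <- function(quantal, strata = c("M", "F", "all"),
                           bmr = 0.10, n_boot = 200, seed = 1,
                           n_starts = 10, boot_starts = 2,
                           keep_fits = FALSE, verbose = FALSE) {
  stopifnot(is.data.frame(quantal),
            all(c("endpoint", "value", "out_of_range", "ni") %in% names(quantal)))
  endpoints <- levels(factor(quantal$endpoint))
  rows <- list()
  cell <- 0L
  for (st in strata) {
    in_stratum <- stratum_index(quantal, st)
    for (ep in endpoints) {
      cell <- cell + 1L
      sub <- quantal[in_stratum & quantal$endpoint == ep, ]
      ok <- !is.na(sub$ni) & sub$ni > 0 & !is.na(sub$out_of_range)
      d <- sub$ni[ok]; y <- sub$out_of_range[ok]
      cell_seed <- (seed * 1000L + cell) %% .Machine$integer.max
      base <- tibble::tibble(
        endpoint = ep, stratum = st, n = length(d), n_out = sum(y),
        estimable = NA, bmd = NA_real_, bmdl = NA_real_, bmdu = NA_real_,
        ratio = NA_real_, narrow = NA, n_censored = NA_integer_,
        unreliable = NA, seed = cell_seed
      )
      if (length(d) < 10 || length(unique(y)) < 2) {
        base$estimable <- FALSE
        if (verbose) message("  ", ep, " / ", st, ": not estimable")
        if (keep_fits) base$fit <- list(NULL)
        rows[[cell]] <- base
        next
      }
      if (verbose) message("  ", ep, " / ", st, ": n = ", length(d))
      fit <- ma_bmd(d, y, bmr = bmr, n_boot = n_boot, seed = cell_seed,
                    n_starts = n_starts, boot_starts = boot_starts,
                    keep_boot_fits = keep_fits)
      base$estimable <- TRUE
      base$bmd <- fit$bmd; base$bmdl <- fit$bmdl; base$bmdu <- fit$bmdu
      base$ratio <- fit$ratio; base$narrow <- fit$narrow
      base$n_censored <- fit$n_censored; base$unreliable <- fit$unreliable
      if (keep_fits) base$fit <- list(fit)
      rows[[cell]] <- base
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
print.thyro_report <- function(x, ...) {
  cat("<thyro_report>\n")
  cat("  subjects:", nrow(x$cohort), "\n")
  cat("  endpoints:", paste(x$config$endpoints, collapse = ", "), "\n")
  if (!is.null(x$bmd)) {
    cat("  BMD cells:", nrow(x$bmd),
        sprintf("(%d estimable)", sum(x$bmd$estimable)), "\n")
  }
  cat("  seed:", x$config$seed, " BMR:", x$config$bmr,
      " n_boot:", x$config$n_boot, "\n")
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes each report table as CSV plus a single JSON bundle carrying the
#' tables and the full configuration (seed, BMR, ranges, constants), so a
#' run can be archived and re-compared byte for byte.
#'
#' @param report A `thyro_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "thyro_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in c("counts", "summary", "correlations", "bmd")) {
    tbl <- report[[nm]]
    if (is.null(tbl)) next
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tbl, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(config = report$config,
         counts = report$counts,
         summary = report$summary,
         correlations = report$correlations,
         bmd = report$bmd),
    jp, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  paths <- c(paths, jp)
  invisible(paths)
}
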