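#' Invert a dose-response curve at a benchmark response
#'
#' Solves \eqn{P(BMD) = P_0 + BMR (1 - P_0)} (extra risk) for the benchmark
#' dose by bisection on log-dose, where \eqn{P_0} is the background
#' response \eqn{\lim_{d \to 0^+} P(d)}. The search window spans
#' `[min(dose_range) * 1e-6, max(dose_range) * 1e6]`; curves too flat to
#' reach the benchmark inside the window are reported as censored at the
#' window bound rather than failing.
#'
#' @param prob_fn A vectorised function dose -> probability, nondecreasing.
#' @param bmr Benchmark response as an extra-risk fraction in (0, 1);
#'   default 0.10.
#' @param dose_range Numeric length-2: the observed dose range anchoring
#'   the search window.
#' @param p0 Background response; computed as `prob_fn` near zero dose if
#'   omitted.
#' @param rel_tol Relative tolerance of the bisection (default 1e-6).
#'
#' @return A list with `bmd` (the dose, or the window bound if censored)
#'   and `censored` (`"none"`, `"left"`, or `"right"`).
#' @examples
#' f <- function(d) quantal_prob("log-logistic", c(a = 0, mu = log(10), sigma = 1), d)
#' bmd_from_curve(f, bmr = 0.10, dose_range = c(1, 100))$bmd # 10/9
#' @export
bmd_from_curve <- function(prob_fn, bmr = 0.10, dose_range, p0 = NULL,
                           rel_tol = 1e-6) {
  stopifnot(is.function(prob_fn), is.numeric(dose_range),
            length(dose_range) == 2, all(dose_range > 0))
  if (!is.numeric(bmr) || length(bmr) != 1 || bmr <= 0 || bmr >= 1) {
    stop("bmd_from_curve(): bmr must be in (0, 1)", call. = FALSE)
  }
  lo <- min(dose_range) * 1e-6
  hi <- max(dose_range) * 1e6
  if (is.null(p0)) p0 <- prob_fn(lo)
  # monotonicity sanity check on a coarse grid
  grid <- exp(seq(log(lo), log(hi), length.out = 25))
  pg <- prob_fn(grid)
  if (any(diff(pg) < -1e-8)) {
    stop("bmd_from_curve(): curve is not nondecreasing in dose", call. = FALSE)
  }
  target <- p0 + bmr * (1 - p0)
  f <- function(d) prob_fn(d) - target
  f_lo <- f(lo); f_hi <- f(hi)
  if (f_lo >= 0) return(list(bmd = lo, censored = "left"))
  if (f_hi < 0) return(list(bmd = hi, censored = "right"))
  llo <- log(lo); lhi <- log(hi)
  while (lhi - llo > rel_tol) {
    mid <- (llo + lhi) / 2
    if (f(exp(mid)) < 0) llo <- mid else lhi <- mid
  }
  list(bmd = exp((llo + lhi) / 2), censored = "none")
}

#' BMD interval ratio and narrowness flag
#'
#' The width of a benchmark-dose interval is judged by the ratio
#' BMDU/BMDL; an interval is conventionally called narrow when the ratio
#' is below 10.
#'
#' @param bmdl,bmdu Positive lower/upper confidence limits, `bmdl <= bmdu`.
#' @return A one-row tibble with `ratio` and `narrow` (logical).
#' @examples
#' bmdi_ratio(1.36, 60.9) # ratio 44.8, not narrow
#' @export
bmdi_ratio <- function(bmdl, bmdu) {
  if (!is.numeric(bmdl) || !is.numeric(bmdu) || length(bmdl) != 1 ||
      length(bmdu) != 1 || !is.finite(bmdl) || bmdl <= 0 || bmdu < bmdl) {
    stop("bmdi_ratio(): need 0 < bmdl <= bmdu", call. = FALSE)
  }
  ratio <- bmdu / bmdl
  tibble::tibble(ratio = ratio, narrow = ratio < 10)
}

# Fit the whole family suite; returns list of quantal_fit objects.
fit_quantal_suite <- function(dose, outcome, families = quantal_families(),
                              n_starts = 10, starts = NULL,
                              control = list(maxit = 300)) {
  fits <- vector("list", length(families))
  names(fits) <- families
  for (fam in families) {
    fits[[fam]] <- fit_quantal(dose, outcome, fam, n_starts = n_starts,
                               start = starts[[fam]], control = control)
  }
  fits
}

# Akaike weights for a suite, zeroing out non-converged fits.
suite_weights <- function(fits) {
  aic <- vapply(fits, function(f) if (f$converged) f$aic else Inf, numeric(1))
  akaike_weights(aic)
}

# Model-averaged response curve for a suite + weights.
ma_curve <- function(fits, weights) {
  keep <- weights > 0
  function(dose) {
    p <- 0
    for (i in which(keep)) {
      p <- p + weights[i] * predict_quantal(fits[[i]], dose)
    }
    p
  }
}

ma_background <- function(fits, weights) {
  p0 <- vapply(fits, function(f) {
    if (f$degenerate || is.null(f$params)) {
      if (is.null(f$p_const)) NA_real_ else f$p_const
    } else {
      quantal_background(f$family, f$params)
    }
  }, numeric(1))
  sum(weights * p0, na.rm = TRUE)
}

#' Model-averaged benchmark dose with bootstrap confidence limits
#'
#' The centrepiece of the dose-response analysis. Fits the full quantal
#' model suite to individual-level (dose, 0/1) data by maximum likelihood,
#' combines the fitted curves with Akaike weights, and inverts the averaged
#' curve at an extra-risk benchmark response (default 10%). BMDL and BMDU
#' are the 5th and 95th percentiles of the benchmark dose across a
#' parametric bootstrap: each iteration redraws outcomes as
#' Bernoulli(\eqn{\hat P(d_i)}) at the observed doses, refits the whole
#' suite, recomputes the weights and re-inverts the averaged curve.
#' Iterations whose curve never reaches the benchmark inside the search
#' window are counted at the window bound and reported as censored.
#'
#' @param dose Strictly positive doses (one per subject).
#' @param outcome 0/1 quantal outcomes.
#' @param bmr Benchmark response, extra risk, in (0, 1); default 0.10.
#' @param n_boot Number of bootstrap iterations; default 200.
#' @param seed Integer seed; the whole computation is deterministic given
#'   (data, configuration, seed).
#' @param families Model suite; default [quantal_families()].
#' @param n_starts Multistarts for the initial suite fit (default 10).
#' @param boot_starts Starts per bootstrap refit (default 2: the warm start
#'   from the full-data fit plus one fresh Latin-hypercube draw).
#' @param keep_boot_fits Keep per-iteration fitted parameters so that
#'   bootstrap curves can be exported ([bmd_curves()], [autoplot.bmd_ma()]);
#'   default TRUE.
#'
#' @return An object of class `bmd_ma`: list with `bmd` (model-averaged
#'   point estimate), `bmdl`, `bmdu`, `ratio`, `narrow`, `bmr`,
#'   `risk_type = "extra"`, `n_boot`, `seed`, `n_censored`, `unreliable`
#'   flag (more than half the iterations censored or failed), the suite
#'   `fits` and `weights`, the per-iteration `boot` tibble, and the search
#'   window. Methods: [tidy()], [glance()], [autoplot()].
#' @examples
#' sim <- sim_quantal(n = 200, family = "log-logistic", bmd10 = 5,
#'                    background = 0.05, seed = 7)
#' fit <- ma_bmd(sim$dose, sim$outcome, n_boot = 20, seed = 7)
#' tidy(fit)
#' @export
ma_bmd <- function(dose, outcome, bmr = 0.10, n_boot = 200, seed = 1,
                   families = quantal_families(), n_starts = 10,
                   boot_starts = 2, keep_boot_fits = TRUE) {
  stopifnot(n_boot >= 1)
  dose <- as.numeric(dose); outcome <- as.numeric(outcome)
  ok <- !is.na(dose) & !is.na(outcome)
  dose <- dose[ok]; outcome <- outcome[ok]
  if (length(dose) < 10) {
    stop("ma_bmd(): need at least 10 complete (dose, outcome) pairs",
         call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  dr <- range(dose)
  fits <- fit_quantal_suite(dose, outcome, families, n_starts = n_starts)
  weights <- suite_weights(fits)
  curve <- ma_curve(fits, weights)
  p0 <- ma_background(fits, weights)
  point <- bmd_from_curve(curve, bmr, dr, p0 = p0)

  warm <- lapply(fits, function(f) if (f$degenerate) NULL else f$params)
  p_hat <- curve(dose)
  n <- length(dose)

  boot_bmd <- numeric(n_boot)
  boot_cens <- character(n_boot)
  boot_fits <- if (keep_boot_fits) vector("list", n_boot) else NULL
  for (b in seq_len(n_boot)) {
    y_star <- stats::rbinom(n, 1, p_hat)
    # refits tolerate a looser optimiser stop: the bootstrap percentiles
    # average over iterations, so per-iteration 1e-5 likelihood slack is
    # far below the Monte-Carlo noise
    fits_b <- fit_quantal_suite(dose, y_star, families,
                                n_starts = boot_starts, starts = warm,
                                control = list(maxit = 150, factr = 1e8))
    w_b <- tryCatch(suite_weights(fits_b), error = function(e) NULL)
    if (is.null(w_b)) {
      boot_bmd[b] <- NA_real_
      boot_cens[b] <- "failed"
      next
    }
    res_b <- bmd_from_curve(ma_curve(fits_b, w_b), bmr, dr,
                            p0 = ma_background(fits_b, w_b))
    boot_bmd[b] <- res_b$bmd
    boot_cens[b] <- res_b$censored
    if (keep_boot_fits) {
      boot_fits[[b]] <- list(
        params = lapply(fits_b, function(f)
          if (f$degenerate) list(p_const = f$p_const) else f$params),
        degenerate = vapply(fits_b, function(f) f$degenerate, logical(1)),
        family = families,
        weights = w_b
      )
    }
  }

  # censored iterations enter the percentiles at the window bound; failed
  # ones at the bound matching a flat curve (right)
  window <- c(dr[1] * 1e-6, dr[2] * 1e6)
  vals <- boot_bmd
  vals[boot_cens == "failed"] <- window[2]
  n_cens <- sum(boot_cens != "none")
  bmdl <- stats::quantile(vals, 0.05, type = 7, names = FALSE)
  bmdu <- stats::quantile(vals, 0.95, type = 7, names = FALSE)
  ratio <- bmdu / bmdl

  structure(
    list(
      bmd = point$bmd, bmd_censored = point$censored,
      bmdl = bmdl, bmdu = bmdu, ratio = ratio, narrow = ratio < 10,
      bmr = bmr, risk_type = "extra", n_boot = n_boot, seed = seed,
      n = n, n_censored = n_cens,
      unreliable = n_cens > n_boot / 2,
      fits = fits, weights = weights, p0 = p0,
      boot = tibble::tibble(iteration = seq_len(n_boot), bmd = boot_bmd,
                            censored = boot_cens),
      boot_fits = boot_fits,
      dose = dose, outcome = outcome, window = window
    ),
    class = "bmd_ma"
  )
}

#' @export
print.bmd_ma <- function(x, ...) {
  cat("<bmd_ma> model-averaged benchmark dose (extra risk, BMR ",
      format(100 * x$bmr), "%)\n", sep = "")
  cat("  BMD:", signif(x$bmd, 4), " BMDL:", signif(x$bmdl, 4),
      " BMDU:", signif(x$bmdu, 4), "\n")
  cat("  BMDU/BMDL:", signif(x$ratio, 4),
      if (x$narrow) "(narrow)" else "(wide)", "\n")
  cat("  bootstrap:", x$n_boot, "iterations,", x$n_censored,
      "censored; seed", x$seed, "\n")
  if (x$unreliable) cat("  WARNING: flagged unreliable (>50% censored)\n")
  invisible(x)
}

#' Evaluate the model-averaged and bootstrap response curves on a dose grid
#'
#' Reconstructs the averaged dose-response curve of a fitted [ma_bmd()]
#' object, plus one curve per retained bootstrap iteration, on a
#' log10-spaced dose grid — the data behind the classic bootstrap
#' curve fan plot.
#'
#' @param x A `bmd_ma` object fitted with `keep_boot_fits = TRUE`.
#' @param n_grid Number of grid points (default 50).
#' @param dose_range Grid range; defaults to the observed dose range.
#'
#' @return A tibble with `curve` (`"estimate"` or `"boot<i>"`),
#'   `iteration` (0 for the point estimate), `dose` and `response`.
#' @export
bmd_curves <- function(x, n_grid = 50, dose_range = NULL) {
  stopifnot(inherits(x, "bmd_ma"))
  if (is.null(dose_range)) dose_range <- range(x$dose)
  grid <- 10^seq(log10(dose_range[1]), log10(dose_range[2]),
                 length.out = n_grid)
  est <- tibble::tibble(
    curve = "estimate", iteration = 0L, dose = grid,
    response = ma_curve(x$fits, x$weights)(grid)
  )
  if (is.null(x$boot_fits)) {
    return(est)
  }
  boot <- purrr::imap_dfr(x$boot_fits, function(bf, b) {
    if (is.null(bf)) return(NULL)
    p <- numeric(length(grid))
    for (i in seq_along(bf$family)) {
      w <- bf$weights[i]
      if (w <= 0) next
      p <- p + w * (if (bf$degenerate[i]) {
        rep(bf$params[[i]]$p_const, length(grid))
      } else {
        quantal_prob(bf$family[i], bf$params[[i]], grid)
      })
    }
    tibble::tibble(curve = paste0("boot", b), iteration = as.integer(b),
                   dose = grid, response = p)
  })
  dplyr::bind_rows(est, boot)
}

#' @rdname bmd_curves
#' @param object A `bmd_ma` object.
#' @param max_boot Number of bootstrap curves to draw (default all).
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @method autoplot bmd_ma
#' @export
autoplot.bmd_ma <- function(object, n_grid = 50, max_boot = Inf, ...) {
  curves <- bmd_curves(object, n_grid = n_grid)
  boot <- dplyr::filter(curves, .data$iteration > 0,
                        .data$iteration <= max_boot)
  est <- dplyr::filter(curves, .data$iteration == 0)
  rug <- tibble::tibble(dose = object$dose, outcome = object$outcome)
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = boot,
      ggplot2::aes(x = log10(.data$dose), y = .data$response,
                   group = .data$curve),
      linetype = "dashed", linewidth = 0.2, colour = "grey30", alpha = 0.4
    ) +
    ggplot2::geom_line(
      data = est,
      ggplot2::aes(x = log10(.data$dose), y = .data$response),
      colour = "red", linewidth = 0.8
    ) +
    ggplot2::geom_point(
      data = rug,
      ggplot2::aes(x = log10(.data$dose), y = .data$outcome),
      shape = 17, colour = "red", alpha = 0.5, size = 1
    ) +
    ggplot2::geom_vline(xintercept = log10(object$bmd),
                        linetype = "dotted") +
    ggplot2::labs(
      x = "log10 dose", y = "quantal response",
      title = sprintf("Model-averaged dose-response (BMR %g%%, %d bootstrap curves)",
                      100 * object$bmr, object$n_boot)
    ) +
    ggplot2::theme_minimal()
}

# --- broom-style accessors -------------------------------------------------

#' Tidy a model-averaged BMD fit
#'
#' @param x A `bmd_ma` object.
#' @param ... Unused.
#' @return One-row tibble with the point estimate, confidence limits,
#'   interval ratio, narrowness flag and bootstrap provenance.
#' @method tidy bmd_ma
#' @export
tidy.bmd_ma <- function(x, ...) {
  tibble::tibble(
    bmd = x$bmd, bmdl = x$bmdl, bmdu = x$bmdu,
    ratio = x$ratio, narrow = x$narrow,
    bmr = x$bmr, risk_type = x$risk_type,
    n = x$n, n_boot = x$n_boot, n_censored = x$n_censored,
    unreliable = x$unreliable, seed = x$seed
  )
}

#' @rdname tidy.bmd_ma
#' @method glance bmd_ma
#' @export
glance.bmd_ma <- function(x, ...) {
  best <- which.max(x$weights)
  tibble::tibble(
    n = x$n, n_models = length(x$fits),
    n_converged = sum(vapply(x$fits, function(f) f$converged, logical(1))),
    best_family = x$fits[[best]]$family,
    best_weight = x$weights[best],
    p0 = x$p0
  )
}

#' Tidy a single quantal model fit
#'
#' @param x A `quantal_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per parameter (empty for degenerate fits).
#' @method tidy quantal_fit
#' @export
tidy.quantal_fit <- function(x, ...) {
  if (is.null(x$params)) {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  tibble::tibble(term = names(x$params),
                 estimate = unname(unlist(x$params)))
}

#' @rdname tidy.quantal_fit
#' @method glance quantal_fit
#' @export
glance.quantal_fit <- function(x, ...) {
  tibble::tibble(family = x$family, logLik = x$loglik, AIC = x$aic,
                 df = x$k, converged = x$converged,
                 degenerate = x$degenerate, nobs = x$n)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
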