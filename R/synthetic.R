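#' Default marginal calibration targets for the synthetic cohort
#'
#' Per-sex quartiles (p25, median, p75) of blood Ni and the five serum
#' hormones in a mixed clinical/healthy adult population. A two-parameter
#' log-normal is matched to the median and the p75/p25 spread of each row,
#' so p25 and p75 are reproduced in ratio, not each exactly.
#'
#' @return Tibble with `variable`, `sex`, `p25`, `median`, `p75`.
#' @export
default_marginals <- function() {
  tibble::tribble(
    ~variable, ~sex, ~p25,   ~median, ~p75,
    "ni",      "M",  2.902,  8.278,   14.20,
    "ni",      "F",  1.771,  7.609,   15.70,
    "tsh",     "M",  1.020,  1.870,   2.700,
    "tsh",     "F",  1.105,  1.790,   2.530,
    "ft4",     "M",  15.37,  16.84,   19.09,
    "ft4",     "F",  5.718,  15.63,   18.46,
    "ft3",     "M",  4.295,  4.760,   5.290,
    "ft3",     "F",  4.173,  4.910,   5.623,
    "t4",      "M",  101.4,  116.5,   132.8,
    "t4",      "F",  94.66,  109.7,   125.0,
    "t3",      "M",  1.630,  1.950,   2.180,
    "t3",      "F",  1.658,  1.955,   2.203
  )
}

#' Default per-endpoint missingness rates for the synthetic cohort
#'
#' Per-sex fractions of subjects lacking each hormone assay, chosen to
#' reproduce contingency-row totals below the stratum sizes (217 men /
#' 218 women) of the emulated study population.
#'
#' @return Tibble with `variable`, `sex`, `rate`.
#' @export
default_missingness <- function() {
  tibble::tribble(
    ~variable, ~sex, ~rate,
    "tsh", "M", 24 / 217, "tsh", "F", 15 / 218,
    "ft4", "M", 32 / 217, "ft4", "F", 10 / 218,
    "ft3", "M", 29 / 217, "ft3", "F", 14 / 218,
    "t4",  "M", 21 / 217, "t4",  "F", 12 / 218,
    "t3",  "M", 23 / 217, "t3",  "F", 17 / 218
  )
}

# log-normal parameters matched to (median, p75/p25): meanlog = log(median),
# sdlog = log(p75/p25) / (2 * qnorm(0.75)).
lognormal_from_quartiles <- function(p25, median, p75) {
  if (!(p25 < median && median < p75)) {
    stop("quartile targets must satisfy p25 < median < p75", call. = FALSE)
  }
  list(meanlog = log(median),
       sdlog = log(p75 / p25) / (2 * stats::qnorm(0.75)))
}

# inverse-CDF draw from a log-normal truncated to a union of intervals
# given as rbind(c(lo, hi), ...); used by the dose-response link to place a
# hormone value inside or outside its reference range while keeping the
# marginal shape.
rlnorm_region <- function(n, meanlog, sdlog, intervals) {
  lo <- pmax(intervals[, 1], 0)
  hi <- intervals[, 2]
  p_lo <- stats::plnorm(lo, meanlog, sdlog)
  p_hi <- stats::plnorm(hi, meanlog, sdlog)
  mass <- pmax(p_hi - p_lo, 0)
  total <- sum(mass)
  if (total <= 1e-12) {
    # the region carries no mass under the marginal; fall back to the
    # nearest boundary of the widest interval
    return(rep(hi[which.max(hi - lo)], n))
  }
  seg <- sample.int(length(mass), n, replace = TRUE, prob = mass / total)
  u <- stats::runif(n, p_lo[seg], p_hi[seg])
  stats::qlnorm(u, meanlog, sdlog)
}

#' Generate a synthetic biomonitoring cohort
#'
#' Draws a seeded, reproducible cohort with the statistical structure the
#' pipeline assumes: per-sex right-skewed (log-normal) blood Ni, hormone
#' panels with log-normal marginals matched to per-sex quartile targets,
#' per-endpoint missingness, and (optionally) a quantal dose-response link
#' that makes the probability of a hormone falling outside its reference
#' range follow a specified model of Ni.
#'
#' Hormones are drawn independently of one another by default; the study
#' population the defaults emulate provides only marginal quartiles. SPINA
#' parameters are not simulated — compute them from the drawn hormones
#' with [add_spina()].
#'
#' @param n_men,n_women Stratum sizes (defaults 217 / 218).
#' @param seed Integer seed; identical configuration + seed gives an
#'   identical cohort.
#' @param marginals Quartile targets: tibble with `variable`, `sex`,
#'   `p25`, `median`, `p75` (default [default_marginals()] values).
#' @param missingness Per-endpoint missing rates: tibble with `variable`,
#'   `sex`, `rate` in \[0, 1); defaults emulate per-assay availability.
#'   Pass a zero-rate table for complete data.
#' @param link Optional dose-response link: a list with `endpoint` (one of
#'   tsh, ft4, ft3, t4, t3), `family` (a [quantal_families()] name),
#'   `params` (natural parameters for [quantal_prob()]). When set, each
#'   subject's endpoint value is drawn from its marginal truncated inside
#'   or outside the reference range according to a Bernoulli draw with
#'   probability `quantal_prob(family, params, ni)`, so the quantal table
#'   and the continuous values stay consistent.
#' @param ranges Reference ranges used by the link; default
#'   [reference_ranges()].
#' @param prop_healthy Proportion labelled `healthy` (default 136/435, the
#'   emulated design); the rest are `unhealthy`.
#' @param age_range Uniform age bounds (default c(18, 94)).
#'
#' @return A tibble with columns `id`, `sex` ("M"/"F"), `age`, `health`,
#'   `ni` (ug/L), `tsh`, `ft4`, `ft3`, `t4`, `t3`.
#' @examples
#' sim_cohort(n_men = 20, n_women = 20, seed = 1)
#' @export
sim_cohort <- function(n_men = 217, n_women = 218, seed = 1,
                       marginals = default_marginals(),
                       missingness = default_missingness(),
                       link = NULL,
                       ranges = reference_ranges(),
                       prop_healthy = 136 / 435,
                       age_range = c(18, 94)) {
  stopifnot(n_men >= 0, n_women >= 0, n_men + n_women >= 1,
            is.data.frame(marginals),
            all(c("variable", "sex", "p25", "median", "p75") %in% names(marginals)))
  if (any(missingness$rate < 0 | missingness$rate >= 1)) {
    stop("sim_cohort(): missingness rates must be in [0, 1)", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  n <- n_men + n_women
  cohort <- tibble::tibble(
    id = sprintf("S%04d", seq_len(n)),
    sex = c(rep("M", n_men), rep("F", n_women)),
    age = round(stats::runif(n, age_range[1], age_range[2])),
    health = ifelse(stats::runif(n) < prop_healthy, "healthy", "unhealthy")
  )

  draw_var <- function(variable, sex_vec) {
    out <- rep(NA_real_, length(sex_vec))
    for (sx in unique(sex_vec)) {
      m <- marginals[marginals$variable == variable & marginals$sex == sx, ]
      if (nrow(m) != 1) {
        stop("sim_cohort(): no quartile target for ", variable, "/", sx,
             call. = FALSE)
      }
      par <- lognormal_from_quartiles(m$p25, m$median, m$p75)
      idx <- sex_vec == sx
      out[idx] <- stats::rlnorm(sum(idx), par$meanlog, par$sdlog)
    }
    out
  }

  cohort$ni <- draw_var("ni", cohort$sex)

  hormones <- c("tsh", "ft4", "ft3", "t4", "t3")
  link_ep <- if (!is.null(link)) link$endpoint else NULL
  if (!is.null(link_ep)) {
    if (!link_ep %in% hormones) {
      stop("sim_cohort(): link endpoint must be a measured hormone (",
           paste(hormones, collapse = ", "), "); SPINA endpoints are ",
           "computed, not drawn", call. = FALSE)
    }
    if (!all(c("family", "params") %in% names(link))) {
      stop("sim_cohort(): link needs 'endpoint', 'family' and 'params'",
           call. = FALSE)
    }
  }

  for (h in hormones) {
    if (identical(h, link_ep)) {
      cohort[[h]] <- draw_linked_endpoint(cohort, h, link, marginals, ranges)
    } else {
      cohort[[h]] <- draw_var(h, cohort$sex)
    }
  }

  # per-endpoint missingness, applied after the draws
  for (i in seq_len(nrow(missingness))) {
    row <- missingness[i, ]
    if (!row$variable %in% names(cohort)) next
    idx <- cohort$sex == row$sex & stats::runif(n) < row$rate
    cohort[[row$variable]][idx] <- NA_real_
  }
  cohort
}

# Draw one hormone endpoint under the quantal dose-response link: the
# out-of-range indicator is Bernoulli(P(ni)); the value is then drawn from
# the sex-specific marginal truncated to the corresponding region.
draw_linked_endpoint <- function(cohort, h, link, marginals, ranges) {
  rr <- ranges[ranges$endpoint == h, ]
  if (nrow(rr) != 1) {
    stop("sim_cohort(): no reference range for link endpoint '", h, "'",
         call. = FALSE)
  }
  p_out <- quantal_prob(link$family, link$params, cohort$ni)
  is_out <- stats::runif(nrow(cohort)) < p_out
  out <- rep(NA_real_, nrow(cohort))
  for (sx in unique(cohort$sex)) {
    m <- marginals[marginals$variable == h & marginals$sex == sx, ]
    par <- lognormal_from_quartiles(m$p25, m$median, m$p75)
    idx_in <- which(cohort$sex == sx & !is_out)
    idx_out <- which(cohort$sex == sx & is_out)
    if (length(idx_in)) {
      out[idx_in] <- rlnorm_region(length(idx_in), par$meanlog, par$sdlog,
                                   rbind(c(rr$low, rr$high)))
    }
    if (length(idx_out)) {
      out[idx_out] <- rlnorm_region(length(idx_out), par$meanlog, par$sdlog,
                                    rbind(c(0, rr$low), c(rr$high, Inf)))
    }
  }
  out
}

#' Simulate individual-level quantal dose-response data
#'
#' The test harness for the BMD engine: draws doses from a log-uniform or
#' log-normal specification and outcomes as Bernoulli(P(dose)) under a
#' chosen quantal family whose true benchmark dose is known in closed form.
#'
#' @param n Number of subjects.
#' @param family A [quantal_families()] name.
#' @param params Natural parameters for [quantal_prob()]. Alternatively
#'   supply `bmd10` + `background` (+ `sigma`) for a log-logistic or
#'   log-probit family and the location is solved so the true extra-risk
#'   BMD at 10% equals `bmd10`.
#' @param bmd10,background,sigma Convenience parameterisation (see above);
#'   `sigma` defaults to 0.5.
#' @param dose_spec Either `list(type = "log-uniform", min =, max =)` or
#'   `list(type = "log-normal", meanlog =, sdlog =)`. Default: log-normal
#'   calibrated to the entire-population Ni quartiles of the default
#'   synthetic cohort.
#' @param seed Integer seed.
#'
#' @return A list with `dose`, `outcome`, `true_bmd10` (closed form where
#'   available, otherwise solved numerically from the true curve),
#'   `family`, `params`.
#' @examples
#' sim_quantal(100, "log-logistic", bmd10 = 5, background = 0.05, seed = 1)$true_bmd10
#' @export
sim_quantal <- function(n, family = "log-logistic", params = NULL,
                        bmd10 = NULL, background = 0.05, sigma = 0.5,
                        dose_spec = list(type = "log-normal",
                                         meanlog = log(8.054),
                                         sdlog = log(15.46 / 2.428) /
                                           (2 * stats::qnorm(0.75))),
                        seed = 1) {
  family <- match.arg(family, quantal_families())
  if (is.null(params)) {
    if (is.null(bmd10)) {
      stop("sim_quantal(): supply params or bmd10", call. = FALSE)
    }
    if (!family %in% c("log-logistic", "log-probit")) {
      stop("sim_quantal(): the bmd10 shortcut needs a log-dose family",
           call. = FALSE)
    }
    # extra risk F((log BMD - mu)/sigma) = 0.10 => mu = log(bmd10) - sigma * F^{-1}(0.10)
    qf <- if (family == "log-logistic") stats::qlogis else stats::qnorm
    params <- c(a = background, mu = log(bmd10) - sigma * qf(0.10),
                sigma = sigma)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  dose <- switch(dose_spec$type,
    "log-uniform" = exp(stats::runif(n, log(dose_spec$min), log(dose_spec$max))),
    "log-normal" = stats::rlnorm(n, dose_spec$meanlog, dose_spec$sdlog),
    stop("sim_quantal(): dose_spec$type must be 'log-uniform' or 'log-normal'",
         call. = FALSE)
  )
  p <- quantal_prob(family, params, dose)
  outcome <- stats::rbinom(n, 1, p)
  true_bmd10 <- true_bmd(family, params, bmr = 0.10,
                         dose_range = range(dose))
  list(dose = dose, outcome = outcome, true_bmd10 = true_bmd10,
       family = family, params = params)
}

# Closed-form extra-risk BMD where available; numeric inversion otherwise.
true_bmd <- function(family, params, bmr = 0.10, dose_range = c(1e-3, 1e3)) {
  p <- as.list(params)
  switch(family,
    "log-logistic" = exp(p$mu + p$sigma * stats::qlogis(bmr)),
    "log-probit" = exp(p$mu + p$sigma * stats::qnorm(bmr)),
    "weibull" = p$b * (-log(1 - bmr))^(1 / p$c),
    "two-stage" = if (p$c == 0) -log(1 - bmr) / p$b else {
      (-p$b + sqrt(p$b^2 - 4 * p$c * log(1 - bmr))) / (2 * p$c)
    },
    bmd_from_curve(function(d) quantal_prob(family, params, d),
                   bmr = bmr, dose_range = dose_range)$bmd
  )
}
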