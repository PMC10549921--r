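#' The quantal dose-response model suite
#'
#' Names of the classical quantal families used for model averaging:
#' logistic, probit, log-logistic, log-probit, Weibull, gamma and two-stage.
#' All are parameterised so that the response probability is nondecreasing
#' in dose and (for the background families) starts at a background rate
#' `a` at dose zero.
#'
#' @return Character vector of family names.
#' @export
quantal_families <- function() {
  c("logistic", "probit", "log-logistic", "log-probit",
    "weibull", "gamma", "two-stage")
}

#' Response probability of a quantal dose-response family
#'
#' Evaluates P(dose) for one family at the given natural-scale parameters:
#' \itemize{
#'   \item logistic: \eqn{P = 1/(1+e^{-(\alpha+\beta d)})}
#'   \item probit: \eqn{P = \Phi(\alpha+\beta d)}
#'   \item log-logistic: \eqn{P = a + (1-a)/(1+e^{-(\ln d-\mu)/\sigma})}
#'   \item log-probit: \eqn{P = a + (1-a)\Phi((\ln d-\mu)/\sigma)}
#'   \item weibull: \eqn{P = a + (1-a)(1-e^{-(d/b)^c})}
#'   \item gamma: \eqn{P = a + (1-a)\,\Gamma_{reg}(c, d/b)}
#'   \item two-stage: \eqn{P = a + (1-a)(1-e^{-(b d + c d^2)})}
#' }
#'
#' @param family One of [quantal_families()].
#' @param params Named numeric vector/list of natural parameters:
#'   `alpha`, `beta` for logistic/probit; `a`, `mu`, `sigma` for
#'   log-logistic/log-probit; `a`, `b`, `c` for weibull/gamma/two-stage.
#' @param dose Numeric vector of doses; must be strictly positive for the
#'   log-dose families.
#'
#' @return Numeric vector of probabilities in \[0, 1\].
#' @examples
#' quantal_prob("log-logistic", c(a = 0, mu = log(10), sigma = 1), 10) # 0.5
#' @export
quantal_prob <- function(family, params, dose) {
  family <- match.arg(family, quantal_families())
  p <- as.list(params)
  dose <- as.numeric(dose)
  if (family %in% c("log-logistic", "log-probit") && any(dose <= 0, na.rm = TRUE)) {
    stop("quantal_prob(): log-dose families require dose > 0", call. = FALSE)
  }
  if (any(dose < 0, na.rm = TRUE)) {
    stop("quantal_prob(): dose must be non-negative", call. = FALSE)
  }
  check_params(family, p)
  switch(family,
    "logistic" = stats::plogis(p$alpha + p$beta * dose),
    "probit" = stats::pnorm(p$alpha + p$beta * dose),
    "log-logistic" = p$a + (1 - p$a) * stats::plogis((log(dose) - p$mu) / p$sigma),
    "log-probit" = p$a + (1 - p$a) * stats::pnorm((log(dose) - p$mu) / p$sigma),
    "weibull" = p$a + (1 - p$a) * (1 - exp(-(dose / p$b)^p$c)),
    "gamma" = p$a + (1 - p$a) * stats::pgamma(dose / p$b, shape = p$c),
    "two-stage" = p$a + (1 - p$a) * (1 - exp(-(p$b * dose + p$c * dose^2)))
  )
}

# Background response P0 = lim_{d -> 0+} P(d) for a family.
quantal_background <- function(family, params) {
  p <- as.list(params)
  switch(family,
    "logistic" = stats::plogis(p$alpha),
    "probit" = stats::pnorm(p$alpha),
    p$a
  )
}

check_params <- function(family, p) {
  need <- switch(family,
    "logistic" = ,
    "probit" = c("alpha", "beta"),
    "log-logistic" = ,
    "log-probit" = c("a", "mu", "sigma"),
    c("a", "b", "c")
  )
  if (!all(need %in% names(p))) {
    stop("quantal_prob(): family '", family, "' needs parameters ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if ("a" %in% need && (p$a < 0 || p$a >= 1)) {
    stop("quantal_prob(): background a must be in [0, 1)", call. = FALSE)
  }
  pos <- switch(family,
    "logistic" = , "probit" = "beta",
    "log-logistic" = , "log-probit" = "sigma",
    "weibull" = , "gamma" = c("b", "c"),
    "two-stage" = "b" # c >= 0 allowed (reduces to one-stage)
  )
  for (nm in pos) {
    if (p[[nm]] <= 0) {
      stop("quantal_prob(): parameter '", nm, "' must be positive", call. = FALSE)
    }
  }
  if (family == "two-stage" && p$c < 0) {
    stop("quantal_prob(): two-stage c must be >= 0", call. = FALSE)
  }
  invisible(TRUE)
}

# --- internal fitting machinery -------------------------------------------
#
# Fits work on doses scaled by their maximum (d' = d / s), which keeps the
# optimiser boxes generic across exposure scales; fitted parameters are
# mapped back to the natural dose scale before they are returned.
#
# Internal optimiser coordinates per family (box-constrained L-BFGS-B):
#   logistic/probit : (alpha, log beta')         alpha in [-30, 30],
#                                                log beta' in [log .01, log 1e4]
#   log-logistic/-probit : (a, mu', log sigma)   a in [0, 1-1e-6],
#                                                mu' in [log min d' - 15, 15],
#                                                log sigma in [log .01, log 20]
#   weibull/gamma  : (a, log b', log c)          log b' in [log min d' - 15, 15],
#                                                log c in [log .01, log 20]
#   two-stage      : (a, log b', log c')         log b', log c' in [log 1e-8, log 1e6]
#
# The lower bounds on slopes/shapes keep the extra-risk inversion well posed
# near zero dose; backgrounds are capped just below 1.

family_box <- function(family, dmin_scaled) {
  lo_mu <- log(dmin_scaled) - 15
  switch(family,
    "logistic" = ,
    "probit" = list(
      par_names = c("alpha", "lbeta"),
      lower = c(-30, log(1e-2)), upper = c(30, log(1e4))
    ),
    "log-logistic" = ,
    "log-probit" = list(
      par_names = c("a", "mu", "lsigma"),
      lower = c(0, lo_mu, log(1e-2)), upper = c(1 - 1e-6, 15, log(20))
    ),
    "weibull" = ,
    "gamma" = list(
      par_names = c("a", "lb", "lc"),
      lower = c(0, lo_mu, log(1e-2)), upper = c(1 - 1e-6, 15, log(20))
    ),
    "two-stage" = list(
      par_names = c("a", "lb", "lc"),
      lower = c(0, log(1e-8), log(1e-8)), upper = c(1 - 1e-6, log(1e6), log(1e6))
    )
  )
}

# probability on the scaled-dose axis from internal coordinates
prob_internal <- function(family, theta, dose_s, log_dose_s) {
  switch(family,
    "logistic" = stats::plogis(theta[1] + exp(theta[2]) * dose_s),
    "probit" = stats::pnorm(theta[1] + exp(theta[2]) * dose_s),
    "log-logistic" = theta[1] + (1 - theta[1]) *
      stats::plogis((log_dose_s - theta[2]) / exp(theta[3])),
    "log-probit" = theta[1] + (1 - theta[1]) *
      stats::pnorm((log_dose_s - theta[2]) / exp(theta[3])),
    "weibull" = theta[1] + (1 - theta[1]) *
      (1 - exp(-exp(exp(theta[3]) * (log_dose_s - theta[2])))),
    "gamma" = theta[1] + (1 - theta[1]) *
      stats::pgamma(exp(log_dose_s - theta[2]), shape = exp(theta[3])),
    "two-stage" = theta[1] + (1 - theta[1]) *
      (1 - exp(-(exp(theta[2]) * dose_s + exp(theta[3]) * dose_s^2)))
  )
}

# internal coords -> natural-scale named parameters (undo the dose scaling).
# L-BFGS-B can land a rounding error outside its box; clamp the background.
natural_params <- function(family, theta, dose_scale) {
  if (family %in% c("log-logistic", "log-probit", "weibull", "gamma",
                    "two-stage")) {
    theta[[1]] <- min(max(theta[[1]], 0), 1 - 1e-6)
  }
  switch(family,
    "logistic" = ,
    "probit" = c(alpha = theta[[1]], beta = exp(theta[[2]]) / dose_scale),
    "log-logistic" = ,
    "log-probit" = c(a = theta[[1]], mu = theta[[2]] + log(dose_scale),
                     sigma = exp(theta[[3]])),
    "weibull" = ,
    "gamma" = c(a = theta[[1]], b = exp(theta[[2]]) * dose_scale,
                c = exp(theta[[3]])),
    "two-stage" = c(a = theta[[1]], b = exp(theta[[2]]) / dose_scale,
                    c = exp(theta[[3]]) / dose_scale^2)
  )
}

# natural-scale params -> internal coords (used to warm-start refits)
internal_coords <- function(family, params, dose_scale, box) {
  p <- as.list(params)
  theta <- switch(family,
    "logistic" = ,
    "probit" = c(p$alpha, log(p$beta * dose_scale)),
    "log-logistic" = ,
    "log-probit" = c(p$a, p$mu - log(dose_scale), log(p$sigma)),
    "weibull" = ,
    "gamma" = c(p$a, log(p$b / dose_scale), log(p$c)),
    "two-stage" = c(p$a, log(max(p$b * dose_scale, 1e-300)),
                    log(max(p$c * dose_scale^2, 1e-300)))
  )
  pmin(pmax(theta, box$lower), box$upper)
}

bernoulli_loglik <- function(prob, y1) {
  prob[prob < 1e-12] <- 1e-12
  prob[prob > 1 - 1e-12] <- 1 - 1e-12
  sum(log(prob[y1])) + sum(log1p(-prob[!y1]))
}

# Gradient of the Bernoulli log-likelihood in the internal optimiser
# coordinates: dL/dtheta_j = sum_i (y_i - P_i)/(P_i(1-P_i)) dP_i/dtheta_j.
# All partials are closed-form except the gamma shape, which uses a central
# difference (pgamma has no elementary shape derivative).
loglik_grad_internal <- function(family, theta, dose_s, log_dose_s, y1,
                                 P = NULL) {
  if (is.null(P)) P <- prob_internal(family, theta, dose_s, log_dose_s)
  Pc <- P
  Pc[Pc < 1e-12] <- 1e-12
  Pc[Pc > 1 - 1e-12] <- 1 - 1e-12
  w <- (y1 - Pc) / (Pc * (1 - Pc))
  switch(family,
    "logistic" = {
      eta <- theta[1] + exp(theta[2]) * dose_s
      dPdeta <- Pc * (1 - Pc)
      c(sum(w * dPdeta), sum(w * dPdeta * exp(theta[2]) * dose_s))
    },
    "probit" = {
      eta <- theta[1] + exp(theta[2]) * dose_s
      dPdeta <- stats::dnorm(eta)
      c(sum(w * dPdeta), sum(w * dPdeta * exp(theta[2]) * dose_s))
    },
    "log-logistic" = ,
    "log-probit" = {
      a <- theta[1]; mu <- theta[2]; sigma <- exp(theta[3])
      z <- (log_dose_s - mu) / sigma
      if (family == "log-logistic") {
        Fz <- stats::plogis(z); fz <- Fz * (1 - Fz)
      } else {
        Fz <- stats::pnorm(z); fz <- stats::dnorm(z)
      }
      c(sum(w * (1 - Fz)),
        sum(w * (-(1 - a) * fz / sigma)),
        sum(w * (-(1 - a) * fz * z)))
    },
    "weibull" = {
      a <- theta[1]; lb <- theta[2]; cc <- exp(theta[3])
      t <- exp(cc * (log_dose_s - lb))
      E <- exp(-t)
      # P = a + (1-a)(1-E), E = exp(-t), t = (d/b)^c = exp(c (log d - lb))
      c(sum(w * E),
        sum(w * (-(1 - a) * E * cc * t)),
        sum(w * (1 - a) * E * t * cc * (log_dose_s - lb)))
    },
    "gamma" = {
      a <- theta[1]; x <- exp(log_dose_s - theta[2]); cc <- exp(theta[3])
      G <- stats::pgamma(x, shape = cc)
      g <- stats::dgamma(x, shape = cc)
      # forward difference on the shape, reusing the current likelihood
      h <- 1e-6
      dshape <- (bernoulli_loglik(a + (1 - a) *
                   stats::pgamma(x, shape = exp(theta[3] + h)), y1) -
                 bernoulli_loglik(P, y1)) / h
      c(sum(w * (1 - G)),
        sum(w * (1 - a) * g * (-x)),
        dshape)
    },
    "two-stage" = {
      a <- theta[1]; b <- exp(theta[2]); cc <- exp(theta[3])
      E <- exp(-(b * dose_s + cc * dose_s^2))
      c(sum(w * E),
        sum(w * (1 - a) * E * b * dose_s),
        sum(w * (1 - a) * E * cc * dose_s^2))
    }
  )
}

#' Fit one quantal dose-response model by maximum likelihood
#'
#' Maximises the individual-level Bernoulli log-likelihood
#' \eqn{\sum_i y_i \ln P(d_i) + (1-y_i)\ln(1-P(d_i))} under the family's
#' monotonicity constraints, using box-constrained quasi-Newton iterations
#' from multiple Latin-hypercube starting points (the best converged
#' likelihood is kept). Dose-independent data collapse every family onto
#' the background-only fit.
#'
#' @param dose Strictly positive numeric vector of doses.
#' @param outcome 0/1 vector of quantal outcomes, same length.
#' @param family One of [quantal_families()].
#' @param n_starts Number of Latin-hypercube multistarts (default 10).
#' @param start Optional named natural-scale parameter vector used as an
#'   additional (first) starting point, e.g. to warm-start bootstrap refits.
#' @param control Control list passed to [stats::optim()].
#'
#' @return An object of class `quantal_fit`: a list with `family`,
#'   `params` (natural scale), `loglik`, `k` (number of parameters),
#'   `aic`, `converged`, `degenerate`, `n`, and the dose range used.
#'   Uses the current RNG stream for the multistart draws; seed it (or call
#'   from [ma_bmd()], which seeds) for reproducibility.
#' @examples
#' set.seed(1)
#' d <- exp(stats::runif(60, log(0.5), log(50)))
#' y <- stats::rbinom(60, 1, quantal_prob("log-logistic",
#'   c(a = 0.05, mu = log(8), sigma = 0.5), d))
#' fit_quantal(d, y, "log-logistic")
#' @export
fit_quantal <- function(dose, outcome, family, n_starts = 10, start = NULL,
                        control = list(maxit = 300)) {
  family <- match.arg(family, quantal_families())
  dose <- as.numeric(dose)
  outcome <- as.numeric(outcome)
  stopifnot(length(dose) == length(outcome))
  ok <- !is.na(dose) & !is.na(outcome)
  dose <- dose[ok]; outcome <- outcome[ok]
  n <- length(dose)
  if (n < 2) stop("fit_quantal(): need at least 2 observations", call. = FALSE)
  if (any(dose <= 0)) stop("fit_quantal(): doses must be > 0", call. = FALSE)
  if (!all(outcome %in% c(0, 1))) {
    stop("fit_quantal(): outcomes must be 0/1", call. = FALSE)
  }

  k_ones <- sum(outcome)
  # degenerate: one outcome class -> background-only model, flagged
  if (k_ones == 0 || k_ones == n) {
    p_hat <- k_ones / n
    ll <- 0 # k log k/n + (n-k) log(1 - k/n) with 0 log 0 = 0
    return(new_quantal_fit(family, params = NULL, loglik = ll, k = 1,
                           converged = TRUE, degenerate = TRUE, n = n,
                           p_const = p_hat, dose_range = range(dose)))
  }

  s <- max(dose)
  dose_s <- dose / s
  log_dose_s <- log(dose_s)
  y1 <- outcome == 1
  box <- family_box(family, min(dose_s))
  k <- length(box$par_names)

  # optim evaluates the objective and its gradient at the same point in
  # sequence; cache the probability vector so it is computed once
  cache_theta <- NULL
  cache_P <- NULL
  prob_at <- function(theta) {
    if (is.null(cache_theta) || !identical(theta, cache_theta)) {
      cache_theta <<- theta
      cache_P <<- prob_internal(family, theta, dose_s, log_dose_s)
    }
    cache_P
  }
  negll <- function(theta) -bernoulli_loglik(prob_at(theta), y1)
  negll_grad <- function(theta) {
    -loglik_grad_internal(family, theta, dose_s, log_dose_s, y1,
                          P = prob_at(theta))
  }

  # starting points: optional warm start, box centre, Latin-hypercube draws
  starts <- list()
  if (!is.null(start)) {
    starts[[length(starts) + 1]] <- internal_coords(family, start, s, box)
  }
  starts[[length(starts) + 1]] <- (box$lower + box$upper) / 2
  n_lhs <- max(n_starts - length(starts), 0)
  if (n_lhs > 0) {
    u <- lhs::randomLHS(n_lhs, k)
    for (i in seq_len(n_lhs)) {
      starts[[length(starts) + 1]] <-
        box$lower + u[i, ] * (box$upper - box$lower)
    }
  }

  best <- NULL
  best_conv <- NULL
  for (th0 in starts) {
    res <- tryCatch(
      stats::optim(th0, negll, gr = negll_grad, method = "L-BFGS-B",
                   lower = box$lower, upper = box$upper, control = control),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) best <- res
    if (res$convergence == 0 &&
        (is.null(best_conv) || res$value < best_conv$value)) {
      best_conv <- res
    }
  }
  if (is.null(best)) {
    return(new_quantal_fit(family, params = NULL, loglik = -Inf, k = k,
                           converged = FALSE, degenerate = FALSE, n = n,
                           dose_range = range(dose)))
  }
  use <- if (!is.null(best_conv)) best_conv else best
  params <- natural_params(family, as.list(use$par), s)
  new_quantal_fit(family, params = params, loglik = -use$value, k = k,
                  converged = !is.null(best_conv),
                  degenerate = FALSE, n = n, dose_range = range(dose))
}

new_quantal_fit <- function(family, params, loglik, k, converged, degenerate,
                            n, p_const = NULL, dose_range = c(NA, NA)) {
  structure(
    list(family = family, params = params, loglik = loglik, k = k,
         aic = 2 * k - 2 * loglik, converged = converged,
         degenerate = degenerate, n = n, p_const = p_const,
         dose_range = dose_range),
    class = "quantal_fit"
  )
}

#' @export
print.quantal_fit <- function(x, ...) {
  cat("<quantal_fit>", x$family,
      if (x$degenerate) "(degenerate: background-only)" else "",
      "\n  logLik:", format(x$loglik), " AIC:", format(x$aic),
      " converged:", x$converged, "\n")
  if (!is.null(x$params)) {
    cat("  params:", paste(names(x$params), signif(unlist(x$params), 5),
                           sep = " = ", collapse = ", "), "\n")
  } else if (!is.null(x$p_const)) {
    cat("  constant response:", format(x$p_const), "\n")
  }
  invisible(x)
}

# Evaluate a fitted model's response curve at natural doses.
predict_quantal <- function(fit, dose) {
  if (fit$degenerate || is.null(fit$params)) {
    return(rep(if (is.null(fit$p_const)) NA_real_ else fit$p_const,
               length(dose)))
  }
  quantal_prob(fit$family, fit$params, dose)
}

#' Akaike weights from a vector of AIC values
#'
#' \eqn{w_k = \exp(-\Delta_k/2) / \sum_j \exp(-\Delta_j/2)} with
#' \eqn{\Delta_k = AIC_k - \min AIC}. Non-finite AIC values (failed fits)
#' receive weight zero.
#'
#' @param aic Numeric vector of AIC values, at least one finite.
#' @return Numeric weights summing to 1.
#' @examples
#' akaike_weights(c(100, 102)) # ~0.731, 0.269
#' @export
akaike_weights <- function(aic) {
  aic <- as.numeric(aic)
  fin <- is.finite(aic)
  if (!any(fin)) stop("akaike_weights(): no finite AIC values", call. = FALSE)
  w <- numeric(length(aic))
  delta <- aic[fin] - min(aic[fin])
  w[fin] <- exp(-delta / 2)
  w / sum(w)
}
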