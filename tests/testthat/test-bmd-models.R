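test_that("response curves hit their landmark values and saturate", {
  expect_equal(quantal_prob("log-logistic", c(a = 0, mu = log(10), sigma = 1), 10),
               0.5)
  expect_equal(quantal_prob("log-probit", c(a = 0.2, mu = log(5), sigma = 2), 5),
               0.2 + 0.8 * 0.5)
  expect_gt(quantal_prob("weibull", c(a = 0.2, b = 3, c = 1.5), 1e6), 0.9999)
  expect_equal(quantal_prob("two-stage", c(a = 0.1, b = 0.2, c = 0), 0), 0.1)
})

test_that("every family is nondecreasing in dose under its constraints", {
  d <- exp(seq(log(0.01), log(100), length.out = 80))
  pars <- list(
    "logistic" = c(alpha = -3, beta = 0.2),
    "probit" = c(alpha = -2, beta = 0.1),
    "log-logistic" = c(a = 0.07, mu = 1.5, sigma = 0.8),
    "log-probit" = c(a = 0.03, mu = 2, sigma = 1.2),
    "weibull" = c(a = 0.05, b = 8, c = 0.7),
    "gamma" = c(a = 0.05, b = 4, c = 1.8),
    "two-stage" = c(a = 0.08, b = 0.03, c = 0.001)
  )
  for (fam in quantal_families()) {
    p <- quantal_prob(fam, pars[[fam]], d)
    expect_true(all(diff(p) >= -1e-12), label = paste(fam, "monotone"))
    expect_true(all(p >= 0 & p <= 1), label = paste(fam, "bounded"))
  }
  expect_error(quantal_prob("log-logistic", pars[["log-logistic"]], c(1, 0)),
               "dose > 0")
  expect_error(quantal_prob("weibull", c(a = 1.2, b = 1, c = 1), 1),
               "background")
})

test_that("dose-independent data collapse every family onto the analytic
           null likelihood", {
  # identical doses carry no information: MLE is the constant k/n
  n <- 24; k <- 7
  d <- rep(5, n)
  y <- c(rep(1, k), rep(0, n - k))
  ll_null <- k * log(k / n) + (n - k) * log(1 - k / n)
  set.seed(1)
  for (fam in quantal_families()) {
    fit <- fit_quantal(d, y, fam)
    expect_equal(fit$loglik, ll_null, tolerance = 1e-6,
                 label = paste(fam, "null collapse"))
  }
  # the two-point version from first principles: P-hat = 1/2
  fit2 <- fit_quantal(c(1, 1), c(0, 1), "logistic")
  expect_equal(fit2$loglik, 2 * log(0.5), tolerance = 1e-6)
})

test_that("single-class outcomes yield a flagged degenerate fit and the
           likelihood never falls below the background-only model", {
  set.seed(2)
  d <- rlnorm(40, 1, 0.8)
  fit0 <- fit_quantal(d, rep(0, 40), "gamma")
  expect_true(fit0$degenerate)
  expect_equal(fit0$loglik, 0)
  expect_equal(fit0$p_const, 0)
  # nesting: fitted loglik >= analytic null loglik for mixed outcomes
  y <- rbinom(40, 1, 0.3)
  k <- sum(y)
  ll_null <- k * log(k / 40) + (40 - k) * log(1 - k / 40)
  for (fam in quantal_families()) {
    expect_gte(fit_quantal(d, y, fam)$loglik, ll_null - 1e-8)
  }
})

test_that("the constrained optimiser reaches the brute-force grid optimum
           on a seeded log-logistic dataset", {
  sim <- sim_quantal(50, "log-logistic", bmd10 = 5, background = 0.05,
                     seed = 1234)
  set.seed(99)
  for (fam in c("log-logistic", "weibull")) {
    fit <- fit_quantal(sim$dose, sim$outcome, fam)
    oracle <- oracle_grid_mle(fam, sim$dose, sim$outcome)
    expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6,
                 label = paste(fam, "grid oracle"))
  }
})

test_that("Akaike weights normalise, respect AIC differences and shift
           invariance", {
  expect_equal(akaike_weights(rep(3, 5)), rep(0.2, 5))
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  # invariant under adding a constant
  set.seed(7)
  a <- runif(6, 50, 90)
  expect_equal(akaike_weights(a), akaike_weights(a + 123.4))
  expect_equal(sum(akaike_weights(a)), 1)
  # an overwhelmingly better model takes all the weight
  expect_equal(akaike_weights(c(0, 1e4))[1], 1)
  # failed fits carry zero weight
  expect_equal(akaike_weights(c(10, Inf, 12))[2], 0)
  expect_error(akaike_weights(c(Inf, NA)), "finite")
})
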