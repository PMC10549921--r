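test_that("curve inversion reproduces closed-form benchmark doses", {
  # log-logistic, zero background: extra risk 0.10 at mu + sigma*log(1/9)
  f1 <- function(d) quantal_prob("log-logistic",
                                 c(a = 0, mu = log(10), sigma = 1), d)
  expect_equal(bmd_from_curve(f1, 0.10, c(1, 100))$bmd, 10 / 9,
               tolerance = 1e-6)
  # one-stage (two-stage with c = 0): BMD = -log(0.9)/b
  b <- 0.07
  f2 <- function(d) quantal_prob("two-stage", c(a = 0, b = b, c = 0), d)
  expect_equal(bmd_from_curve(f2, 0.10, c(0.5, 50))$bmd, -log(0.9) / b,
               tolerance = 1e-6)
  # nonzero background: the extra-risk target shifts with P0
  f3 <- function(d) quantal_prob("log-probit",
                                 c(a = 0.15, mu = log(4), sigma = 0.7), d)
  bmd <- bmd_from_curve(f3, 0.10, c(0.1, 40))$bmd
  expect_equal(exp(log(4) + 0.7 * qnorm(0.10)), bmd, tolerance = 1e-6)
  # inverse property at the root
  p0 <- 0.15
  expect_lt(abs(f3(bmd) - (p0 + 0.10 * (1 - p0))), 1e-6 * 0.10)
})

test_that("flat or ill-posed curves are censored or rejected, not solved", {
  flat <- function(d) rep(0.2, length(d))
  res <- bmd_from_curve(flat, 0.10, c(1, 10))
  expect_equal(res$censored, "right")
  expect_equal(res$bmd, 10 * 1e6)
  decr <- function(d) 1 - stats::plogis(log(d))
  expect_error(bmd_from_curve(decr, 0.10, c(0.5, 5)), "nondecreasing")
  expect_error(bmd_from_curve(flat, 1.2, c(1, 10)), "bmr")
})

test_that("interval ratios follow the narrowness rule", {
  expect_equal(bmdi_ratio(1, 9)$ratio, 9)
  expect_true(bmdi_ratio(1, 9)$narrow)
  expect_equal(bmdi_ratio(2, 2), tibble::tibble(ratio = 1, narrow = TRUE))
  expect_false(bmdi_ratio(0.397, 66.8)$narrow)
  expect_error(bmdi_ratio(0, 1))
  expect_error(bmdi_ratio(3, 2))
})

sim <- sim_quantal(150, "log-logistic", bmd10 = 5, background = 0.05,
                   seed = 314)

test_that("a full model-averaged run is deterministic given data and seed", {
  f1 <- ma_bmd(sim$dose, sim$outcome, n_boot = 30, seed = 42)
  f2 <- ma_bmd(sim$dose, sim$outcome, n_boot = 30, seed = 42)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$boot, f2$boot)
  expect_identical(bmd_curves(f1, n_grid = 40), bmd_curves(f2, n_grid = 40))
  # and the result is internally consistent
  expect_true(f1$bmdl <= f1$bmdu)
  expect_equal(f1$narrow, f1$ratio < 10)
  expect_equal(sum(f1$weights), 1)
})

test_that("the averaged curve stays inside the member-model envelope", {
  fit <- ma_bmd(sim$dose, sim$outcome, n_boot = 5, seed = 7)
  grid <- 10^seq(log10(min(sim$dose)), log10(max(sim$dose)), length.out = 50)
  members <- vapply(fit$fits, function(f) thyrobmd:::predict_quantal(f, grid),
                    numeric(50))
  avg <- thyrobmd:::ma_curve(fit$fits, fit$weights)(grid)
  active <- fit$weights > 0
  expect_true(all(avg >= apply(members[, active, drop = FALSE], 1, min) - 1e-12))
  expect_true(all(avg <= apply(members[, active, drop = FALSE], 1, max) + 1e-12))
})

test_that("bootstrap curve export carries one curve per iteration, all
           valid probabilities", {
  fit <- ma_bmd(sim$dose, sim$outcome, n_boot = 25, seed = 9,
                keep_boot_fits = TRUE)
  curves <- bmd_curves(fit, n_grid = 30)
  expect_equal(length(unique(curves$curve)), 26) # estimate + 25 bootstrap
  expect_true(all(curves$response >= 0 & curves$response <= 1))
  expect_equal(nrow(curves), 26 * 30)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("benchmark doses scale with the dose axis for dose-scale-free
           families", {
  fams <- c("log-logistic", "log-probit", "weibull", "gamma", "two-stage")
  s <- 3.7
  f1 <- ma_bmd(sim$dose, sim$outcome, n_boot = 15, seed = 11,
               families = fams, keep_boot_fits = FALSE)
  f2 <- ma_bmd(sim$dose * s, sim$outcome, n_boot = 15, seed = 11,
               families = fams, keep_boot_fits = FALSE)
  expect_equal(f2$bmd, s * f1$bmd, tolerance = 1e-4)
  expect_equal(f2$bmdl, s * f1$bmdl, tolerance = 1e-4)
  expect_equal(f2$bmdu, s * f1$bmdu, tolerance = 1e-4)
})

test_that("no-signal data produce heavy censoring and the unreliable flag", {
  set.seed(60)
  d <- rlnorm(80, 1, 0.9)
  y <- rbinom(80, 1, 0.25) # outcome independent of dose
  fit <- ma_bmd(d, y, n_boot = 40, seed = 60, keep_boot_fits = FALSE)
  expect_equal(fit$unreliable, fit$n_censored > 20)
  expect_true(all(fit$boot$censored %in% c("none", "left", "right", "failed")))
})
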