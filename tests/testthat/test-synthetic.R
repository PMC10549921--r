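test_that("cohort generation is reproducible and respects stratum sizes", {
  a <- sim_cohort(n_men = 40, n_women = 35, seed = 5)
  b <- sim_cohort(n_men = 40, n_women = 35, seed = 5)
  expect_identical(a, b)
  expect_equal(sum(a$sex == "M"), 40)
  expect_equal(sum(a$sex == "F"), 35)
  expect_true(all(a$ni > 0, na.rm = TRUE))
  expect_true(all(a$age >= 18 & a$age <= 94))
  c2 <- sim_cohort(n_men = 40, n_women = 35, seed = 6)
  expect_false(identical(a$ni, c2$ni))
})

test_that("generated exposure quartiles converge to the configured
           targets", {
  big <- sim_cohort(n_men = 10000, n_women = 0, seed = 77,
                    missingness = dplyr::mutate(default_missingness(),
                                                rate = 0))
  q <- quartiles(big$ni)
  expect_equal(q[["median"]], 8.278, tolerance = 0.05)
  # the log-normal is fitted to the quartile ratio, so p75/p25 is the
  # second calibrated quantity
  expect_equal(q[["p75"]] / q[["p25"]], 14.20 / 2.902, tolerance = 0.05)
  # hormone marginals calibrate the same way
  expect_equal(quartiles(big$tsh)[["median"]], 1.870, tolerance = 0.05)
  expect_equal(quartiles(big$ft4)[["median"]], 16.84, tolerance = 0.05)
})

test_that("missingness is per endpoint at the configured rates and zero
           rates give complete data", {
  full <- sim_cohort(n_men = 300, n_women = 300, seed = 9,
                     missingness = dplyr::mutate(default_missingness(),
                                                 rate = 0))
  expect_false(anyNA(full))
  miss <- sim_cohort(n_men = 2000, n_women = 0, seed = 10)
  expect_equal(mean(is.na(miss$tsh)), 24 / 217, tolerance = 0.25)
  expect_equal(mean(is.na(miss$ft4)), 32 / 217, tolerance = 0.25)
  expect_false(anyNA(miss$ni))
  expect_error(sim_cohort(missingness = tibble::tibble(
    variable = "tsh", sex = "M", rate = 1.5)), "rates")
})

test_that("unsatisfiable quartile targets are rejected", {
  bad <- default_marginals()
  bad$p25[bad$variable == "ni" & bad$sex == "M"] <- 99
  expect_error(sim_cohort(n_men = 5, n_women = 0, seed = 1, marginals = bad),
               "p25 < median")
})

test_that("the quantal link ties out-of-range probability to exposure and
           keeps continuous values consistent with the indicator", {
  link <- list(endpoint = "ft3", family = "log-logistic",
               params = c(a = 0.05, mu = log(5) + 0.5 * log(9), sigma = 0.5))
  coh <- sim_cohort(n_men = 3000, n_women = 3000, seed = 21, link = link,
                    missingness = dplyr::mutate(default_missingness(),
                                                rate = 0))
  rr <- reference_ranges()
  lo <- rr$low[rr$endpoint == "ft3"]; hi <- rr$high[rr$endpoint == "ft3"]
  out <- as.integer(coh$ft3 < lo | coh$ft3 > hi)
  # marginal out rate matches the model mean over the Ni distribution
  p_bar <- mean(quantal_prob(link$family, link$params, coh$ni))
  expect_equal(mean(out), p_bar, tolerance = 0.1)
  # out-of-range fraction rises across Ni deciles (compare tails)
  dec <- dplyr::ntile(coh$ni, 10)
  rate_by_dec <- tapply(out, dec, mean)
  expect_gt(mean(rate_by_dec[8:10]), mean(rate_by_dec[1:3]))
  # monotone within binomial error: allow small inversions only
  expect_true(all(diff(rate_by_dec) > -0.06))
  # a link on a computed endpoint is refused
  expect_error(sim_cohort(n_men = 5, n_women = 0, seed = 1,
                          link = list(endpoint = "spina_gt",
                                      family = "log-logistic",
                                      params = link$params)),
               "measured hormone")
})

test_that("sim_quantal matches its closed-form benchmark dose and rates", {
  s <- sim_quantal(5000, "log-logistic", bmd10 = 5, background = 0.05,
                   seed = 3)
  expect_equal(s$true_bmd10, 5, tolerance = 1e-12)
  p_bar <- mean(quantal_prob(s$family, s$params, s$dose))
  expect_equal(mean(s$outcome), p_bar, tolerance = 0.05)
  # flat curve: rate equals the background
  flat <- sim_quantal(4000, "log-logistic",
                      params = c(a = 0.3, mu = 50, sigma = 0.05), seed = 4)
  expect_equal(mean(flat$outcome), 0.3, tolerance = 0.05)
  # determinism and the closed forms for the other families
  s2 <- sim_quantal(5000, "log-logistic", bmd10 = 5, background = 0.05,
                    seed = 3)
  expect_identical(s$dose, s2$dose)
  expect_equal(thyrobmd:::true_bmd("weibull", c(a = 0, b = 4, c = 2), 0.10),
               4 * (-log(0.9))^0.5)
  expect_equal(thyrobmd:::true_bmd("two-stage", c(a = 0, b = 0.2, c = 0), 0.10),
               -log(0.9) / 0.2)
})
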