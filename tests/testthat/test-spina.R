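test_that("plasma-binding factors take their exact dimensionless values", {
  k <- spina_constants()
  expect_identical(1 + k$K41 * k$TBG * 1e-9 + k$K42 * k$TBPA * 1e-6, 6901)
  expect_identical(1 + k$K30 * k$TBG * 1e-9, 601)
})

test_that("GT and GD match an independent transcription of the equations", {
  # frozen hand-computed values at the male median hormone panel
  expect_equal(spina_gt(1.87, 16.84), 3.158, tolerance = 5e-4)
  expect_equal(spina_gd(16.84, 4.76), 26.14, tolerance = 5e-4)
  # 100 random in-range panels: agreement to 10 significant digits
  set.seed(4711)
  tsh <- runif(100, 0.27, 4.2)
  ft4 <- runif(100, 12, 22)
  ft3 <- runif(100, 3.1, 6.8)
  expect_equal(spina_gt(tsh, ft4), oracle_gt(tsh, ft4), tolerance = 1e-10)
  expect_equal(spina_gd(ft4, ft3), oracle_gd(ft4, ft3), tolerance = 1e-10)
})

test_that("GT is linear in fT4, decreasing in TSH, and zero at zero fT4", {
  tsh <- c(0.5, 1.87, 4)
  expect_equal(spina_gt(tsh, 2 * 16.84), 2 * spina_gt(tsh, 16.84))
  gt_seq <- spina_gt(seq(0.3, 5, length.out = 30), 16)
  expect_true(all(diff(gt_seq) < 0))
  expect_equal(spina_gt(c(0.5, 2, 10), 0), c(0, 0, 0))
  # saturation: gt * tsh / (D_T + tsh) is constant in tsh
  k <- spina_constants()
  sat <- spina_gt(c(1, 10, 100), 16) * c(1, 10, 100) / (k$D_T + c(1, 10, 100))
  expect_equal(sat, rep(sat[1], 3))
})

test_that("GD is linear in fT3, decreasing in fT4, and zero at zero fT3", {
  expect_equal(spina_gd(16.84, 2 * 4.76), 2 * spina_gd(16.84, 4.76))
  gd_seq <- spina_gd(seq(12, 22, length.out = 30), 4.76)
  expect_true(all(diff(gd_seq) < 0))
  expect_equal(spina_gd(16.84, 0), 0)
})

test_that("interquartile hormone panels map into the SPINA reference
           ranges; full-range panels stay the right order of magnitude", {
  # central (interquartile) panels: within GT 1.4-8.7 pmol/s, GD 20-60 nmol/s
  ctr <- expand.grid(tsh = seq(1.02, 2.70, length.out = 8),
                     ft4 = seq(15.37, 19.09, length.out = 8),
                     ft3 = seq(4.295, 5.29, length.out = 8))
  expect_true(all(spina_gt(ctr$tsh, ctr$ft4) > 1.4 &
                    spina_gt(ctr$tsh, ctr$ft4) < 8.7))
  expect_true(all(spina_gd(ctr$ft4, ctr$ft3) > 20 &
                    spina_gd(ctr$ft4, ctr$ft3) < 60))
  # the full in-range rectangle includes discordant corners (low TSH with
  # high fT4 flags hyperthyroid-like secretion), so only the order of
  # magnitude is constrained there
  grid <- expand.grid(tsh = seq(0.27, 4.2, length.out = 12),
                      ft4 = seq(12, 22, length.out = 12),
                      ft3 = seq(3.1, 6.8, length.out = 12))
  gt <- spina_gt(grid$tsh, grid$ft4)
  gd <- spina_gd(grid$ft4, grid$ft3)
  expect_true(all(gt > 1 & gt < 25))
  expect_true(all(gd > 10 & gd < 65))
})

test_that("invalid hormone inputs are rejected", {
  expect_error(spina_gt(0, 16), "tsh > 0")
  expect_error(spina_gt(-1, 16), "tsh > 0")
  expect_error(spina_gt(1.5, -2), "ft4 >= 0")
  expect_error(spina_gd(0, 4), "ft4 > 0")
  expect_error(spina_gd(16, -1), "ft3 >= 0")
  expect_error(spina_constants(TBG = -3), "positive")
  expect_error(spina_constants(nonsense = 1), "unknown")
})

test_that("add_spina propagates per-endpoint missingness without error", {
  panel <- tibble::tibble(
    tsh = c(NA, 1.87, 1.87, NA),
    ft4 = c(16.84, 16.84, NA, NA),
    ft3 = c(4.76, 4.76, 4.76, NA)
  )
  out <- add_spina(panel)
  expect_true(is.na(out$spina_gt[1]) && !is.na(out$spina_gd[1]))
  expect_equal(out$spina_gt[2], 3.158, tolerance = 5e-4)
  expect_equal(out$spina_gd[2], 26.14, tolerance = 5e-4)
  expect_true(is.na(out$spina_gt[3]) && is.na(out$spina_gd[3]))
  expect_true(is.na(out$spina_gt[4]) && is.na(out$spina_gd[4]))
  # gd undefined at ft4 = 0 even though gt is fine there
  zero <- add_spina(tibble::tibble(tsh = 1, ft4 = 0, ft3 = 4))
  expect_equal(zero$spina_gt, 0)
  expect_true(is.na(zero$spina_gd))
})

test_that("beta_corr is carried in the constants but does not enter results", {
  a <- spina_gt(1.87, 16.84, spina_constants(beta_corr = 0.1345))
  b <- spina_gt(1.87, 16.84, spina_constants(beta_corr = 99))
  expect_identical(a, b)
})
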