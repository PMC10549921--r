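# Independent oracles used across the suite. These are deliberately
# separate transcriptions of the underlying formulas -- they never call the
# package's own kernels.

# direct transcription of the secretory-capacity equation, all hand-converted
# to mol/L before multiplying
oracle_gt <- function(tsh, ft4) {
  binding <- 1 + 2e10 * 300e-9 + 2e8 * 4.5e-6
  gt_mol <- 1.1e-6 * (2.75 + tsh) * binding * (ft4 * 1e-12) / (0.1 * tsh)
  gt_mol * 1e12
}

# direct transcription of the deiodinase-activity equation
oracle_gd <- function(ft4, ft3) {
  binding <- 1 + 2e9 * 300e-9
  gd_mol <- 8e-6 * (500e-9 + ft4 * 1e-12) * binding * (ft3 * 1e-12) /
    (0.026 * ft4 * 1e-12)
  gd_mol * 1e9
}

# Independent response-probability transcriptions on the natural dose axis,
# parameterised directly (no internal rescaling).
oracle_prob <- function(family, par, d) {
  switch(family,
    "logistic" = 1 / (1 + exp(-(par[1] + par[2] * d))),
    "probit" = pnorm(par[1] + par[2] * d),
    "log-logistic" = par[1] + (1 - par[1]) /
      (1 + exp(-(log(d) - par[2]) / par[3])),
    "log-probit" = par[1] + (1 - par[1]) * pnorm((log(d) - par[2]) / par[3]),
    "weibull" = par[1] + (1 - par[1]) * (1 - exp(-(d / par[2])^par[3])),
    "gamma" = par[1] + (1 - par[1]) * pgamma(d / par[2], shape = par[3]),
    "two-stage" = par[1] + (1 - par[1]) *
      (1 - exp(-(par[2] * d + par[3] * d^2)))
  )
}

oracle_loglik <- function(family, par, d, y) {
  p <- oracle_prob(family, par, d)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# Search box on the natural dose axis, mirroring the documented fitting
# constraints (background in [0, 1), slopes/shapes bounded away from zero);
# doses enter only through their observed range.
oracle_box <- function(family, d) {
  s <- max(d)
  lg <- c(log(min(d) / s) - 15, 15) # log-location window on the scaled axis
  switch(family,
    "logistic" = ,
    "probit" = list(lower = c(-30, log(1e-2) - log(s)),
                    upper = c(30, log(1e4) - log(s)),
                    logpar = c(FALSE, TRUE)),
    "log-logistic" = ,
    "log-probit" = list(lower = c(0, lg[1] + log(s), log(1e-2)),
                        upper = c(1 - 1e-6, lg[2] + log(s), log(20)),
                        logpar = c(FALSE, FALSE, TRUE)),
    "weibull" = ,
    "gamma" = list(lower = c(0, lg[1] + log(s), log(1e-2)),
                   upper = c(1 - 1e-6, lg[2] + log(s), log(20)),
                   logpar = c(FALSE, TRUE, TRUE)),
    "two-stage" = list(lower = c(0, log(1e-8) - log(s), log(1e-8) - 2 * log(s)),
                       upper = c(1 - 1e-6, log(1e6) - log(s), log(1e6) - 2 * log(s)),
                       logpar = c(FALSE, TRUE, TRUE))
  )
}

# Brute-force maximum likelihood by iterated grid refinement: a dense grid
# over the whole box, then repeated shrinking grids centred on the best
# point. Converges to the global constrained optimum to well below 1e-6 in
# log-likelihood for these smooth low-dimensional surfaces.
oracle_grid_mle <- function(family, d, y, n_grid = 13, n_zoom = 35,
                            shrink = 0.55) {
  box <- oracle_box(family, d)
  k <- length(box$lower)
  lower <- box$lower; upper <- box$upper
  eval_at <- function(theta) {
    par <- theta
    par[box$logpar] <- exp(par[box$logpar])
    oracle_loglik(family, par, d, y)
  }
  best <- NULL; best_ll <- -Inf
  centre <- (lower + upper) / 2
  half <- (upper - lower) / 2
  for (it in seq_len(n_zoom)) {
    axes <- lapply(seq_len(k), function(j) {
      seq(max(lower[j], centre[j] - half[j]),
          min(upper[j], centre[j] + half[j]), length.out = n_grid)
    })
    grid <- as.matrix(expand.grid(axes))
    ll <- apply(grid, 1, eval_at)
    i <- which.max(ll)
    if (ll[i] > best_ll) { best_ll <- ll[i]; best <- grid[i, ] }
    centre <- best
    half <- half * shrink
  }
  list(loglik = best_ll, theta = best)
}

# exact two-sided permutation p-value for the Spearman statistic (small n,
# no ties assumed)
oracle_spearman_perm_p <- function(x, y) {
  n <- length(x)
  r_obs <- cor(rank(x), rank(y))
  perms <- gtools_permutations(n)
  rx <- rank(x)
  count <- 0L
  for (i in seq_len(nrow(perms))) {
    r <- cor(rx, rank(y)[perms[i, ]])
    if (abs(r) >= abs(r_obs) - 1e-12) count <- count + 1L
  }
  count / nrow(perms)
}

# all permutations of 1..n (tiny n only)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

# small complete cohort used by several pipeline tests
make_test_cohort <- function(n = 60, seed = 99) {
  sim_cohort(n_men = n %/% 2, n_women = n - n %/% 2, seed = seed,
             missingness = dplyr::mutate(default_missingness(), rate = 0))
}
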