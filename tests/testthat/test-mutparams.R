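test_that("Bateman-Mukai arithmetic and flags", {
  bm <- bateman_mukai(-0.01, 0.001)
  expect_equal(bm$U_min, 0.1)
  expect_equal(bm$effect_max, 0.1)
  expect_true(bm$valid)
  bad <- bateman_mukai(-0.01, -1e-5)
  expect_false(bad$valid)
  expect_true(is.na(bad$U_min))
})

test_that("Bateman-Mukai is unbiased for equal effects and a lower bound
           for dispersed effects", {
  # equal effects: U_min -> U, s_max -> s in expectation
  U <- 2e-3; t <- 500; s <- 0.05
  set.seed(51)
  est <- replicate(60, {
    z <- sim_line_means(400, U, t, beta = 1e6, mean_effect = s,
                        sd_line_mean = 0, m0 = 0)
    dm <- mean(z) / t
    vm <- var(z) / t
    bateman_mukai(dm, vm)$U_min
  })
  expect_lt(abs(mean(est) - U), 3 * sd(est) / sqrt(length(est)))
  # gamma effects (beta = 1): E(s)^2 < E(s^2) makes U_min biased low
  est_g <- replicate(60, {
    z <- sim_line_means(400, U, t, beta = 1, mean_effect = s,
                        sd_line_mean = 0, m0 = 0)
    bateman_mukai(mean(z) / t, var(z) / t)$U_min
  })
  expect_lt(mean(est_g) + 3 * sd(est_g) / sqrt(length(est_g)), U)
})

test_that("likelihood is exactly Gaussian at U = 0", {
  set.seed(52)
  z <- rnorm(30, 0.4, 0.02)
  m <- list(U = 0, beta = 2, alpha = 50, p_beneficial = 0, t = 1500,
            m0 = 0.4, error_var = 4e-4)
  expect_equal(ml_line_likelihood(z, m),
               sum(dnorm(z, 0.4, 0.02, log = TRUE)), tolerance = 1e-12)
})

test_that("equal-effects likelihood matches the closed-form Poisson-normal
           mixture", {
  set.seed(53)
  z <- c(rnorm(20, 0.35, 0.02), 0.35 - 0.03, 0.35 - 0.065)
  for (pb in c(0, 0.15)) {
    m <- list(U = 8e-4, t = 1573, m0 = 0.35, error_var = 4e-4,
              p_beneficial = pb, equal_effects = TRUE, mean_effect = 0.03,
              beta = NA, alpha = NA)
    lam <- m$U * m$t
    oracle <- vapply(z, function(zi) {
      tot <- 0
      for (n in 0:40) {
        for (k in 0:n) {
          shift <- (k - (n - k)) * m$mean_effect
          tot <- tot + dpois(n, lam) * dbinom(k, n, pb) *
            dnorm(zi - m$m0, shift, sqrt(m$error_var))
        }
      }
      tot
    }, numeric(1))
    expect_equal(ml_line_likelihood(z, m), sum(log(oracle)),
                 tolerance = 1e-6)
  }
})

test_that("the gamma model approaches the equal-effects envelope as beta
           grows at fixed mean", {
  set.seed(54)
  z <- sim_line_means(40, 5e-4, 1573, beta = 1e6, mean_effect = 0.03,
                      sd_line_mean = 0.015, m0 = 0.35)
  ll_eq <- ml_line_likelihood(z, list(
    U = 5e-4, t = 1573, m0 = 0.35, error_var = 0.015^2, p_beneficial = 0,
    equal_effects = TRUE, mean_effect = 0.03))
  gap <- vapply(c(50, 400, 3000), function(beta) {
    abs(ml_line_likelihood(z, list(
      U = 5e-4, beta = beta, alpha = beta / 0.03, p_beneficial = 0,
      t = 1573, m0 = 0.35, error_var = 0.015^2)) - ll_eq)
  }, numeric(1))
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[3], 0.01)
})

test_that("the convolution density integrates to one", {
  for (pars in list(c(beta = 1.8, pb = 0), c(beta = 0.3, pb = 0.4))) {
    grid <- seq(-6, 4, length.out = 60001)
    f <- mutarch:::ma_line_density(grid, U = 5e-4, beta = pars["beta"],
                                   alpha = pars["beta"] / 0.05,
                                   pb = pars["pb"], t = 1573,
                                   error_var = 4e-4)
    expect_equal(sum(f) * diff(grid)[1], 1, tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to a joint shift of line means and m0", {
  set.seed(55)
  z <- sim_line_means(25, 4e-4, 1573, beta = 2, mean_effect = 0.03,
                      sd_line_mean = 0.02, m0 = 0.35)
  m <- list(U = 4e-4, beta = 2, alpha = 2 / 0.03, p_beneficial = 0.1,
            t = 1573, m0 = 0.35, error_var = 4e-4)
  m_shift <- m
  m_shift$m0 <- m$m0 + 11.3
  expect_equal(ml_line_likelihood(z, m),
               ml_line_likelihood(z + 11.3, m_shift), tolerance = 1e-9)
})

test_that("profile fit recovers sane estimates and respects the grid-
           refinement monotonicity", {
  set.seed(56)
  anc <- rnorm(120, 0.35, 0.05)
  z <- sim_line_means(45, 4e-4, 1573, beta = 2, mean_effect = 0.03,
                      sd_line_mean = 0.05 / sqrt(10), m0 = 0.35)
  coarse <- ml_profile_fit(z, anc, t = 1573, beta_grid = c(1, 5),
                           pb_grid = 0, n_rep = rep(10, 45),
                           estimate_m0 = FALSE, ci = FALSE)
  fine <- ml_profile_fit(z, anc, t = 1573, beta_grid = c(0.5, 1, 2, 5),
                         pb_grid = 0, n_rep = rep(10, 45),
                         estimate_m0 = FALSE, ci = FALSE)
  expect_gte(fine$logL, coarse$logL - 1e-6)
  expect_true(fine$U > 0 && fine$mean_effect > 0)
  # joint m0 estimation stays close to the ancestor mean
  j <- ml_profile_fit(z, anc, t = 1573, beta_grid = 2, pb_grid = 0,
                      n_rep = rep(10, 45), estimate_m0 = TRUE, ci = FALSE)
  expect_lt(abs(j$m0 - mean(anc)), 3 * 0.05 / sqrt(120))
})

test_that("a no-signal dataset drives U toward zero", {
  set.seed(57)
  anc <- rnorm(100, 0.35, 0.05)
  z <- rnorm(40, 0.35, 0.05 / sqrt(10))
  fit <- ml_profile_fit(z, anc, t = 1500, beta_grid = c(1, 5), pb_grid = 0,
                        n_rep = rep(10, 40), estimate_m0 = FALSE, ci = FALSE)
  ll0 <- sum(dnorm(z, 0.35, 0.05 / sqrt(10), log = TRUE))
  expect_lt(fit$logL - ll0, 2)  # no meaningful improvement over U = 0
})

test_that("dominance follows the diploid/haploid decline ratio", {
  expect_equal(dominance(0.1, 0.1)$h, 0.5)
  d <- dominance(0.07, 0.1)
  expect_equal(d$k, -0.3)
  expect_equal(d$h, 0.35)
  expect_error(dominance(0.1, 0), "zero haploid")
})

test_that("dominance is recovered from a simulated experiment", {
  traits <- data.frame(trait = c("diploid_growth", "haploid_growth"),
                       ploidy = c("diploid", "haploid"),
                       m0 = c(0.35, 0.30), sd_anc = c(0, 0),
                       sd_ma = c(0, 0))
  cfg <- sim_config(U = 0.004, generations = 1500, beta = 4,
                    mean_effect = 0.04, p_beneficial = 0, h = 0.2,
                    n_lines = 150, replicates = 1, traits = traits,
                    anc_replicates = 5, n_haploid_lines = 150,
                    n_tetrads = 3, haploid_replicates = 1,
                    viability_p0 = 1, seed = 58)
  dip <- simulate_diploid_ma(cfg)
  hap <- simulate_haploid_derivation(dip)
  est <- estimate_dominance(
    mutarch:::obs_subset(dip, "diploid_growth", "normal"),
    mutarch:::obs_subset(hap, "haploid_growth", "normal"),
    mutarch:::obs_subset(dip, "diploid_growth", "ancestor"),
    mutarch:::obs_subset(hap, "haploid_growth", "ancestor"))
  expect_lt(abs(est$h - 0.2), 0.05)
})
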