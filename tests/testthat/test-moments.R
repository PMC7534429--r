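test_that("delta_mean is the per-generation line-mean decline", {
  ma <- observation_table(data.frame(
    treatment = "normal", line = rep(c("a", "b"), each = 2),
    trait = "x", replicate = rep(1:2, 2), value = c(0.85, 0.85, 0.85, 0.85)))
  anc <- observation_table(data.frame(
    treatment = "ancestor", line = "A0", trait = "x",
    replicate = 1:4, value = rep(1, 4)))
  expect_equal(delta_mean(ma, anc, 1500), -1e-4)
  expect_equal(delta_mean(anc, anc, 1500), 0)
  expect_error(delta_mean(ma, anc, 0), "positive")
  # invariance to adding a constant to both tables
  ma2 <- ma; ma2$value <- ma2$value + 3
  anc2 <- anc; anc2$value <- anc2$value + 3
  expect_equal(delta_mean(ma2, anc2, 1500), delta_mean(ma, anc, 1500))
})

test_that("among-line REML equals the balanced ANOVA closed form", {
  for (seed in c(1, 2, 3)) {
    obs <- make_oneway_obs(n_lines = 12, reps = 6, sd_line = 1.5,
                           sd_resid = 0.8, seed = seed)
    fit <- among_line_variance(obs)
    grp <- split(obs$value, obs$line)
    r <- 6
    msb <- r * var(vapply(grp, mean, numeric(1)))
    msw <- mean(vapply(grp, var, numeric(1)))
    expect_equal(fit$line, (msb - msw) / r, tolerance = 1e-8)
    expect_equal(fit$residual, msw, tolerance = 1e-8)
  }
})

test_that("among-line REML agrees with lme4 on unbalanced designs", {
  skip_if_not_installed("lme4")
  set.seed(41)
  obs <- as.data.frame(make_oneway_obs(n_lines = 15, reps = 6,
                                       sd_line = 2, sd_resid = 1, seed = 6))
  obs <- obs[-sample(nrow(obs), 17), ]  # unbalance it
  fit <- among_line_variance(observation_table(obs))
  lf <- lme4::lmer(value ~ 1 + (1 | line), data = obs, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$line, vc$vcov[vc$grp == "line"], tolerance = 1e-4)
  expect_equal(fit$residual, vc$vcov[vc$grp == "Residual"], tolerance = 1e-4)
})

test_that("among-line REML recovers a known line variance", {
  obs <- make_oneway_obs(n_lines = 200, reps = 10, sd_line = 2,
                         sd_resid = 1, seed = 7)
  fit <- among_line_variance(obs)
  se <- 4 * sqrt(2 / 199)  # approx SE of a variance from 200 effects
  expect_lt(abs(fit$line - 4), 3 * se)
  # degenerate input: all values equal
  same <- observation_table(data.frame(
    treatment = "normal", line = rep(c("a", "b"), each = 2), trait = "x",
    replicate = rep(1:2, 2), value = rep(5, 4)))
  fit0 <- among_line_variance(same)
  expect_equal(fit0$line, 0)
  expect_equal(fit0$residual, 0)
})

test_that("mutational variance scales among-line differences by t", {
  expect_equal(mutational_variance(1.06e-3, 0, 1573), 6.7387e-7,
               tolerance = 1e-4)
  expect_equal(mutational_variance(2, 2, 100), 0)
  expect_equal(mutational_variance(2, 1, 100, diploid_convention = TRUE),
               1 / 200)
  expect_error(mutational_variance(1, 0, 0), "positive")
})

test_that("ancestor pseudo-lines mimic the comparator structure", {
  anc <- make_ancestor_obs(n = 80, seed = 9)
  comp <- make_oneway_obs(n_lines = 10, reps = 5, seed = 10)
  ps <- ancestor_pseudo_lines(anc, comp, seed = 3)
  lm_ps <- line_means(ps)
  expect_equal(nrow(lm_ps), 10)
  expect_true(all(lm_ps$n_rep == 5))
  # among-pseudo-line variance is near zero for structureless ancestors
  set.seed(4)
  v <- mean(vapply(1:30, function(i) {
    among_line_variance(ancestor_pseudo_lines(anc, comp))$line
  }, numeric(1)))
  expect_lt(abs(v), 0.1)
})

test_that("delta_VE recovers an injected residual-variance difference", {
  ma <- make_oneway_obs(n_lines = 60, reps = 20, sd_line = 0.5,
                        sd_resid = sqrt(2.0), seed = 11)
  anc <- make_ancestor_obs(n = 1200, sd = sqrt(1.2), seed = 12)
  dve <- delta_ve(ma, anc, 1600)
  expect_lt(abs(dve$total - 0.8), 0.25)
  expect_equal(dve$per_gen, dve$total / 1600)
})

test_that("mutational heritability follows its two conventions", {
  expect_equal(mutational_heritability(4.4e-7, 1e-3), 4.4e-4)
  expect_equal(mutational_heritability(0, 1e-3), 0)
  expect_equal(mutational_heritability(4.4e-7, 1e-3, "residual",
                                       residual_var = 2e-3), 2.2e-4)
  expect_error(mutational_heritability(1e-7, 0), "denominator")
})

test_that("harmonic-mean Ne matches closed forms", {
  expect_equal(harmonic_mean_ne(c(1, 2, 4, 8, 16)), 5 / (31 / 16))
  expect_equal(round(harmonic_mean_ne(c(1, 2, 4, 8, 16)), 2), 2.58)
  expect_equal(harmonic_mean_ne(rep(7.3, 12)), 7.3)
  k <- 6
  expect_equal(harmonic_mean_ne(2^(0:k)), (k + 1) / (2 - 2^(-k)))
  expect_error(harmonic_mean_ne(c(1, 0, 2)), "positive")
})

test_that("canalization CVs standardize by the mean change", {
  # V_m = dVE/t = dM^2 for two traits: both CVs are 1, R^2 of the 2-point
  # regression is 1 by construction
  dm <- c(-2e-5, 1e-4)
  res <- canalization_cv(v_m = dm^2, delta_ve_total = dm^2 * 1000,
                         delta_m = dm, t = 1000)
  expect_equal(res$cv$cv_m, c(1, 1))
  expect_equal(res$cv$cv_e, c(1, 1))
  # sign of delta_M is irrelevant
  res2 <- canalization_cv(dm^2, dm^2 * 1000, -dm, 1000)
  expect_equal(res2$cv, res$cv)
  # 3-trait set against the closed-form R^2
  vm <- c(2e-7, 8e-7, 3e-7)
  dve <- c(1e-3, 4e-3, 0.5e-3)
  dm3 <- c(-1e-5, -3e-5, -0.6e-5)
  res3 <- canalization_cv(vm, dve, dm3, 1500)
  x <- sqrt(dve / 1500) / abs(dm3)
  y <- sqrt(vm) / abs(dm3)
  r2 <- cov(x, y)^2 / (var(x) * var(y))
  expect_equal(res3$r_squared, r2, tolerance = 1e-12)
  expect_error(canalization_cv(vm, dve, c(0, dm3[2:3]), 1500), "non-zero")
})

test_that("line-level bootstrap is reproducible and behaves at the extremes", {
  ma <- make_oneway_obs(n_lines = 12, reps = 4, sd_line = 1, sd_resid = 1,
                        m0 = -2, seed = 13)
  anc <- make_ancestor_obs(n = 48, sd = 1, m0 = 0, seed = 14)
  stat <- function(a, b) delta_mean(a, b, 1000)
  b1 <- bootstrap_statistic(ma, anc, stat, n_iter = 300, seed = 5)
  b2 <- bootstrap_statistic(ma, anc, stat, n_iter = 300, seed = 5)
  expect_identical(b1$boot, b2$boot)
  # a large injected difference is detected decisively
  expect_lt(b1$p, 0.001)
  expect_true(b1$ci[2] < 0)
  # constant statistic: zero-width interval
  bc <- bootstrap_statistic(ma, anc, function(a, b) 42, n_iter = 100,
                            seed = 1)
  expect_equal(unname(diff(bc$ci)), 0)
})

test_that("many-to-one rank test flags a strongly shifted line", {
  set.seed(15)
  lines <- lapply(1:8, function(i) rnorm(6, 0, 1))
  lines[[3]] <- lines[[3]] - 6
  ma <- observation_table(data.frame(
    treatment = "normal",
    line = rep(sprintf("L%d", 1:8), each = 6),
    trait = "x", replicate = rep(1:6, 8), value = unlist(lines)))
  anc <- make_ancestor_obs(n = 60, sd = 1, m0 = 0, seed = 16)
  res <- many_to_one_rank_test(ma, anc, alpha = 0.05, n_mc = 2000, seed = 2)
  expect_true(res$significant[res$line == "L3"])
  expect_equal(res$direction[res$line == "L3"], "low")
  expect_false(any(res$significant[res$line != "L3"]))
  # empty input: empty result
  empty <- ma[0, ]
  expect_equal(nrow(many_to_one_rank_test(empty, anc, n_mc = 10)), 0)
})
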