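# compound-Poisson moment identities and the tetrad segregation model

test_that("U = 0 gives mutation-free lines at the ancestral mean", {
  traits <- data.frame(trait = "diploid_growth", ploidy = "diploid",
                       m0 = 0.35, sd_anc = 0, sd_ma = 0)
  cfg <- sim_config(U = 0, n_lines = 20, replicates = 3, traits = traits,
                    anc_replicates = 5, seed = 4)
  obs <- simulate_diploid_ma(cfg)
  expect_true(all(obs$value == 0.35))
})

test_that("line means and variances follow the compound-Poisson identities", {
  # 10,000 lines, one noise-free replicate each: the sample mean and
  # among-line variance of genotypic values must match U t E(hs) and
  # U t E((hs)^2) within 3 Monte-Carlo standard errors
  U <- 3.6e-4; t <- 1573; E <- 0.029; beta <- 1.8
  traits <- data.frame(trait = "diploid_growth", ploidy = "diploid",
                       m0 = 0, sd_anc = 0, sd_ma = 0)
  cfg <- sim_config(U = U, generations = t, beta = beta, mean_effect = E,
                    p_beneficial = 0, h = 1, n_lines = 10000,
                    replicates = 1, traits = traits, anc_replicates = 2,
                    seed = 8)
  obs <- simulate_diploid_ma(cfg, include_ancestor = FALSE)
  g <- obs$value
  exp_mean <- -U * t * E
  exp_var <- U * t * E^2 * (beta + 1) / beta
  se_mean <- sd(g) / sqrt(length(g))
  m2 <- mean((g - mean(g))^2)
  m4 <- mean((g - mean(g))^4)
  se_var <- sqrt((m4 - m2^2) / length(g))
  expect_lt(abs(mean(g) - exp_mean), 3 * se_mean)
  expect_lt(abs(var(g) - exp_var), 3 * se_var)
  # per-generation decline matches the law-of-total-expectation value
  expect_equal(mean(g) / t, -1.04e-5, tolerance = 3 * se_mean / t / 1.04e-5)
})

test_that("symmetric beneficial fraction gives zero expected decline", {
  traits <- data.frame(trait = "diploid_growth", ploidy = "diploid",
                       m0 = 0, sd_anc = 0, sd_ma = 0)
  cfg <- sim_config(U = 0.01, generations = 1000, mean_effect = 0.05,
                    p_beneficial = 0.5, h = 1, n_lines = 4000,
                    replicates = 1, traits = traits, anc_replicates = 2,
                    seed = 12)
  obs <- simulate_diploid_ma(cfg, include_ancestor = FALSE)
  se <- sd(obs$value) / sqrt(nrow(obs))
  expect_lt(abs(mean(obs$value)), 3 * se)
})

test_that("identical seeds reproduce byte-identical tables and added lines
           leave earlier lines untouched", {
  strip <- function(d) {
    d <- data.frame(as.data.frame(d), stringsAsFactors = FALSE)
    attr(d, "mutations") <- NULL
    attr(d, "config") <- NULL
    rownames(d) <- NULL
    d
  }
  cfg <- sim_config(n_lines = 6, replicates = 3, anc_replicates = 10,
                    seed = 21)
  a <- simulate_diploid_ma(cfg)
  b <- simulate_diploid_ma(cfg)
  expect_identical(strip(a), strip(b))
  cfg2 <- sim_config(n_lines = 9, replicates = 3, anc_replicates = 10,
                     seed = 21)
  c <- simulate_diploid_ma(cfg2)
  first6 <- c[c$line %in% unique(a$line[a$treatment == "normal"]), ]
  expect_identical(strip(first6), strip(a[a$treatment == "normal", ]))
})

test_that("2:2 segregation puts one mutation into exactly two spores", {
  dip <- make_fake_diploid(list(0.2), n_tetrads = 100)
  hap <- simulate_haploid_derivation(dip)
  hg <- hap[hap$trait == "haploid_growth", ]
  per_tetrad <- split(hg$value, hg$tetrad)
  for (v in per_tetrad) {
    expect_equal(sort(v), c(0, 0, 0.2, 0.2))
    expect_equal(pvar(v), 0.2^2 / 4)
  }
  # all spores survive (beneficial effect, baseline survival 1)
  expect_true(all(hap$value[hap$trait == "haploid_viability"] == 4))
})

test_that("within-tetrad variance of multi-locus tetrads matches the
           segregation enumeration oracle", {
  a <- c(0.15, 0.08, 0.3)
  # brute force over the 6^3 equally likely segregation assignments
  pats <- combn(4, 2)
  grid <- expand.grid(seq_len(6), seq_len(6), seq_len(6))
  exp_var <- mean(apply(grid, 1, function(gidx) {
    v <- numeric(4)
    for (m in seq_along(a)) v[pats[, gidx[m]]] <- v[pats[, gidx[m]]] + a[m]
    pvar(v)
  }))
  expect_equal(exp_var, sum(a^2) / 4, tolerance = 1e-12)
  dip <- make_fake_diploid(list(a), n_tetrads = 600, seed = 17)
  hap <- simulate_haploid_derivation(dip)
  hg <- hap[hap$trait == "haploid_growth", ]
  vt <- vapply(split(hg$value, hg$tetrad), pvar, numeric(1))
  se <- sd(vt) / sqrt(length(vt))
  expect_lt(abs(mean(vt) - exp_var), 3 * se)
})

test_that("ancestor-derived tetrads carry no genetic variance", {
  traits <- data.frame(trait = "haploid_growth", ploidy = "haploid",
                       m0 = 0.3, sd_anc = 0, sd_ma = 0)
  cfg <- sim_config(U = 0, n_lines = 2, traits = traits,
                    n_haploid_lines = 0, n_tetrads = 4, anc_tetrads = 6,
                    haploid_replicates = 2, viability_p0 = 1, seed = 5)
  dip <- data.frame(treatment = "ancestor")
  attr(dip, "mutations") <- stats::setNames(list(), character(0))
  hap <- simulate_haploid_derivation(dip, cfg)
  hg <- hap$value[hap$trait == "haploid_growth"]
  expect_true(all(hg == 0.3))
  expect_true(all(hap$value[hap$trait == "haploid_viability"] == 4))
})

test_that("haploids cannot be derived without retained mutation lists", {
  obs <- make_oneway_obs()
  expect_error(simulate_haploid_derivation(obs), "mutation lists")
})

test_that("growth curves behave like logistic trajectories", {
  flat <- simulate_growth_curve(0, noise_sd = 0, blank = 0.08, seed = 1)
  expect_true(all(abs(flat$od - (0.05 + 0.08)) < 1e-12))
  # exponential limit: K >> OD0 keeps the curve log-linear early on
  ser <- simulate_growth_curve(0.3, od0 = 1e-4, K = 1, noise_sd = 0,
                               blank = 0)
  early <- ser[ser$time_h <= 7, ]
  slope <- coef(lm(log(early$od) ~ early$time_h))[2]
  expect_equal(unname(slope), 0.3, tolerance = 0.002)
  expect_error(simulate_growth_curve(0.3, noise_sd = -1), "noise_sd")
})
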