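# Fixture builders shared across the test files. Everything is generated in
# code under fixed seeds; no stored data.

# one-way design: n_lines with `reps` replicates, line effects N(0, sd_line^2)
make_oneway_obs <- function(n_lines = 10, reps = 5, sd_line = 1,
                            sd_resid = 1, m0 = 0, treatment = "normal",
                            trait = "diploid_growth", seed = 1) {
  set.seed(seed)
  eff <- rnorm(n_lines, 0, sd_line)
  df <- data.frame(
    treatment = treatment,
    line = rep(sprintf("L%02d", seq_len(n_lines)), each = reps),
    trait = trait,
    replicate = rep(seq_len(reps), n_lines),
    value = m0 + rep(eff, each = reps) + rnorm(n_lines * reps, 0, sd_resid))
  observation_table(df)
}

make_ancestor_obs <- function(n = 60, sd = 1, m0 = 0,
                              trait = "diploid_growth", seed = 2) {
  set.seed(seed)
  observation_table(data.frame(
    treatment = "ancestor", line = "A0", trait = trait,
    replicate = seq_len(n), value = m0 + rnorm(n, 0, sd)))
}

# balanced nested design (parent / tetrad / spore strain / replicate) with
# known generating components; returns the observation table plus the
# closed-form nested-ANOVA (EMS) component estimates as the oracle
make_nested_obs <- function(p = 8, tt = 3, s = 4, r = 4,
                            comps = c(parent = 2, tetrad = 1,
                                      spore = 1.5, residual = 0.5),
                            treatment = "normal", seed = 3) {
  set.seed(seed)
  df <- expand.grid(rep = seq_len(r), spore = seq_len(s),
                    tetrad = seq_len(tt), parent = seq_len(p))
  ti <- (df$parent - 1) * tt + df$tetrad
  si <- (ti - 1) * s + df$spore
  df$value <- 10 +
    rnorm(p, 0, sqrt(comps["parent"]))[df$parent] +
    rnorm(p * tt, 0, sqrt(comps["tetrad"]))[ti] +
    rnorm(p * tt * s, 0, sqrt(comps["spore"]))[si] +
    rnorm(nrow(df), 0, sqrt(comps["residual"]))
  obs <- observation_table(data.frame(
    treatment = treatment,
    line = sprintf("P%02dT%dS%d", df$parent, df$tetrad, df$spore),
    parent = sprintf("P%02d", df$parent),
    tetrad = sprintf("T%d", df$tetrad),
    spore = as.character(df$spore),
    trait = "haploid_growth", replicate = df$rep, value = df$value))
  fp <- factor(df$parent, levels = seq_len(p))
  ft <- factor(ti, levels = seq_len(p * tt))
  fs <- factor(si, levels = seq_len(p * tt * s))
  m <- tapply(df$value, fp, mean)
  mt <- tapply(df$value, ft, mean)
  ms <- tapply(df$value, fs, mean)
  gm <- mean(df$value)
  MSP <- tt * s * r * sum((m - gm)^2) / (p - 1)
  MST <- s * r * sum((mt - rep(m, each = tt))^2) / (p * (tt - 1))
  MSS <- r * sum((ms - rep(mt, each = s))^2) / (p * tt * (s - 1))
  MSR <- sum((df$value - ms[fs])^2) / (p * tt * s * (r - 1))
  ems <- c(parent = (MSP - MST) / (tt * s * r),
           tetrad = (MST - MSS) / (s * r),
           spore = (MSS - MSR) / r,
           residual = MSR)
  list(obs = obs, ems = ems)
}

# compound-Poisson line means: the independent generator used as the oracle
# for mutation-parameter recovery (deliberately not the package simulator)
sim_line_means <- function(n, U, t, beta, mean_effect, sd_line_mean,
                           m0 = 0.35, pb = 0) {
  lam <- U * t
  nmut <- rpois(n, lam)
  g <- vapply(nmut, function(k) {
    if (k == 0) return(0)
    mag <- rgamma(k, shape = beta, rate = beta / mean_effect)
    sgn <- ifelse(runif(k) < pb, 1, -1)
    sum(sgn * mag)
  }, numeric(1))
  m0 + g + rnorm(n, 0, sd_line_mean)
}

# craft a diploid-lines object with hand-chosen mutation effects so tetrad
# segregation can be tested exactly (no noise, guaranteed spore survival)
make_fake_diploid <- function(effects_per_line, n_tetrads = 50,
                              haploid_replicates = 1, seed = 11) {
  traits <- data.frame(trait = "haploid_growth", ploidy = "haploid",
                       m0 = 0, sd_anc = 0, sd_ma = 0)
  cfg <- sim_config(n_lines = length(effects_per_line), traits = traits,
                    n_haploid_lines = length(effects_per_line),
                    n_tetrads = n_tetrads,
                    haploid_replicates = haploid_replicates,
                    viability_p0 = 1, seed = seed)
  muts <- lapply(effects_per_line, function(a) {
    list(sign = rep(1, length(a)),
         magnitude = matrix(a, ncol = 1,
                            dimnames = list(NULL, "haploid_growth")))
  })
  names(muts) <- sprintf("L%d", seq_along(muts))
  dip <- data.frame(treatment = "normal", line = names(muts))
  attr(dip, "mutations") <- muts
  attr(dip, "config") <- cfg
  dip
}

# population (divide-by-n) variance
pvar <- function(x) mean((x - mean(x))^2)
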