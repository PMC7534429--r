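#' Per-generation change in trait mean relative to the ancestor
#'
#' `(mean of MA line means - ancestor mean) / t`. Line means weight lines
#' equally regardless of replicate counts; the ancestor mean is the plain
#' mean of its replicates (it has no line structure).
#'
#' @param ma_obs MA-treatment `ma_obs` table (one trait).
#' @param anc_obs ancestor `ma_obs` table (same trait).
#' @param t number of MA generations (> 0).
#' @return delta-M, trait units per generation.
#' @export
delta_mean <- function(ma_obs, anc_obs, t) {
  if (t <= 0) stop("t must be positive")
  ma_obs <- observation_table(ma_obs)
  anc_obs <- observation_table(anc_obs)
  stopifnot(nrow(ma_obs) > 0, nrow(anc_obs) > 0)
  lm_ma <- line_means(ma_obs)
  (mean(lm_ma$mean) - mean(anc_obs$value)) / t
}

#' Among-line variance component (one-way REML)
#'
#' Estimates the among-line and residual variance components of a one-way
#' random-effects model by direct maximization of the restricted
#' likelihood, profiled to a one-dimensional search over the ratio
#' `sigma_L^2 / sigma_e^2`. The among-line component is left unconstrained
#' (it can go negative, down to the boundary where the line-mean variance
#' vanishes) so that on balanced designs the estimate coincides with the
#' closed-form ANOVA estimator `(MS_between - MS_within) / r`; set
#' `truncate = TRUE` to pin a negative estimate at zero.
#'
#' @param obs `ma_obs` table (one trait, one treatment, >= 2 lines).
#' @param truncate truncate a negative among-line component at 0.
#' @return list: `line` (among-line component), `residual`, `logLik` (REML),
#'   `truncated`, `n_lines`.
#' @export
among_line_variance <- function(obs, truncate = FALSE) {
  obs <- observation_table(obs)
  grp <- split(obs$value, obs$line)
  if (length(grp) < 2) stop("need >= 2 lines")
  n_i <- lengths(grp)
  ybar <- vapply(grp, mean, numeric(1))
  ssw <- sum(vapply(grp, function(y) sum((y - mean(y))^2), numeric(1)))
  N <- sum(n_i)
  if (stats::var(obs$value) < 1e-24) {
    return(list(line = 0, residual = 0, logLik = NA_real_,
                truncated = FALSE, n_lines = length(grp)))
  }
  # profiled REML criterion in c = sigma_L^2 / sigma_e^2
  prof <- function(c) {
    w <- n_i / (1 + n_i * c)
    sw <- sum(w)
    q <- ssw + sum(w * ybar^2) - sum(w * ybar)^2 / sw
    (N - 1) * log(q / (N - 1)) + sum(log(1 + n_i * c)) + log(sw)
  }
  lo <- -1 / max(n_i) + 1e-9
  hi <- 1e6
  opt <- stats::optimize(prof, interval = c(lo, hi), tol = 1e-12)
  # polish near the optimum (optimize() can stop early on flat stretches)
  for (span in c(1e-2, 1e-4)) {
    o2 <- stats::optimize(prof, interval = c(max(lo, opt$minimum - span),
                                             opt$minimum + span),
                          tol = .Machine$double.eps^0.6)
    if (o2$objective <= opt$objective) opt <- o2
  }
  c_hat <- opt$minimum
  # Newton refinement on the profiled criterion for interior optima
  if (c_hat > lo + 1e-7) {
    for (it in 1:3) {
      h <- 1e-5 * (1 + abs(c_hat))
      g <- (prof(c_hat + h) - prof(c_hat - h)) / (2 * h)
      g2 <- (prof(c_hat + h) - 2 * prof(c_hat) + prof(c_hat - h)) / h^2
      if (!is.finite(g) || !is.finite(g2) || g2 <= 0) break
      step <- g / g2
      cand <- c_hat - step
      if (cand <= lo || !is.finite(cand)) break
      if (prof(cand) <= prof(c_hat)) c_hat <- cand
      if (abs(step) < 1e-12 * (1 + abs(c_hat))) break
    }
  }
  truncated <- FALSE
  if (truncate && c_hat < 0) {
    c_hat <- 0
    truncated <- TRUE
  }
  w <- n_i / (1 + n_i * c_hat)
  sw <- sum(w)
  q <- ssw + sum(w * ybar^2) - sum(w * ybar)^2 / sw
  s2e <- q / (N - 1)
  neg2ll <- (N - 1) * log(s2e) + sum(log(1 + n_i * c_hat)) + log(sw) -
    log(s2e) + q / s2e + (N - 1) * log(2 * pi)
  list(line = c_hat * s2e, residual = s2e, logLik = -neg2ll / 2,
       truncated = truncated, n_lines = length(grp))
}

#' Mutational variance
#'
#' Per-generation change in genetic (among-line) variance:
#' `(V_among_MA - V_among_ancestor_pseudo) / t`. The ancestor term is the
#' among-pseudo-line component estimated under the comparator treatment's
#' line/replicate structure (see [ancestor_pseudo_lines()]); it is zero in
#' expectation but subtracting it removes the finite-sampling bias. A
#' labeled `diploid_convention` divides by `2t` instead.
#'
#' @param v_among_ma among-line variance component of the MA treatment.
#' @param v_among_anc_pseudo among-pseudo-line component of the ancestor.
#' @param t generations (> 0).
#' @param diploid_convention divide by `2t` (off by default; the default
#'   follows the per-generation among-line convention).
#' @return V_m, trait units^2 per generation (sign retained).
#' @export
mutational_variance <- function(v_among_ma, v_among_anc_pseudo = 0, t,
                                diploid_convention = FALSE) {
  if (t <= 0) stop("t must be positive")
  (v_among_ma - v_among_anc_pseudo) / (if (diploid_convention) 2 * t else t)
}

#' Impose a comparator line structure on ancestor replicates
#'
#' The ancestor has no line structure; to make its variance components
#' comparable to an MA treatment's, its replicates are partitioned at
#' random into pseudo-lines matching the comparator's line count and
#' per-line replicate counts. When the comparator has more observations
#' than the ancestor, pseudo-lines are filled by resampling with
#' replacement.
#'
#' @param anc_obs ancestor `ma_obs` table (one trait).
#' @param comparator_obs the MA `ma_obs` table whose structure to mimic, or
#'   a data.frame with columns `line`, `n_rep`.
#' @param seed RNG seed; NULL leaves the RNG state alone (for use inside
#'   bootstrap loops).
#' @return `ma_obs` table with pseudo-line ids in `line`.
#' @export
ancestor_pseudo_lines <- function(anc_obs, comparator_obs, seed = NULL) {
  anc_obs <- observation_table(anc_obs)
  if (!is.null(seed)) set.seed(seed)
  if (all(c("line", "n_rep") %in% names(comparator_obs)) &&
      !inherits(comparator_obs, "ma_obs")) {
    struct <- comparator_obs
  } else {
    lm_c <- line_means(observation_table(comparator_obs))
    struct <- data.frame(line = lm_c$line, n_rep = lm_c$n_rep)
  }
  n_needed <- sum(struct$n_rep)
  n_have <- nrow(anc_obs)
  idx <- if (n_needed <= n_have) {
    sample.int(n_have, n_needed)
  } else {
    sample.int(n_have, n_needed, replace = TRUE)
  }
  out <- anc_obs[idx, , drop = FALSE]
  out$line <- rep(sprintf("pseudo%03d", seq_len(nrow(struct))), struct$n_rep)
  out$replicate <- stats::ave(seq_len(nrow(out)), out$line, FUN = seq_along)
  observation_table(as.data.frame(out))
}

#' Change in environmental (within-line) variance relative to the ancestor
#'
#' Residual variance of the MA treatment (from the one-way REML fit) minus
#' the ancestor replicate variance, returned both raw (total) and divided
#' by t (per generation).
#'
#' @inheritParams delta_mean
#' @return list: `total`, `per_gen`.
#' @export
delta_ve <- function(ma_obs, anc_obs, t) {
  if (t <= 0) stop("t must be positive")
  fit <- among_line_variance(ma_obs)
  anc <- observation_table(anc_obs)
  d <- fit$residual - stats::var(anc$value)
  list(total = d, per_gen = d / t)
}

#' Mutational heritability
#'
#' Ratio of per-generation mutational variance to environmental variance.
#' The default denominator is the change in environmental variance from the
#' ancestor (total, not per generation); the conventional residual-variance
#' denominator is available as a labeled alternative.
#'
#' @param v_m mutational variance (per generation).
#' @param delta_ve_total change in environmental variance (total).
#' @param convention `"delta_ve"` (default) or `"residual"`.
#' @param residual_var MA residual variance, required for the
#'   `"residual"` convention.
#' @return h^2_m (dimensionless).
#' @export
mutational_heritability <- function(v_m, delta_ve_total,
                                    convention = c("delta_ve", "residual"),
                                    residual_var = NULL) {
  convention <- match.arg(convention)
  den <- if (convention == "delta_ve") delta_ve_total else residual_var
  if (is.null(den) || den == 0) stop("zero or missing denominator")
  v_m / den
}

#' Line-level bootstrap for any moment statistic
#'
#' Resamples lines with replacement within each table and recomputes
#' `statistic(obs_a, obs_b)`. A table whose treatment is `"ancestor"` is
#' resampled as pseudo-lines mimicking the comparator's line/replicate
#' structure, repartitioned at every iteration. Returns the percentile
#' confidence interval and the two-sided bootstrap p-value
#' `2 min(P(stat* <= 0), P(stat* >= 0))` appropriate for difference
#' statistics.
#'
#' @param obs_a,obs_b `ma_obs` tables (either may be the ancestor).
#' @param statistic function of two tables returning a scalar.
#' @param n_iter bootstrap iterations (>= 1000 for inference; the study
#'   used 10,000 or 20,000).
#' @param seed RNG seed.
#' @param conf confidence level for the percentile interval.
#' @return list: `estimate`, `ci` (length 2), `p`, `boot`.
#' @export
bootstrap_statistic <- function(obs_a, obs_b, statistic, n_iter = 10000,
                                seed = 1L, conf = 0.95) {
  obs_a <- observation_table(obs_a)
  obs_b <- observation_table(obs_b)
  is_anc <- function(o) all(o$treatment == "ancestor")
  comparator <- if (is_anc(obs_a)) obs_b else obs_a
  struct <- {
    lm_c <- line_means(comparator)
    data.frame(line = lm_c$line, n_rep = lm_c$n_rep)
  }
  # point estimate: an ancestor table (single pseudo-line) is partitioned
  # into comparator-structured pseudo-lines first, like every iteration
  set.seed(seed)
  prep <- function(o) if (is_anc(o)) ancestor_pseudo_lines(o, struct) else o
  est <- statistic(prep(obs_a), prep(obs_b))
  idx_by_line <- function(o) split(seq_len(nrow(o)), o$line)
  ia <- idx_by_line(obs_a)
  ib <- idx_by_line(obs_b)
  if (length(ia) < 2 && !is_anc(obs_a)) stop("fewer than 2 lines in obs_a")
  if (length(ib) < 2 && !is_anc(obs_b)) stop("fewer than 2 lines in obs_b")
  bs_labels_a <- sprintf("bs%03d", seq_along(ia))
  bs_labels_b <- sprintf("bs%03d", seq_along(ib))
  # lean constructor: valid ma_obs without revalidation overhead
  rebuild <- function(o, rows, line, replicate) {
    structure(list(treatment = o$treatment[rows], line = line,
                   parent = o$parent[rows], tetrad = o$tetrad[rows],
                   spore = o$spore[rows], trait = o$trait[rows],
                   replicate = replicate, value = o$value[rows]),
              class = c("ma_obs", "data.frame"),
              row.names = seq_along(rows))
  }
  resample <- function(o, idx, labels) {
    if (is_anc(o)) {
      n_have <- nrow(o)
      rows <- sample.int(n_have, sum(struct$n_rep),
                         replace = sum(struct$n_rep) > n_have)
      return(rebuild(o, rows,
                     rep(sprintf("pseudo%03d", seq_len(nrow(struct))),
                         struct$n_rep),
                     sequence(struct$n_rep)))
    }
    pick <- sample(length(idx), length(idx), replace = TRUE)
    rows <- unlist(idx[pick], use.names = FALSE)
    lens <- lengths(idx[pick])
    rebuild(o, rows, rep(labels, lens), sequence(lens))
  }
  set.seed(seed)
  boot <- vapply(seq_len(n_iter), function(it) {
    statistic(resample(obs_a, ia, bs_labels_a),
              resample(obs_b, ib, bs_labels_b))
  }, numeric(1))
  alpha <- 1 - conf
  list(estimate = est,
       ci = unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2),
                                   na.rm = TRUE)),
       p = min(1, 2 * min(mean(boot <= 0, na.rm = TRUE),
                          mean(boot >= 0, na.rm = TRUE))),
       boot = boot)
}

#' Steel-type many-to-one rank test of MA lines against the ancestor
#'
#' Each line's replicates are compared to the shared ancestor control by a
#' Wilcoxon rank sum computed on the combined (control + line) sample. The
#' familywise error rate is controlled by Monte-Carlo calibration of the
#' joint null: observations are permuted across all groups, and each
#' line's adjusted p-value is the fraction of permutations whose maximum
#' absolute standardized rank statistic exceeds the observed one.
#'
#' @param ma_obs MA `ma_obs` table (one trait, >= 2 replicates per line).
#' @param anc_obs ancestor `ma_obs` table (same trait).
#' @param alpha familywise error rate for the `significant` flag.
#' @param n_mc Monte-Carlo permutations (default 10,000).
#' @param seed RNG seed.
#' @return data.frame: `line`, `z` (standardized rank statistic),
#'   `direction` (`"low"`/`"high"`), `p_adj`, `significant`.
#' @export
many_to_one_rank_test <- function(ma_obs, anc_obs, alpha = 0.05,
                                  n_mc = 10000, seed = 1L) {
  ma_obs <- observation_table(ma_obs)
  anc_obs <- observation_table(anc_obs)
  grp <- split(ma_obs$value, ma_obs$line)
  if (length(grp) == 0) {
    return(data.frame(line = character(0), z = numeric(0),
                      direction = character(0), p_adj = numeric(0),
                      significant = logical(0)))
  }
  if (any(lengths(grp) < 2)) stop("every line needs >= 2 replicates")
  ctrl <- anc_obs$value
  n0 <- length(ctrl)
  zstat <- function(ctrl_v, line_v) {
    ni <- length(line_v)
    r <- rank(c(ctrl_v, line_v))
    W <- sum(r[(length(ctrl_v) + 1):(length(ctrl_v) + ni)])
    EW <- ni * (ni + length(ctrl_v) + 1) / 2
    VW <- length(ctrl_v) * ni * (length(ctrl_v) + ni + 1) / 12
    (W - EW) / sqrt(VW)
  }
  z_obs <- vapply(grp, function(v) zstat(ctrl, v), numeric(1))
  pool <- c(ctrl, unlist(grp, use.names = FALSE))
  sizes <- lengths(grp)
  set.seed(seed)
  max_null <- vapply(seq_len(n_mc), function(it) {
    perm <- sample(pool)
    c0 <- perm[seq_len(n0)]
    off <- n0
    m <- 0
    for (k in seq_along(sizes)) {
      v <- perm[(off + 1):(off + sizes[k])]
      off <- off + sizes[k]
      m <- max(m, abs(zstat(c0, v)))
    }
    m
  }, numeric(1))
  p_adj <- vapply(abs(z_obs), function(z) {
    (1 + sum(max_null >= z)) / (n_mc + 1)
  }, numeric(1))
  data.frame(line = names(grp), z = unname(z_obs),
             direction = ifelse(z_obs < 0, "low", "high"),
             p_adj = unname(p_adj),
             significant = unname(p_adj <= alpha),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Harmonic-mean effective population size
#'
#' `N_e = n / sum(1 / N_i)` over the per-transfer population sizes: the
#' harmonic mean, which weights the single-cell bottlenecks that dominate
#' drift during MA propagation.
#'
#' @param sizes per-transfer (or per-generation) population sizes, all > 0.
#' @return harmonic mean N_e.
#' @export
harmonic_mean_ne <- function(sizes) {
  if (any(sizes <= 0)) stop("all sizes must be positive")
  length(sizes) / sum(1 / sizes)
}

#' Mutational and environmental coefficients of variation (canalization)
#'
#' Standardizes the per-generation mutational and environmental variance
#' changes by the per-generation change in mean:
#' `CV_m = sqrt(max(V_m, 0)) / |delta_M|`,
#' `CV_E = sqrt(max(delta_VE / t, 0)) / |delta_M|`,
#' putting variance and mean changes on the same per-generation scale.
#' A least-squares regression of `CV_m` on `CV_E` across traits summarizes
#' the association between mutational input and decanalization.
#'
#' @param v_m per-trait mutational variances (per generation).
#' @param delta_ve_total per-trait total changes in environmental variance.
#' @param delta_m per-trait mean changes (per generation), all non-zero.
#' @param t generations.
#' @return list: `cv` (data.frame `cv_m`, `cv_e`), `r_squared` of the
#'   across-trait regression (NA with < 3 traits... 2 traits give a perfect
#'   line by construction).
#' @export
canalization_cv <- function(v_m, delta_ve_total, delta_m, t) {
  if (any(delta_m == 0)) stop("delta_M must be non-zero for CV standardization")
  cv_m <- sqrt(pmax(v_m, 0)) / abs(delta_m)
  cv_e <- sqrt(pmax(delta_ve_total / t, 0)) / abs(delta_m)
  r2 <- if (length(cv_m) >= 2 && stats::var(cv_e) > 0) {
    summary(stats::lm(cv_m ~ cv_e))$r.squared
  } else NA_real_
  list(cv = data.frame(cv_m = cv_m, cv_e = cv_e), r_squared = r2)
}

#' Full moment summary for one trait and treatment
#'
#' Convenience wrapper computing delta-M, V_m (ancestor pseudo-line
#' corrected, averaged over `n_partition` partitions), delta-V_E and h^2_m,
#' with optional line-level bootstrap confidence intervals and p-values for
#' each.
#'
#' @param ma_obs,anc_obs `ma_obs` tables for one trait.
#' @param t generations.
#' @param n_boot bootstrap iterations (0 skips bootstrap inference).
#' @param n_partition ancestor pseudo-line partitions averaged for the
#'   V_m point estimate.
#' @param seed RNG seed.
#' @return one-row data.frame with the estimates (and CI columns when
#'   bootstrapped).
#' @export
moment_estimates <- function(ma_obs, anc_obs, t, n_boot = 0,
                             n_partition = 20, seed = 1L) {
  ma_obs <- observation_table(ma_obs)
  anc_obs <- observation_table(anc_obs)
  dm <- delta_mean(ma_obs, anc_obs, t)
  fit <- among_line_variance(ma_obs)
  set.seed(seed)
  v_anc <- mean(vapply(seq_len(n_partition), function(i) {
    among_line_variance(ancestor_pseudo_lines(anc_obs, ma_obs))$line
  }, numeric(1)))
  vm <- mutational_variance(fit$line, v_anc, t)
  dve <- delta_ve(ma_obs, anc_obs, t)
  h2m <- if (dve$total != 0) mutational_heritability(vm, dve$total) else NA_real_
  out <- data.frame(trait = ma_obs$trait[1], treatment = ma_obs$treatment[1],
                    t = t, delta_m = dm, v_m = vm,
                    delta_ve_total = dve$total, delta_ve_per_gen = dve$per_gen,
                    h2_m = h2m, stringsAsFactors = FALSE)
  if (n_boot > 0) {
    stat_dm <- function(a, b) delta_mean(a, b, t)
    stat_vm <- function(a, b) {
      mutational_variance(among_line_variance(a)$line,
                          among_line_variance(b)$line, t)
    }
    bs_dm <- bootstrap_statistic(ma_obs, anc_obs, stat_dm, n_boot, seed)
    bs_vm <- bootstrap_statistic(ma_obs, anc_obs, stat_vm, n_boot, seed + 1L)
    out$delta_m_lo <- bs_dm$ci[1]; out$delta_m_hi <- bs_dm$ci[2]
    out$delta_m_p <- bs_dm$p
    out$v_m_lo <- bs_vm$ci[1]; out$v_m_hi <- bs_vm$ci[2]
    out$v_m_p <- bs_vm$p
  }
  out
}
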