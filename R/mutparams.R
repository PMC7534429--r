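#' Bateman-Mukai moment estimates of mutation rate and effect
#'
#' Under the assumption that all mutations are deleterious and of equal
#' effect, the per-generation mean change and mutational variance give a
#' lower bound on the genomic mutation rate, `U_min = delta_M^2 / V_m`, and
#' an upper bound on the mean effect, `s_max = V_m / |delta_M|` (reported
#' as a decline magnitude). With dispersed effects `E(s)^2 < E(s^2)`, so
#' `U_min` underestimates the true rate. For haploid growth rate, method A
#' feeds in the among-diploid-parent variance component only, method B the
#' total genetic (non-residual) variance from the nested model; the tag
#' records which was used.
#'
#' @param delta_m per-generation change in mean (trait units/generation).
#' @param v_m per-generation mutational variance.
#' @param method label recorded on the estimate (`"among_line"`,
#'   `"among_parent"` = method A, `"total_minus_residual"` = method B).
#' @return list: `U_min`, `effect_max`, `method`, `valid` (FALSE when
#'   `v_m <= 0`, in which case the estimates are NA).
#' @export
bateman_mukai <- function(delta_m, v_m, method = "among_line") {
  if (!is.finite(delta_m) || !is.finite(v_m)) stop("non-finite inputs")
  if (v_m <= 0) {
    return(list(U_min = NA_real_, effect_max = NA_real_,
                method = method, valid = FALSE))
  }
  list(U_min = delta_m^2 / v_m, effect_max = v_m / abs(delta_m),
       method = method, valid = TRUE)
}

# ---- Poisson-gamma line-mean likelihood -----------------------------------
#
# Line mean z_i = m0 + sum of n_i signed mutational effects + e_i,
# n_i ~ Poisson(U t), |effect| ~ gamma(shape beta, rate alpha), sign
# positive with probability P_B (the reflected gamma), e_i ~ N(0, error_var)
# with error_var the ancestral residual variance over the (harmonic mean)
# replicate count. The marginal density is a compound-Poisson convolution,
# evaluated by characteristic-function inversion: the CF of the signed
# effect is closed-form,
#   phi_s(w) = P_B (1 - iw/alpha)^-beta + (1 - P_B)(1 + iw/alpha)^-beta
# (deleterious effects are declines, hence the conjugate term carries the
# 1 - P_B weight), the compound-Poisson CF is exp(lambda (phi_s - 1)) with
# lambda = U t — exact in the Poisson number, no truncation — and the
# density is recovered by quadrature of Re(phi(w) e^{-iwd}) on a uniform
# frequency grid whose span and resolution adapt to the error sd and the
# effect-sum tail.

ma_model_cf <- function(omega, lambda, beta, alpha, pb, sigma2,
                        equal_effects = FALSE, mean_effect = NULL) {
  phi_s <- if (equal_effects) {
    pb * exp(1i * omega * mean_effect) + (1 - pb) * exp(-1i * omega * mean_effect)
  } else {
    pb * (1 - 1i * omega / alpha)^(-beta) +
      (1 - pb) * (1 + 1i * omega / alpha)^(-beta)
  }
  exp(lambda * (phi_s - 1) - sigma2 * omega^2 / 2)
}

# density of d = z - m0 at the supplied points; n_cap guards the frequency
# grid size (beyond it the quadrature cannot meet its accuracy contract)
ma_line_density <- function(d, U, beta, alpha, pb, t, error_var,
                            equal_effects = FALSE, mean_effect = NULL,
                            n_cap = 2^17) {
  sigma <- sqrt(error_var)
  lambda <- U * t
  if (lambda <= 0) return(stats::dnorm(d, 0, sigma))
  if (equal_effects) {
    e1 <- mean_effect
    m2 <- mean_effect^2
    qtail <- (stats::qpois(1e-13, lambda, lower.tail = FALSE) + 1) * e1
  } else {
    e1 <- beta / alpha
    m2 <- beta * (beta + 1) / alpha^2
    nmax <- stats::qpois(1e-13, lambda, lower.tail = FALSE) + 1
    qtail <- stats::qgamma(exp(-30), shape = beta * nmax, rate = alpha,
                           lower.tail = FALSE)
  }
  m_g <- lambda * e1 * (2 * pb - 1)
  v_g <- lambda * m2
  half <- max(abs(d)) + abs(m_g) + qtail + 12 * sqrt(v_g) + 12 * sigma
  d_omega <- pi / half
  omega_max <- sqrt(2 * 39) / sigma
  n_omega <- ceiling(omega_max / d_omega)
  if (n_omega > n_cap) {
    stop("characteristic-function grid exceeds its size cap (", n_cap,
         " points needed ", n_omega,
         "); the quadrature cannot meet its accuracy contract here")
  }
  omega <- (seq_len(n_omega) - 0.5) * d_omega
  phi <- ma_model_cf(omega, lambda, beta, alpha, pb, error_var,
                     equal_effects, mean_effect)
  co <- cos(outer(d, omega))
  si <- sin(outer(d, omega))
  f <- (co %*% Re(phi) + si %*% Im(phi)) * d_omega / pi
  pmax(as.numeric(f), 1e-300)
}

#' Log-likelihood of MA line means under the Poisson-gamma model
#'
#' @param line_means numeric vector of MA line mean trait values.
#' @param model list with elements `U`, `beta`, `alpha` (or `mean_effect`
#'   with `equal_effects = TRUE`), `p_beneficial`, `t`, `m0`, `error_var`,
#'   and optionally `equal_effects`.
#' @return the log-likelihood (sum over lines).
#' @export
ml_line_likelihood <- function(line_means, model) {
  stopifnot(model$error_var > 0, model$t >= 1)
  d <- line_means - model$m0
  if (model$U <= 0) {
    return(sum(stats::dnorm(d, 0, sqrt(model$error_var), log = TRUE)))
  }
  eq <- isTRUE(model$equal_effects)
  f <- ma_line_density(d, model$U, model$beta, model$alpha,
                       model$p_beneficial, model$t, model$error_var,
                       equal_effects = eq, mean_effect = model$mean_effect)
  sum(log(f))
}

# ancestor replicate log-likelihood term used for joint m0 estimation
anc_loglik <- function(anc_values, m0, anc_var) {
  sum(stats::dnorm(anc_values, m0, sqrt(anc_var), log = TRUE))
}

# harmonic mean, internal (replicate counts)
hmean <- function(x) length(x) / sum(1 / x)

#' Profile maximum-likelihood fit of the Poisson-gamma mutation model
#'
#' For each point of the (beta, P_B) grid, maximizes the line-mean
#' likelihood over (U, alpha) — optionally jointly over the ancestral mean
#' m0 using the ancestor replicate likelihood — and returns the global MLE,
#' the full profile surface, an equal-effects fit (the beta -> infinity
#' envelope), and 2-log-likelihood profile confidence intervals for U, the
#' mean effect E = beta/alpha, beta and P_B.
#'
#' @param ma_obs MA `ma_obs` table for one trait (or a numeric vector of
#'   line means, in which case `n_rep` gives the per-line replicate counts).
#' @param anc_obs ancestor `ma_obs` table for the same trait (or numeric
#'   vector of ancestor replicate values).
#' @param t MA generations.
#' @param beta_grid gamma-shape grid (study grid:
#'   0.01, 0.1, 0.5, 1, 2, 5, 10, 15, 20, 40).
#' @param pb_grid beneficial-proportion grid (study grid: 0, 0.01, then
#'   0.05 steps to 0.55).
#' @param n_rep replicate counts per line when `ma_obs` is numeric.
#' @param estimate_m0 estimate m0 jointly with the ancestor likelihood
#'   term (default) or fix it at the ancestor sample mean.
#' @param ci compute 2-LL profile confidence intervals for U and the mean
#'   effect (the beta and P_B intervals come from the grid surface either
#'   way).
#' @return object of class `gamma_mutation_model`: the MLE (`U`, `beta`,
#'   `alpha`, `mean_effect`, `p_beneficial`, `logL`), `m0`, `error_var`,
#'   `surface` (data.frame over the grid), `equal_effects` fit, and `ci`.
#' @export
ml_profile_fit <- function(ma_obs, anc_obs, t,
                           beta_grid = c(0.01, 0.1, 0.5, 1, 2, 5, 10, 15, 20, 40),
                           pb_grid = c(0, 0.01, seq(0.05, 0.55, by = 0.05)),
                           n_rep = NULL, estimate_m0 = TRUE, ci = TRUE) {
  if (is.numeric(ma_obs)) {
    z <- as.numeric(ma_obs)
    reps <- if (is.null(n_rep)) rep(1, length(z)) else n_rep
  } else {
    lm_ma <- line_means(observation_table(ma_obs))
    z <- lm_ma$mean
    reps <- lm_ma$n_rep
  }
  anc <- if (is.numeric(anc_obs)) as.numeric(anc_obs) else {
    observation_table(anc_obs)$value
  }
  stopifnot(length(beta_grid) > 0, length(pb_grid) > 0)
  m0_hat <- mean(anc)
  anc_var <- stats::var(anc)
  error_var <- anc_var / hmean(reps)
  loglik <- function(U, beta, alpha, pb, m0, equal_effects = FALSE,
                     mean_effect = NULL) {
    ll <- tryCatch(
      ml_line_likelihood(z, list(U = U, beta = beta, alpha = alpha,
                                 p_beneficial = pb, t = t, m0 = m0,
                                 error_var = error_var,
                                 equal_effects = equal_effects,
                                 mean_effect = mean_effect)),
      error = function(e) -1e10)
    if (!is.finite(ll)) ll <- -1e10
    if (estimate_m0) ll <- ll + anc_loglik(anc, m0, anc_var)
    ll
  }
  # moment-based seeds
  dm <- (mean(z) - m0_hat) / t
  vm <- max((stats::var(z) - error_var) / t, 1e-3 * stats::var(z) / t)
  e_seed <- min(max(vm / max(abs(dm), 1e-12), 1e-4), 1)
  u_seed <- min(max(abs(dm) / e_seed, 0.05 / t), 100 / t)
  lam_lim <- c(1e-6, 2e4)
  e_lim <- c(1e-8, 10 * (max(abs(z - m0_hat)) + 5 * sqrt(error_var)))
  fit_point <- function(beta, pb, equal_effects = FALSE) {
    obj <- function(th) {
      U <- exp(th[1]) / t
      e1 <- exp(th[2])
      m0 <- if (estimate_m0) th[3] else m0_hat
      -loglik(U, beta, if (equal_effects) NA else beta / e1, pb, m0,
              equal_effects, mean_effect = e1)
    }
    base <- c(log(u_seed * t), log(e_seed), if (estimate_m0) m0_hat)
    starts <- list(base,
                   base + c(log(10), -log(10), if (estimate_m0) 0),
                   base + c(-log(10), log(10), if (estimate_m0) 0))
    lower <- c(log(lam_lim[1]), log(e_lim[1]),
               if (estimate_m0) m0_hat - 10 * sqrt(anc_var))
    upper <- c(log(lam_lim[2]), log(e_lim[2]),
               if (estimate_m0) m0_hat + 10 * sqrt(anc_var))
    fit <- tryCatch(multi_start_optim(obj, starts, lower, upper),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(U = exp(fit$par[1]) / t, mean_effect = exp(fit$par[2]),
         m0 = if (estimate_m0) fit$par[3] else m0_hat,
         logL = -fit$objective, convergence = fit$convergence)
  }
  surface <- expand.grid(beta = beta_grid, pb = pb_grid)
  surface$U <- surface$mean_effect <- surface$logL <- NA_real_
  for (i in seq_len(nrow(surface))) {
    p <- fit_point(surface$beta[i], surface$pb[i])
    if (is.null(p)) next
    surface$U[i] <- p$U
    surface$mean_effect[i] <- p$mean_effect
    surface$logL[i] <- p$logL
  }
  if (all(is.na(surface$logL))) stop("all profile grid points failed")
  best <- which.max(surface$logL)
  mle <- fit_point(surface$beta[best], surface$pb[best])
  # equal-effects envelope over the P_B grid
  eq_tab <- lapply(pb_grid, function(pb) {
    p <- fit_point(NA, pb, equal_effects = TRUE)
    if (is.null(p)) return(NULL)
    data.frame(pb = pb, U = p$U, mean_effect = p$mean_effect, logL = p$logL)
  })
  eq_tab <- do.call(rbind, eq_tab)
  eq_best <- if (!is.null(eq_tab) && nrow(eq_tab) > 0) {
    eq_tab[which.max(eq_tab$logL), ]
  } else NULL
  ll_max <- mle$logL
  # 2-LL grid intervals for the profiled grid parameters
  prof_b <- tapply(surface$logL, surface$beta, max, na.rm = TRUE)
  prof_p <- tapply(surface$logL, surface$pb, max, na.rm = TRUE)
  ci_beta <- range(as.numeric(names(prof_b))[prof_b >= ll_max - 2])
  ci_pb <- range(as.numeric(names(prof_p))[prof_p >= ll_max - 2])
  ci_u <- ci_e <- c(NA_real_, NA_real_)
  if (ci) {
    ci_u <- profile_interval_u(surface, beta_grid, pb_grid, loglik, ll_max,
                               mle, t, estimate_m0, m0_hat, anc_var,
                               lam_lim, e_lim)
    ci_e <- profile_interval_e(surface, beta_grid, pb_grid, loglik, ll_max,
                               mle, t, estimate_m0, m0_hat, anc_var,
                               lam_lim, e_lim)
  }
  out <- list(U = mle$U, beta = surface$beta[best],
              alpha = surface$beta[best] / mle$mean_effect,
              mean_effect = mle$mean_effect,
              p_beneficial = surface$pb[best], logL = ll_max,
              m0 = mle$m0, error_var = error_var, t = t,
              surface = surface,
              equal_effects = eq_best,
              ci = list(U = ci_u, mean_effect = ci_e,
                        beta = ci_beta, p_beneficial = ci_pb),
              n_lines = length(z))
  class(out) <- "gamma_mutation_model"
  out
}

# profile of logL over fixed U (maximized over alpha and the grids); walks
# outward from the MLE until the 2-LL drop is bracketed, then interpolates
profile_interval_u <- function(surface, beta_grid, pb_grid, loglik, ll_max,
                               mle, t, estimate_m0, m0_hat, anc_var,
                               lam_lim, e_lim, drop = 2, step = log(2),
                               max_steps = 30) {
  prof_at_u <- function(U) {
    vals <- vapply(seq_len(nrow(surface)), function(i) {
      beta <- surface$beta[i]
      e0 <- surface$mean_effect[i]
      if (!is.finite(e0)) e0 <- mle$mean_effect
      obj <- function(le) {
        -loglik(U, beta, beta / exp(le), surface$pb[i],
                if (estimate_m0) mle$m0 else m0_hat)
      }
      o <- tryCatch(stats::optimize(obj, interval = log(e_lim) +
                                      c(0, 0), tol = 1e-6),
                    error = function(e) NULL)
      o2 <- tryCatch(stats::optimize(obj,
                                     interval = c(log(e0) - 6, log(e0) + 6),
                                     tol = 1e-6),
                     error = function(e) NULL)
      cand <- c(if (!is.null(o)) -o$objective,
                if (!is.null(o2)) -o2$objective)
      if (length(cand) == 0) -Inf else max(cand)
    }, numeric(1))
    max(vals)
  }
  walk <- function(direction) {
    lu <- log(mle$U)
    last_ll <- ll_max
    last_lu <- lu
    for (k in seq_len(max_steps)) {
      lu <- lu + direction * step
      if (exp(lu) * t < lam_lim[1] || exp(lu) * t > lam_lim[2]) break
      ll <- prof_at_u(exp(lu))
      if (ll < ll_max - drop) {
        frac <- (last_ll - (ll_max - drop)) / (last_ll - ll)
        return(exp(last_lu + direction * step * frac))
      }
      last_ll <- ll
      last_lu <- lu
    }
    exp(last_lu)  # drop never reached inside the searched range
  }
  c(walk(-1), walk(+1))
}

# profile over the mean effect E = beta/alpha (maximized over U, grids)
profile_interval_e <- function(surface, beta_grid, pb_grid, loglik, ll_max,
                               mle, t, estimate_m0, m0_hat, anc_var,
                               lam_lim, e_lim, drop = 2, step = log(2),
                               max_steps = 30) {
  prof_at_e <- function(E) {
    vals <- vapply(seq_len(nrow(surface)), function(i) {
      beta <- surface$beta[i]
      u0 <- surface$U[i]
      if (!is.finite(u0)) u0 <- mle$U
      obj <- function(llam) {
        -loglik(exp(llam) / t, beta, beta / E, surface$pb[i],
                if (estimate_m0) mle$m0 else m0_hat)
      }
      o <- tryCatch(stats::optimize(obj,
                                    interval = c(log(u0 * t) - 8,
                                                 log(u0 * t) + 8),
                                    tol = 1e-6),
                    error = function(e) NULL)
      if (is.null(o)) -Inf else -o$objective
    }, numeric(1))
    max(vals)
  }
  walk <- function(direction) {
    le <- log(mle$mean_effect)
    last_ll <- ll_max
    last_le <- le
    for (k in seq_len(max_steps)) {
      le <- le + direction * step
      if (exp(le) < e_lim[1] || exp(le) > e_lim[2]) break
      ll <- prof_at_e(exp(le))
      if (ll < ll_max - drop) {
        frac <- (last_ll - (ll_max - drop)) / (last_ll - ll)
        return(exp(last_le + direction * step * frac))
      }
      last_ll <- ll
      last_le <- le
    }
    exp(last_le)
  }
  c(walk(-1), walk(+1))
}

#' @export
print.gamma_mutation_model <- function(x, ...) {
  cat(sprintf(
    "Poisson-gamma ML fit (%d lines, t = %d): U = %.3g (2-LL CI %.3g - %.3g)\n",
    x$n_lines, x$t, x$U, x$ci$U[1], x$ci$U[2]))
  cat(sprintf("  E(effect) = %.3g (CI %.3g - %.3g), beta = %.3g, P_B = %.2f, logL = %.3f\n",
              x$mean_effect, x$ci$mean_effect[1], x$ci$mean_effect[2],
              x$beta, x$p_beneficial, x$logL))
  invisible(x)
}

#' Dominance from diploid and derived-haploid mean declines
#'
#' With additive effects across loci and a mean heterozygous mutation
#' number n per line, the cumulative mean fitness declines are
#' `w_dip = n a (1 + k)` in diploids and `w_hap = n a` in derived haploids,
#' so `k = w_dip / w_hap - 1` and `h = (k + 1) / 2 = w_dip / (2 w_hap)` —
#' independent of the mutation number. `h = 0.5` is additivity; smaller
#' values mean deleterious mutations are partially recessive.
#'
#' @param w_dip_bar,w_hap_bar cumulative mean declines (trait units) of the
#'   same trait over the same lines; `w_hap_bar` must be non-zero.
#' @return list: `k`, `h`, `w_dip_bar`, `w_hap_bar`.
#' @export
dominance <- function(w_dip_bar, w_hap_bar) {
  if (w_hap_bar == 0) stop("zero haploid decline: dominance undefined")
  k <- w_dip_bar / w_hap_bar - 1
  list(k = k, h = (k + 1) / 2, w_dip_bar = w_dip_bar, w_hap_bar = w_hap_bar)
}

#' Dominance estimated from observation tables
#'
#' Computes the cumulative mean declines of diploid and derived-haploid
#' growth rate relative to their ancestors, restricted to the MA lines with
#' both diploid and haploid measurements, and applies [dominance()].
#'
#' @param dip_obs diploid MA `ma_obs` (one trait); `hap_obs` haploid MA
#'   table whose `parent` keys match `dip_obs` lines.
#' @param hap_obs haploid MA `ma_obs` table (one trait).
#' @param anc_dip,anc_hap ancestor tables for the two traits.
#' @return as [dominance()], plus `n_lines` used.
#' @export
estimate_dominance <- function(dip_obs, hap_obs, anc_dip, anc_hap) {
  dip_obs <- observation_table(dip_obs)
  hap_obs <- observation_table(hap_obs)
  shared <- intersect(unique(dip_obs$line), unique(hap_obs$parent))
  if (length(shared) == 0) stop("no shared lines between ploidies")
  dip_lm <- line_means(dip_obs[dip_obs$line %in% shared, ])
  hap_sub <- hap_obs[hap_obs$parent %in% shared, ]
  hap_parent_means <- tapply(hap_sub$value, hap_sub$parent, mean)
  w_dip <- mean(observation_table(anc_dip)$value) - mean(dip_lm$mean)
  w_hap <- mean(observation_table(anc_hap)$value) - mean(hap_parent_means)
  c(dominance(w_dip, w_hap), list(n_lines = length(shared)))
}
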