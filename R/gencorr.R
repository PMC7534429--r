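# Bivariate line-level REML. Replicates of the two traits come from
# different assays and are not paired, so only the line-level covariance is
# identifiable: the model has an unstructured 2x2 among-line covariance G
# and independent trait-specific residual variances (no residual
# covariance). Blocks are per line; X carries trait-specific intercepts.

build_bivariate_blocks <- function(obs1, obs2) {
  lines <- intersect(unique(obs1$line), unique(obs2$line))
  if (length(lines) < 3) stop("fewer than 3 shared lines")
  y1 <- split(obs1$value, factor(obs1$line, levels = lines))
  y2 <- split(obs2$value, factor(obs2$line, levels = lines))
  lapply(lines, function(l) list(y1 = y1[[l]], y2 = y2[[l]],
                                 n1 = length(y1[[l]]), n2 = length(y2[[l]])))
}

bivariate_neg2ll <- function(blocks, G, r1, r2) {
  V_list <- X_list <- y_list <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    n <- b$n1 + b$n2
    tr <- rep(1:2, c(b$n1, b$n2))
    V <- G[tr, tr, drop = FALSE]
    diag(V) <- diag(V) + c(rep(r1, b$n1), rep(r2, b$n2))
    X <- matrix(0, n, 2)
    X[cbind(seq_len(n), tr)] <- 1
    V_list[[i]] <- V
    X_list[[i]] <- X
    y_list[[i]] <- c(b$y1, b$y2)
  }
  reml_neg2ll_blocks(V_list, y_list, X_list)
}

#' Mutational genetic correlation between two traits
#'
#' Fits the bivariate among-line mixed model by direct REML maximization
#' and reports the line-level (mutational) correlation
#' `r_g = cov_L / (sigma_L1 sigma_L2)`. The among-line covariance is
#' parameterized by its Cholesky factor, which enforces positive
#' semi-definiteness; at the boundary `r_g` is pinned to +/-(1 - 1e-9).
#' The fit is flagged inestimable when either line variance collapses to
#' (numerical) zero, in which case the correlation is undefined.
#'
#' @param obs_trait1,obs_trait2 `ma_obs` tables of the two traits measured
#'   on the same lines (one treatment; replicates need not be paired).
#' @param constrain_r fix the correlation at this value (0 or 1) for the
#'   likelihood-ratio null fits; NULL (default) leaves it free.
#' @return object of class `genetic_correlation`: `r_g`, `G` (2x2 among-line
#'   covariance), `residuals` (per-trait), `logLik`, `estimable`, `n_lines`.
#' @export
fit_bivariate_lines <- function(obs_trait1, obs_trait2, constrain_r = NULL) {
  obs1 <- observation_table(obs_trait1)
  obs2 <- observation_table(obs_trait2)
  blocks <- build_bivariate_blocks(obs1, obs2)
  v1 <- stats::var(obs1$value)
  v2 <- stats::var(obs2$value)
  if (is.null(constrain_r)) {
    # theta: log l11, l21 (scaled), log l22, log r1, log r2
    obj <- function(theta) {
      L <- matrix(c(exp(theta[1]), theta[2], 0, exp(theta[3])), 2, 2)
      G <- L %*% t(L)
      bivariate_neg2ll(blocks, G, exp(theta[4]), exp(theta[5]))
    }
    s0 <- c(log(sqrt(v1 / 4)), 0, log(sqrt(v2 / 4)),
            log(v1 / 2), log(v2 / 2))
    starts <- list(s0, s0 + c(log(3), 0.1, log(3), 0, 0),
                   s0 + c(log(0.2), -0.1, log(0.2), 0, 0))
    fit <- multi_start_optim(obj, starts, lower = -40, upper = 20)
    L <- matrix(c(exp(fit$par[1]), fit$par[2], 0, exp(fit$par[3])), 2, 2)
    G <- L %*% t(L)
    res <- exp(fit$par[4:5])
  } else {
    stopifnot(constrain_r >= -1, constrain_r <= 1)
    obj <- function(theta) {
      s1 <- exp(theta[1]); s2 <- exp(theta[2])
      G <- matrix(c(s1^2, constrain_r * s1 * s2,
                    constrain_r * s1 * s2, s2^2), 2, 2)
      bivariate_neg2ll(blocks, G, exp(theta[3]), exp(theta[4]))
    }
    s0 <- c(log(sqrt(v1 / 4)), log(sqrt(v2 / 4)), log(v1 / 2), log(v2 / 2))
    starts <- list(s0, s0 + log(3), s0 - log(3))
    fit <- multi_start_optim(obj, starts, lower = -40, upper = 20)
    s1 <- exp(fit$par[1]); s2 <- exp(fit$par[2])
    G <- matrix(c(s1^2, constrain_r * s1 * s2,
                  constrain_r * s1 * s2, s2^2), 2, 2)
    res <- exp(fit$par[3:4])
  }
  tol1 <- 1e-7 * (v1 + res[1])
  tol2 <- 1e-7 * (v2 + res[2])
  estimable <- G[1, 1] > tol1 && G[2, 2] > tol2
  r_g <- if (estimable) G[1, 2] / sqrt(G[1, 1] * G[2, 2]) else NA_real_
  if (!is.na(r_g)) r_g <- max(min(r_g, 1 - 1e-9), -(1 - 1e-9))
  out <- list(r_g = r_g, G = G, residuals = res,
              logLik = -fit$objective / 2, estimable = estimable,
              n_lines = length(blocks), constrain_r = constrain_r)
  class(out) <- "genetic_correlation"
  out
}

#' @export
print.genetic_correlation <- function(x, ...) {
  cat(sprintf("Among-line genetic correlation: r_g = %s (%d lines, logLik %.3f)%s\n",
              ifelse(is.na(x$r_g), "inestimable", sprintf("%.3f", x$r_g)),
              x$n_lines, x$logLik,
              if (!x$estimable) " [line variance at boundary]" else ""))
  invisible(x)
}

#' Likelihood-ratio test of the genetic correlation against 0 or 1
#'
#' The test against `r_g = 0` is two-tailed (`chi^2_1`); the test against
#' `r_g = 1` lies on the boundary of the correlation's range and uses the
#' halved `0.5 chi^2_0 + 0.5 chi^2_1` reference (one-tailed).
#'
#' @param obs_trait1,obs_trait2 `ma_obs` tables as in [fit_bivariate_lines()].
#' @param r0 null value, 0 or 1.
#' @param full optional pre-computed unconstrained fit.
#' @return list: `p`, `lr`, `full`, `constrained`.
#' @export
lrt_rg <- function(obs_trait1, obs_trait2, r0 = 0, full = NULL) {
  stopifnot(r0 %in% c(0, 1))
  if (is.null(full)) full <- fit_bivariate_lines(obs_trait1, obs_trait2)
  if (!full$estimable) stop("unconstrained fit inestimable")
  constrained <- fit_bivariate_lines(obs_trait1, obs_trait2, constrain_r = r0)
  lr <- max(0, 2 * (full$logLik - constrained$logLik))
  p <- if (r0 == 0) {
    stats::pchisq(lr, df = 1, lower.tail = FALSE)
  } else if (lr <= 0) 1 else {
    0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  }
  list(p = p, lr = lr, full = full, constrained = constrained)
}

#' Bootstrap test for a difference in genetic correlation between treatments
#'
#' Resamples lines with replacement within each treatment, refits the
#' bivariate model in both, and forms the bootstrap distribution of
#' `r_g(A) - r_g(B)`. The two-sided percentile p-value is the doubled
#' smaller tail of that distribution around zero.
#'
#' @param pair_a,pair_b lists of two `ma_obs` tables (the trait pair) for
#'   treatments A and B.
#' @param n_iter bootstrap iterations (study default 2000).
#' @param seed RNG seed.
#' @return list: `p`, `difference` (point estimate), `boot` (vector of
#'   bootstrap differences), `n_used` (iterations with estimable fits).
#' @export
bootstrap_rg_difference <- function(pair_a, pair_b, n_iter = 2000, seed = 1L) {
  fit_a <- fit_bivariate_lines(pair_a[[1]], pair_a[[2]])
  fit_b <- fit_bivariate_lines(pair_b[[1]], pair_b[[2]])
  point <- fit_a$r_g - fit_b$r_g
  set.seed(seed)
  resample_pair <- function(pair) {
    o1 <- observation_table(pair[[1]])
    o2 <- observation_table(pair[[2]])
    lines <- intersect(unique(o1$line), unique(o2$line))
    pick <- sample(lines, length(lines), replace = TRUE)
    rebuild <- function(o) {
      parts <- lapply(seq_along(pick), function(i) {
        d <- o[o$line == pick[i], , drop = FALSE]
        d$line <- sprintf("bs%03d", i)
        d
      })
      do.call(rbind, parts)
    }
    list(rebuild(o1), rebuild(o2))
  }
  boot <- rep(NA_real_, n_iter)
  for (it in seq_len(n_iter)) {
    ra <- resample_pair(pair_a)
    rb <- resample_pair(pair_b)
    fa <- tryCatch(fit_bivariate_lines(ra[[1]], ra[[2]]),
                   error = function(e) NULL)
    fb <- tryCatch(fit_bivariate_lines(rb[[1]], rb[[2]]),
                   error = function(e) NULL)
    if (is.null(fa) || is.null(fb)) next
    boot[it] <- fa$r_g - fb$r_g
  }
  ok <- boot[is.finite(boot)]
  p <- if (length(ok) == 0) NA_real_ else {
    min(1, 2 * min(mean(ok <= 0), mean(ok >= 0)))
  }
  list(p = p, difference = point, boot = boot, n_used = length(ok))
}
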