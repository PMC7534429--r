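#' Nested REML variance components for derived-haploid growth
#'
#' Decomposes haploid growth-rate variance into components due to diploid
#' parent line, tetrad within parent, haploid strain (spore) within tetrad,
#' and residual (replicate measurements of the same strain), by direct
#' maximization of the restricted likelihood of the four-component nested
#' Gaussian model. The fit supports unbalanced designs; components are
#' constrained non-negative (optimization over log variances with
#' multi-start seeding at 0.1x, 1x and 10x of a moment-based guess).
#'
#' @param obs haploid `ma_obs` table for one treatment with complete
#'   `parent`, `tetrad` keys (`line` identifies the haploid strain).
#' @param fixed_zero character vector of components to pin at zero
#'   (`"parent"`, `"tetrad"`, `"spore"`): the constrained null fits used by
#'   [lrt_component_zero()].
#' @return object of class `nested_varcomp`: `components` (named numeric:
#'   parent, tetrad, spore, residual), `proportions`, `logLik` (REML),
#'   `n_levels`, `treatment`, `convergence`.
#' @export
fit_nested_reml <- function(obs, fixed_zero = character(0)) {
  obs <- observation_table(obs)
  trts <- unique(obs$treatment)
  if (length(trts) != 1) {
    stop("fit_nested_reml expects a single treatment; got: ",
         paste(trts, collapse = ", "))
  }
  comp_names <- c("parent", "tetrad", "spore", "residual")
  stopifnot(all(fixed_zero %in% comp_names[1:3]))
  n_levels <- c(parent = length(unique(obs$parent)),
                tetrad = length(unique(paste(obs$parent, obs$tetrad))),
                spore = length(unique(obs$line)),
                residual = nrow(obs))
  if (stats::var(obs$value) < 1e-24) {
    out <- list(components = stats::setNames(rep(0, 4), comp_names),
                proportions = stats::setNames(rep(0, 4), comp_names),
                logLik = NA_real_, n_levels = n_levels,
                treatment = trts, convergence = 0L)
    class(out) <- "nested_varcomp"
    return(out)
  }
  blocks <- build_nested_blocks(obs)
  free <- setdiff(comp_names, fixed_zero)
  seed <- nested_mom_seed(obs)
  names(seed) <- comp_names
  obj <- function(theta) {
    s2 <- stats::setNames(rep(0, 4), comp_names)
    s2[free] <- exp(theta)
    sl <- list(s2)
    names(sl) <- trts
    nested_neg2ll(blocks, sl)
  }
  starts <- lapply(c(0.1, 1, 10), function(f) log(seed[free] * f))
  fit <- multi_start_optim(obj, starts, lower = -45, upper = 20,
                           polish = TRUE)
  s2 <- stats::setNames(rep(0, 4), comp_names)
  s2[free] <- exp(fit$par)
  s2[s2 < 1e-12 * sum(s2)] <- 0
  out <- list(components = s2, proportions = s2 / sum(s2),
              logLik = -fit$objective / 2, n_levels = n_levels,
              treatment = trts, convergence = fit$convergence)
  class(out) <- "nested_varcomp"
  out
}

#' @export
print.nested_varcomp <- function(x, ...) {
  cat(sprintf("Nested REML variance components (%s), logLik = %.3f\n",
              x$treatment, x$logLik))
  print(round(rbind(component = x$components,
                    proportion = x$proportions), 6))
  invisible(x)
}

#' Likelihood-ratio test of a variance component against zero
#'
#' Compares the full nested fit to the fit with one component pinned at
#' zero. Because the null value lies on the boundary of the parameter
#' space, the LR statistic is referred to the 50:50 mixture
#' `0.5 chi^2_0 + 0.5 chi^2_1` (a one-tailed test).
#'
#' @param obs haploid `ma_obs` table (single treatment).
#' @param component one of `"parent"`, `"tetrad"`, `"spore"`.
#' @param full optional pre-computed full fit from [fit_nested_reml()].
#' @return list: `p`, `lr` (the LR statistic), `full`, `constrained`.
#' @export
lrt_component_zero <- function(obs, component, full = NULL) {
  if (!component %in% c("parent", "tetrad", "spore")) {
    stop("unknown component: ", component)
  }
  if (is.null(full)) full <- fit_nested_reml(obs)
  constrained <- fit_nested_reml(obs, fixed_zero = component)
  lr <- max(0, 2 * (full$logLik - constrained$logLik))
  p <- if (lr <= 0) 1 else 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  list(p = p, lr = lr, full = full, constrained = constrained)
}

#' Compare a variance-component proportion between MA treatments
#'
#' Each treatment's observations are standardized to mean zero and standard
#' deviation one, so components become proportions of total variance. The
#' alternative fits the four components separately in each treatment; the
#' null constrains the focal component to a single shared value (other
#' components stay treatment-specific). The LR statistic is referred to
#' `chi^2_1` (a two-tailed test on the shared-value constraint).
#'
#' @param obs_a,obs_b haploid `ma_obs` tables, one treatment each.
#' @param component `"parent"`, `"tetrad"`, `"spore"` or `"residual"`.
#' @return list: `p`, `lr`, `fit_a`, `fit_b` (separate standardized fits),
#'   `shared` (the constrained component value).
#' @export
compare_proportion_between_treatments <- function(obs_a, obs_b, component) {
  comp_names <- c("parent", "tetrad", "spore", "residual")
  stopifnot(component %in% comp_names)
  std <- function(obs) {
    obs <- observation_table(obs)
    s <- stats::sd(obs$value)
    if (!is.finite(s) || s == 0) stop("degenerate standardization: zero variance")
    obs$value <- (obs$value - mean(obs$value)) / s
    obs
  }
  obs_a <- std(obs_a)
  obs_b <- std(obs_b)
  ta <- unique(obs_a$treatment)
  tb <- unique(obs_b$treatment)
  stopifnot(length(ta) == 1, length(tb) == 1)
  if (ta == tb) {
    tb <- paste0(tb, "_b")
    obs_b$treatment <- tb
  }
  fit_a <- fit_nested_reml(obs_a)
  fit_b <- fit_nested_reml(obs_b)
  ll_alt <- fit_a$logLik + fit_b$logLik
  blocks <- c(build_nested_blocks(obs_a), build_nested_blocks(obs_b))
  k <- match(component, comp_names)
  free <- setdiff(seq_len(4), k)
  # theta: 3 free components for a, 3 for b, 1 shared focal component
  start_a <- pmax(fit_a$components, 1e-8)
  start_b <- pmax(fit_b$components, 1e-8)
  base_start <- log(c(start_a[free], start_b[free],
                      (start_a[k] + start_b[k]) / 2))
  obj <- function(theta) {
    s2a <- numeric(4); s2b <- numeric(4)
    s2a[free] <- exp(theta[1:3])
    s2b[free] <- exp(theta[4:6])
    s2a[k] <- s2b[k] <- exp(theta[7])
    sl <- list(s2a, s2b)
    names(sl) <- c(ta, tb)
    nested_neg2ll(blocks, sl)
  }
  starts <- list(base_start, base_start + log(0.3), base_start + log(3))
  fit0 <- multi_start_optim(obj, starts, lower = -45, upper = 20)
  ll_null <- -fit0$objective / 2
  lr <- max(0, 2 * (ll_alt - ll_null))
  list(p = stats::pchisq(lr, df = 1, lower.tail = FALSE), lr = lr,
       fit_a = fit_a, fit_b = fit_b,
       shared = exp(fit0$par[7]))
}
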