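#' Configure a mutation-accumulation simulation
#'
#' Describes one MA treatment generatively: a Poisson number of mutations per
#' line accumulates over `generations` single-cell bottleneck transfers; each
#' mutation's homozygous effect magnitude is gamma-distributed with shape
#' `beta` and rate `alpha` (mean magnitude `beta/alpha`), its sign positive
#' (beneficial) with probability `p_beneficial` and negative otherwise
#' (a reflected gamma); diploids express the fraction `h` of the homozygous
#' effect (heterozygous carriers); effects act additively across loci on the
#' measured trait scale. Replicate measurements add Gaussian noise with a
#' per-trait residual sd; MA lines may carry an inflated residual sd
#' (`sd_ma`) to emulate mutational decanalization.
#'
#' @param treatment treatment label, e.g. `"normal"` or `"salt"`.
#' @param n_lines number of MA lines.
#' @param generations number of cell generations of MA.
#' @param U genomic mutation rate (mutations / genome / generation).
#' @param beta gamma shape of the effect-magnitude distribution.
#' @param mean_effect mean homozygous effect magnitude `beta/alpha`
#'   (proportional trait decline); supply either this or `alpha`.
#' @param alpha gamma rate parameter; defaults to `beta/mean_effect`.
#' @param p_beneficial probability a mutation's effect is positive.
#' @param h dominance: fraction of the homozygous effect expressed in
#'   heterozygous diploids (0.5 = additive).
#' @param traits data.frame describing the continuous traits:
#'   columns `trait`, `ploidy` (`"diploid"`/`"haploid"`), `m0` (ancestral
#'   mean), `sd_anc` (ancestral residual sd), `sd_ma` (MA residual sd).
#' @param pleiotropy_rho copula correlation of per-mutation effect magnitudes
#'   across traits; 1 (default) gives identical effects on every trait
#'   (mutational correlation 1), 0 gives independent magnitudes.
#' @param replicates replicate measurements per diploid line and trait.
#' @param anc_replicates ancestor replicate measurements per trait.
#' @param n_haploid_lines number of MA lines sampled for haploid derivation.
#' @param n_tetrads tetrads dissected per sampled line.
#' @param haploid_replicates growth replicates per surviving spore.
#' @param anc_tetrads tetrads dissected from the ancestor.
#' @param viability_p0 baseline per-spore recovery probability (mutation-free
#'   spores), calibrated so the mutation-free mean viability matches the
#'   observed ancestral spores-per-tetrad.
#' @param seed integer RNG seed; per-line streams are derived from it so
#'   adding lines never changes earlier lines.
#' @return A `sim_config` list.
#' @export
sim_config <- function(treatment = "normal",
                       n_lines = 50,
                       generations = 1503,
                       U = 1.5e-4,
                       beta = 4.4,
                       mean_effect = 0.171,
                       alpha = beta / mean_effect,
                       p_beneficial = 0,
                       h = 0.35,
                       traits = default_trait_table(treatment),
                       pleiotropy_rho = 1,
                       replicates = 10,
                       anc_replicates = 200,
                       n_haploid_lines = min(17L, n_lines),
                       n_tetrads = 5,
                       haploid_replicates = 5,
                       anc_tetrads = 11,
                       viability_p0 = 0.575,
                       seed = 1L) {
  cfg <- list(treatment = treatment, n_lines = as.integer(n_lines),
              generations = as.integer(generations), U = U, beta = beta,
              alpha = alpha, mean_effect = beta / alpha,
              p_beneficial = p_beneficial, h = h, traits = traits,
              pleiotropy_rho = pleiotropy_rho,
              replicates = as.integer(replicates),
              anc_replicates = as.integer(anc_replicates),
              n_haploid_lines = as.integer(n_haploid_lines),
              n_tetrads = as.integer(n_tetrads),
              haploid_replicates = as.integer(haploid_replicates),
              anc_tetrads = as.integer(anc_tetrads),
              viability_p0 = viability_p0, seed = as.integer(seed))
  num <- c(cfg$U, cfg$beta, cfg$alpha, cfg$p_beneficial, cfg$h,
           cfg$traits$m0, cfg$traits$sd_anc, cfg$traits$sd_ma,
           cfg$pleiotropy_rho, cfg$viability_p0)
  if (any(!is.finite(num))) stop("non-finite values in sim_config")
  stopifnot(cfg$U >= 0, cfg$beta > 0, cfg$alpha > 0,
            cfg$p_beneficial >= 0, cfg$p_beneficial <= 1,
            cfg$h >= 0, cfg$h <= 1, all(cfg$traits$sd_anc >= 0),
            all(cfg$traits$sd_ma >= 0), cfg$generations >= 1,
            cfg$viability_p0 >= 0, cfg$viability_p0 <= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Default trait table for the yeast MA design
#'
#' Four fitness components: diploid maximal growth rate and sporulation
#' efficiency measured on diploid MA lines; haploid maximal growth rate and
#' haploid viability (spores recovered per dissected tetrad) measured on
#' derived haploids. Baselines follow the reported ancestral phenotypes
#' (sporulation efficiency 23.4%, 2.3 viable spores per tetrad); residual
#' sds are set so mutational heritabilities fall in the observed
#' 1e-4 to 1e-3 range, with MA residual sds inflated to emulate the
#' observed decanalization.
#'
#' @param treatment `"normal"` or `"salt"`; selects the MA residual sds.
#' @return data.frame with columns `trait, ploidy, m0, sd_anc, sd_ma`.
#' @export
default_trait_table <- function(treatment = "normal") {
  salt <- identical(treatment, "salt")
  data.frame(
    trait = c("diploid_growth", "sporulation", "haploid_growth"),
    ploidy = c("diploid", "diploid", "haploid"),
    m0 = c(0.35, 0.234, 0.30),
    sd_anc = c(0.040, 0.080, 0.040),
    sd_ma = if (salt) c(0.043, 0.118, 0.084) else c(0.056, 0.098, 0.059),
    stringsAsFactors = FALSE
  )
}

#' Study-condition configurations for the two MA treatments
#'
#' Defaults reproduce the experiment's structure: 42 recovered normal-MA
#' lines over 1,503 generations and 47 salt-MA lines over 1,573 generations,
#' 10 growth replicates per line, 200 ancestor replicates, haploids derived
#' from 17 (normal) and 21 (salt) lines. Mutational parameters are the
#' treatment-specific ML point estimates for diploid growth rate
#' (normal: U = 1.5e-4, beta = 4.4, E(hs) = 0.060, h = 0.35;
#' salt: U = 3.6e-4, beta = 1.8, E(hs) = 0.029, h = 0.20; no beneficial
#' mutations), with homozygous magnitudes E(hs)/h.
#'
#' @param seed base RNG seed.
#' @return list with elements `normal` and `salt` (each a [sim_config()]).
#' @export
ma_study_configs <- function(seed = 1L) {
  list(
    normal = sim_config(treatment = "normal", n_lines = 42,
                        generations = 1503, U = 1.5e-4, beta = 4.4,
                        mean_effect = 0.060 / 0.35, h = 0.35,
                        n_haploid_lines = 17, seed = seed),
    salt = sim_config(treatment = "salt", n_lines = 47,
                      generations = 1573, U = 3.6e-4, beta = 1.8,
                      mean_effect = 0.029 / 0.20, h = 0.20,
                      n_haploid_lines = 21, seed = seed + 1L)
  )
}

# deterministic per-line RNG stream: adding lines never perturbs earlier ones
line_seed <- function(seed, stream, i) {
  as.integer((as.numeric(seed) * 1009 + stream * 131071 + i * 7919) %%
               2147483399)
}

# draw the per-mutation effect table for one line: one row per mutation,
# columns: sign, magnitude_<trait> for each continuous trait, fitness
# magnitude (shared scale used for spore survival)
draw_mutations <- function(n_mut, cfg) {
  traits <- cfg$traits$trait
  if (n_mut == 0) {
    eff <- matrix(numeric(0), nrow = 0, ncol = length(traits),
                  dimnames = list(NULL, traits))
    return(list(sign = numeric(0), magnitude = eff))
  }
  sign <- ifelse(stats::runif(n_mut) < cfg$p_beneficial, 1, -1)
  rho <- cfg$pleiotropy_rho
  if (rho >= 1) {
    x <- stats::rgamma(n_mut, shape = cfg$beta, rate = cfg$alpha)
    mag <- matrix(x, nrow = n_mut, ncol = length(traits),
                  dimnames = list(NULL, traits))
  } else {
    z0 <- stats::rnorm(n_mut)
    mag <- sapply(traits, function(tr) {
      z <- sqrt(rho) * z0 + sqrt(1 - rho) * stats::rnorm(n_mut)
      stats::qgamma(stats::pnorm(z), shape = cfg$beta, rate = cfg$alpha)
    })
    mag <- matrix(mag, nrow = n_mut, dimnames = list(NULL, traits))
  }
  list(sign = sign, magnitude = mag)
}

#' Simulate diploid MA lines and the ancestor
#'
#' Each line accumulates `n_i ~ Poisson(U * t)` mutations; the diploid
#' genotypic value of a trait is `m0 + h * sum(signed effects)`; replicates
#' add Gaussian residual noise. Ancestor rows (treatment `"ancestor"`,
#' a single pseudo-line) are generated with zero mutations at the ancestral
#' residual sd. The per-line mutation tables are retained in the
#' `"mutations"` attribute for haploid derivation.
#'
#' @param config a [sim_config()].
#' @param include_ancestor generate ancestor replicate rows (default TRUE).
#' @return `ma_obs` table of the diploid traits, with attribute
#'   `"mutations"` (named list per line).
#' @export
simulate_diploid_ma <- function(config, include_ancestor = TRUE) {
  cfg <- config
  stopifnot(inherits(cfg, "sim_config"))
  dip <- cfg$traits[cfg$traits$ploidy == "diploid", , drop = FALSE]
  if (nrow(dip) == 0) stop("config has no diploid traits")
  lam <- cfg$U * cfg$generations
  rows <- vector("list", cfg$n_lines + 1L)
  muts <- vector("list", cfg$n_lines)
  names(muts) <- sprintf("%s_L%02d", cfg$treatment, seq_len(cfg$n_lines))
  for (i in seq_len(cfg$n_lines)) {
    set.seed(line_seed(cfg$seed, 1L, i))
    n_mut <- stats::rpois(1, lam)
    mt <- draw_mutations(n_mut, cfg)
    muts[[i]] <- mt
    id <- names(muts)[i]
    g <- vapply(dip$trait, function(tr) {
      s <- if (n_mut > 0) sum(mt$sign * mt$magnitude[, tr]) else 0
      dip$m0[dip$trait == tr] + cfg$h * s
    }, numeric(1))
    vals <- lapply(seq_len(nrow(dip)), function(j) {
      g[j] + stats::rnorm(cfg$replicates, 0, dip$sd_ma[j])
    })
    rows[[i]] <- data.frame(
      treatment = cfg$treatment, line = id, parent = NA_character_,
      tetrad = NA_character_, spore = NA_character_,
      trait = rep(dip$trait, each = cfg$replicates),
      replicate = rep(seq_len(cfg$replicates), nrow(dip)),
      value = unlist(vals), stringsAsFactors = FALSE)
  }
  if (include_ancestor) {
    set.seed(line_seed(cfg$seed, 7L, 0L))
    rows[[cfg$n_lines + 1L]] <- data.frame(
      treatment = "ancestor", line = "A0", parent = NA_character_,
      tetrad = NA_character_, spore = NA_character_,
      trait = rep(dip$trait, each = cfg$anc_replicates),
      replicate = rep(seq_len(cfg$anc_replicates), nrow(dip)),
      value = unlist(lapply(seq_len(nrow(dip)), function(j) {
        dip$m0[j] + stats::rnorm(cfg$anc_replicates, 0, dip$sd_anc[j])
      })), stringsAsFactors = FALSE)
  }
  obs <- observation_table(do.call(rbind, rows))
  attr(obs, "mutations") <- muts
  attr(obs, "config") <- cfg
  obs
}

# the 6 ways to place a heterozygous mutation into exactly 2 of 4 spores
segregation_patterns <- utils::combn(4, 2)

#' Derive haploid spores from diploid MA lines by tetrad dissection
#'
#' For each sampled line, `n_tetrads` tetrads of four spores are generated;
#' every heterozygous mutation segregates 2:2, i.e. is assigned to exactly
#' two of the four spores, uniformly over the six possible assignments and
#' independently across mutations (free recombination). A spore survives
#' dissection with probability `viability_p0 * prod(max(0, 1 + s_j))`
#' (truncated to [0, 1]) over its carried signed fitness effects; the
#' viability trait records surviving spores per tetrad. Surviving spores are
#' measured for haploid growth: full (homozygous-scale) effects plus
#' residual noise. Ancestor rows in the input yield mutation-free ancestor
#' tetrads.
#'
#' @param diploid_lines output of [simulate_diploid_ma()] (must carry the
#'   `"mutations"` attribute).
#' @param config the matching [sim_config()]; defaults to the one stored on
#'   the input.
#' @return `ma_obs` table with traits `haploid_growth` (spore-level keys)
#'   and `haploid_viability` (tetrad-level counts).
#' @export
simulate_haploid_derivation <- function(diploid_lines, config = NULL) {
  muts <- attr(diploid_lines, "mutations")
  if (is.null(muts)) {
    stop("diploid lines lack retained mutation lists; ",
         "generate them with simulate_diploid_ma()")
  }
  cfg <- if (is.null(config)) attr(diploid_lines, "config") else config
  stopifnot(inherits(cfg, "sim_config"))
  hap <- cfg$traits[cfg$traits$ploidy == "haploid", , drop = FALSE]
  stopifnot(nrow(hap) >= 1)
  m0_hap <- hap$m0[1]
  sd_hap_ma <- hap$sd_ma[1]
  sd_hap_anc <- hap$sd_anc[1]
  sampled <- names(muts)[seq_len(min(cfg$n_haploid_lines, length(muts)))]
  has_anc <- any(diploid_lines$treatment == "ancestor")
  parents <- c(sampled, if (has_anc) "A0")
  rows <- list()
  for (p in seq_along(parents)) {
    pid <- parents[p]
    is_anc <- identical(pid, "A0")
    set.seed(line_seed(cfg$seed, 3L, p))
    mt <- if (is_anc) list(sign = numeric(0),
                           magnitude = matrix(numeric(0), 0, 0)) else muts[[pid]]
    n_mut <- length(mt$sign)
    eff_hap <- if (n_mut > 0 && "haploid_growth" %in% colnames(mt$magnitude)) {
      mt$sign * mt$magnitude[, "haploid_growth"]
    } else numeric(n_mut)
    eff_fit <- if (n_mut > 0) mt$sign * mt$magnitude[, 1] else numeric(0)
    n_tet <- if (is_anc) cfg$anc_tetrads else cfg$n_tetrads
    sd_g <- if (is_anc) sd_hap_anc else sd_hap_ma
    trt <- if (is_anc) "ancestor" else cfg$treatment
    for (tt in seq_len(n_tet)) {
      carried <- matrix(FALSE, nrow = 4, ncol = n_mut)
      if (n_mut > 0) {
        pat <- segregation_patterns[, sample.int(6, n_mut, replace = TRUE),
                                    drop = FALSE]
        for (m in seq_len(n_mut)) carried[pat[, m], m] <- TRUE
      }
      p_surv <- vapply(1:4, function(s) {
        w <- prod(pmax(0, 1 + eff_fit[carried[s, ]]))
        min(max(cfg$viability_p0 * w, 0), 1)
      }, numeric(1))
      alive <- stats::runif(4) < p_surv
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = trt, line = pid, parent = pid,
        tetrad = as.character(tt), spore = NA_character_,
        trait = "haploid_viability", replicate = 1L,
        value = sum(alive), stringsAsFactors = FALSE)
      for (s in which(alive)) {
        g <- m0_hap + sum(eff_hap[carried[s, ]])
        sid <- sprintf("%s.T%d.S%d", pid, tt, s)
        rows[[length(rows) + 1L]] <- data.frame(
          treatment = trt, line = sid, parent = pid,
          tetrad = as.character(tt), spore = as.character(s),
          trait = "haploid_growth",
          replicate = seq_len(cfg$haploid_replicates),
          value = g + stats::rnorm(cfg$haploid_replicates, 0, sd_g),
          stringsAsFactors = FALSE)
      }
    }
  }
  observation_table(do.call(rbind, rows))
}

#' Simulate the full two-treatment MA experiment
#'
#' Runs [simulate_diploid_ma()] for both treatments (ancestor rows from the
#' first) and [simulate_haploid_derivation()] for each, returning one
#' combined observation table covering all four fitness components.
#'
#' @param configs list with [sim_config()]s `normal` and `salt`,
#'   as from [ma_study_configs()].
#' @param seed overrides the configs' seeds when non-NULL.
#' @return list: `observations` (`ma_obs`), `diploid` (per-treatment tables
#'   with mutation attributes), `configs`.
#' @export
simulate_ma_experiment <- function(configs = ma_study_configs(), seed = NULL) {
  if (!is.null(seed)) {
    configs <- lapply(seq_along(configs), function(i) {
      cfg <- configs[[i]]
      cfg$seed <- as.integer(seed + i - 1L)
      cfg
    })
    names(configs) <- c("normal", "salt")[seq_along(configs)]
  }
  dips <- lapply(seq_along(configs), function(i) {
    simulate_diploid_ma(configs[[i]], include_ancestor = (i == 1L))
  })
  haps <- lapply(dips, simulate_haploid_derivation)
  all_obs <- do.call(rbind, c(lapply(dips, as.data.frame),
                              lapply(haps, as.data.frame)))
  list(observations = observation_table(all_obs),
       diploid = dips, configs = configs)
}

#' Simulate an optical-density growth curve
#'
#' Logistic trajectory `OD(t) = K OD0 e^{rt} / (K + OD0 (e^{rt} - 1))`
#' sampled on a regular grid over the assay duration, plus an additive blank
#' and Gaussian measurement noise. The generating rate is recorded in the
#' `"true_rate"` attribute so reduction estimators can be validated.
#'
#' @param true_rate Malthusian growth rate (per hour), >= 0.
#' @param od0 inoculum OD; `K` carrying-capacity OD.
#' @param K carrying capacity (OD units).
#' @param interval_h sampling interval (hours); `duration_h` assay length.
#' @param duration_h assay duration in hours.
#' @param noise_sd sd of OD measurement noise (>= 0).
#' @param blank additive blank OD.
#' @param seed RNG seed (NULL leaves the RNG state alone).
#' @return data.frame `time_h`, `od` with attributes `true_rate`, `blank`.
#' @export
simulate_growth_curve <- function(true_rate, od0 = 0.05, K = 1.0,
                                  interval_h = 0.25, duration_h = 48,
                                  noise_sd = 0.003, blank = 0.08,
                                  seed = NULL) {
  stopifnot(true_rate >= 0, noise_sd >= 0, od0 > 0, K > 0)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration_h, by = interval_h)
  e <- exp(true_rate * t)
  od <- K * od0 * e / (K + od0 * (e - 1))
  ser <- data.frame(time_h = t,
                    od = od + blank + stats::rnorm(length(t), 0, noise_sd))
  attr(ser, "true_rate") <- true_rate
  attr(ser, "blank") <- blank
  ser
}

#' Write the retained mutation lists to a sidecar CSV
#'
#' One row per mutation: line, signed effect on each trait column, and the
#' sign of the draw. Lines without mutations appear with zero rows.
#'
#' @param diploid_lines output of [simulate_diploid_ma()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(diploid_lines, path) {
  muts <- attr(diploid_lines, "mutations")
  if (is.null(muts)) stop("no retained mutation lists on this table")
  rows <- lapply(names(muts), function(l) {
    mt <- muts[[l]]
    if (length(mt$sign) == 0) return(NULL)
    cbind(data.frame(line = l, sign = mt$sign),
          as.data.frame(mt$sign * mt$magnitude))
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) out <- data.frame(line = character(0), sign = numeric(0))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
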