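#' Run the full MA analysis pipeline
#'
#' Orchestrates the stages on a combined observation table (or a freshly
#' simulated experiment): per-trait moment estimates against the ancestor,
#' nested variance components for haploid growth, pairwise genetic
#' correlations, Bateman-Mukai and (optionally) profile-ML mutation
#' parameters, dominance, and M-matrix assembly with a random-skewers
#' treatment comparison. Every stochastic stage draws from the single
#' `seed`; rerunning with the same inputs and seed reproduces the results
#' exactly.
#'
#' @param obs combined `ma_obs` table (treatments plus `"ancestor"` rows),
#'   e.g. `simulate_ma_experiment()$observations`.
#' @param generations named vector of MA generations per treatment
#'   (defaults: normal 1503, salt 1573).
#' @param n_boot bootstrap iterations for moment inference (0 = point
#'   estimates only).
#' @param run_ml run the profile-ML mutation-model fit for diploid growth
#'   (the slowest stage); `beta_grid`/`pb_grid` forwarded to
#'   [ml_profile_fit()].
#' @param beta_grid,pb_grid ML profile grids.
#' @param seed master RNG seed.
#' @param out_dir when non-NULL, per-stage CSVs and a results JSON are
#'   written there.
#' @return list of per-stage results (`moments`, `varcomp`, `gencorr`,
#'   `mutparams`, `mmatrix`, `skewers`, `dominance`, `log`).
#' @export
run_ma_pipeline <- function(obs, generations = c(normal = 1503, salt = 1573),
                            n_boot = 0, run_ml = FALSE,
                            beta_grid = c(0.5, 1, 2, 5, 20),
                            pb_grid = c(0, 0.1, 0.2),
                            seed = 1L, out_dir = NULL) {
  obs <- observation_table(obs)
  treatments <- setdiff(unique(obs$treatment), "ancestor")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  diploid_traits <- intersect(unique(obs$trait),
                              c("diploid_growth", "sporulation"))
  # moments per trait x treatment
  moments <- stage("moments", {
    rows <- list()
    for (trt in treatments) {
      t_gen <- generations[[trt]]
      for (tr in setdiff(unique(obs$trait), "haploid_viability")) {
        ma <- obs_subset(obs, tr, trt)
        an <- obs_subset(obs, tr, "ancestor")
        if (nrow(ma) == 0 || nrow(an) == 0) next
        rows[[paste(trt, tr)]] <-
          moment_estimates(ma, an, t_gen, n_boot = n_boot, seed = seed)
      }
    }
    do.call(rbind, rows)
  })
  # nested variance components for haploid growth
  varcomp <- stage("varcomp", {
    out <- lapply(treatments, function(trt) {
      hg <- obs_subset(obs, "haploid_growth", trt)
      if (nrow(hg) == 0) return(NULL)
      fit <- fit_nested_reml(hg)
      lrts <- lapply(c("parent", "tetrad", "spore"), function(cp) {
        lrt_component_zero(hg, cp, full = fit)$p
      })
      list(fit = fit, p_zero = stats::setNames(unlist(lrts),
                                               c("parent", "tetrad", "spore")))
    })
    stats::setNames(out, treatments)
  })
  # pairwise genetic correlations among diploid-assayed traits + haploid growth
  gencorr <- stage("gencorr", {
    hap_as_lines <- function(trt) {
      hg <- obs_subset(obs, "haploid_growth", trt)
      if (nrow(hg) == 0) return(NULL)
      hg$line <- hg$parent  # line-level correlation uses the diploid parent
      hg
    }
    rows <- list()
    for (trt in treatments) {
      tabs <- c(lapply(diploid_traits, function(tr) obs_subset(obs, tr, trt)),
                list(hap_as_lines(trt)))
      names(tabs) <- c(diploid_traits, "haploid_growth")
      tabs <- Filter(function(x) !is.null(x) && nrow(x) > 0, tabs)
      prs <- utils::combn(names(tabs), 2, simplify = FALSE)
      for (pr in prs) {
        fit <- tryCatch(fit_bivariate_lines(tabs[[pr[1]]], tabs[[pr[2]]]),
                        error = function(e) NULL)
        rows[[paste(trt, pr[1], pr[2])]] <- data.frame(
          treatment = trt, trait1 = pr[1], trait2 = pr[2],
          r_g = if (is.null(fit)) NA_real_ else fit$r_g,
          estimable = !is.null(fit) && fit$estimable,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  # mutation parameters: BM always, ML optionally (diploid growth)
  mutparams <- stage("mutparams", {
    out <- list()
    for (trt in treatments) {
      mm <- moments[moments$treatment == trt &
                      moments$trait == "diploid_growth", ]
      if (nrow(mm) == 1) {
        out[[trt]]$bm <- bateman_mukai(mm$delta_m, mm$v_m)
        if (run_ml) {
          out[[trt]]$ml <- ml_profile_fit(
            obs_subset(obs, "diploid_growth", trt),
            obs_subset(obs, "diploid_growth", "ancestor"),
            t = generations[[trt]],
            beta_grid = beta_grid, pb_grid = pb_grid, ci = FALSE)
        }
      }
    }
    out
  })
  dominance_est <- stage("dominance", {
    out <- lapply(treatments, function(trt) {
      dip <- obs_subset(obs, "diploid_growth", trt)
      hap <- obs_subset(obs, "haploid_growth", trt)
      if (nrow(dip) == 0 || nrow(hap) == 0) return(NULL)
      tryCatch(estimate_dominance(dip, hap,
                                  obs_subset(obs, "diploid_growth", "ancestor"),
                                  obs_subset(obs, "haploid_growth", "ancestor")),
               error = function(e) NULL)
    })
    stats::setNames(out, treatments)
  })
  # M-matrices from V_m and r_g, compared by random skewers
  mres <- stage("mmatrix", {
    mats <- lapply(treatments, function(trt) {
      mm <- moments[moments$treatment == trt, ]
      vm <- stats::setNames(pmax(mm$v_m, 0), mm$trait)
      rg <- diag(length(vm))
      dimnames(rg) <- list(names(vm), names(vm))
      gc <- gencorr[gencorr$treatment == trt, ]
      for (i in seq_len(nrow(gc))) {
        if (gc$trait1[i] %in% names(vm) && gc$trait2[i] %in% names(vm)) {
          rg[gc$trait1[i], gc$trait2[i]] <- gc$r_g[i]
          rg[gc$trait2[i], gc$trait1[i]] <- gc$r_g[i]
        }
      }
      assemble_m(vm, rg, treatment = trt)
    })
    names(mats) <- treatments
    sk <- if (length(mats) == 2) {
      shared <- intersect(complete_submatrix(mats[[1]])$traits,
                          complete_submatrix(mats[[2]])$traits)
      random_skewers(complete_submatrix(mats[[1]], keep = shared),
                     complete_submatrix(mats[[2]], keep = shared),
                     n_vectors = 100000, seed = seed)
    } else NULL
    list(matrices = mats,
         e_max = lapply(mats, function(m) {
           evolvability_max(complete_submatrix(m))
         }),
         skewers = sk)
  })
  log <- list(seed = seed, n_boot = n_boot, run_ml = run_ml,
              generations = as.list(generations),
              package_version = as.character(utils::packageVersion("mutarch")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  res <- list(moments = moments, varcomp = varcomp, gencorr = gencorr,
              mutparams = mutparams, dominance = dominance_est,
              mmatrix = mres$matrices, e_max = mres$e_max,
              skewers = mres$skewers, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(moments, file.path(out_dir, "moments.csv"),
                     row.names = FALSE)
    utils::write.csv(gencorr, file.path(out_dir, "gencorr.csv"),
                     row.names = FALSE)
    summary <- list(
      log = log,
      e_max = res$e_max,
      skewers = if (!is.null(res$skewers)) {
        list(metric = res$skewers$metric, p = res$skewers$p)
      },
      dominance = lapply(dominance_est, function(d) {
        if (is.null(d)) NULL else list(k = d$k, h = d$h)
      }))
    jsonlite::write_json(summary, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
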