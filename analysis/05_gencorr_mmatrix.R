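#!/usr/bin/env Rscript
# Stage 5: mutational genetic correlations, M-matrices and evolvability.
#
# Bivariate REML correlations among the traits (haploid growth aggregated
# to its diploid parent for line-level correlation), assembly of the
# per-generation M-matrix per treatment from V_m and r_g, random-skewers
# comparison of the two treatments, and maximum evolvability. Also
# recomputes the same quantities from the study's published matrices.

library(mutarch)

out_dir <- "results"
obs <- read_observation_table(file.path(out_dir, "observations.csv"))
moments <- read.csv(file.path(out_dir, "moments.csv"))

trait_tab <- function(trt, tr) {
  d <- obs[obs$treatment == trt & obs$trait == tr, ]
  if (tr == "haploid_growth") d$line <- d$parent
  d
}

traits <- c("diploid_growth", "sporulation", "haploid_growth")
gc_rows <- list()
mats <- list()
for (trt in c("normal", "salt")) {
  rg <- diag(3)
  dimnames(rg) <- list(traits, traits)
  for (pr in combn(traits, 2, simplify = FALSE)) {
    fit <- tryCatch(fit_bivariate_lines(trait_tab(trt, pr[1]),
                                        trait_tab(trt, pr[2])),
                    error = function(e) NULL)
    r <- if (is.null(fit) || !fit$estimable) NA_real_ else fit$r_g
    p0 <- if (!is.null(fit) && fit$estimable) {
      lrt_rg(trait_tab(trt, pr[1]), trait_tab(trt, pr[2]), r0 = 0,
             full = fit)$p
    } else NA_real_
    rg[pr[1], pr[2]] <- rg[pr[2], pr[1]] <- r
    gc_rows[[paste(trt, pr[1], pr[2])]] <- data.frame(
      treatment = trt, trait1 = pr[1], trait2 = pr[2], r_g = r, p_vs_0 = p0)
  }
  mm <- moments[moments$treatment == trt, ]
  vm <- setNames(pmax(mm$v_m, 0), mm$trait)[traits]
  mats[[trt]] <- assemble_m(vm, rg, treatment = trt)
}
gencorr <- do.call(rbind, gc_rows)
rownames(gencorr) <- NULL
write.csv(gencorr, file.path(out_dir, "gencorr.csv"), row.names = FALSE)

cat("Mutational genetic correlations:\n")
print(gencorr, digits = 2)

shared <- intersect(complete_submatrix(mats$normal)$traits,
                    complete_submatrix(mats$salt)$traits)
m_n <- complete_submatrix(mats$normal, keep = shared)
m_s <- complete_submatrix(mats$salt, keep = shared)
sk <- random_skewers(m_n, m_s, n_vectors = 100000, seed = 31)
cat(sprintf("\nsimulated M-matrices: skewers metric %.3f (p = %.3f)\n",
            sk$metric, sk$p))
cat(sprintf("  e_max: normal %.3g, salt %.3g\n",
            evolvability_max(m_n), evolvability_max(m_s)))

# the published matrices, for comparison
pm <- published_m_matrices()
p_n <- complete_submatrix(pm$normal)
p_s <- complete_submatrix(pm$salt, keep = p_n$traits)
sk_pub <- random_skewers(p_n, p_s, n_vectors = 100000, seed = 31)
cat(sprintf("\npublished M-matrices: skewers metric %.3f (p = %.3f)\n",
            sk_pub$metric, sk_pub$p))
cat(sprintf("  e_max: normal %.3g, salt %.3g\n",
            evolvability_max(p_n), evolvability_max(p_s)))
write.csv(data.frame(treatment = rep(c("normal", "salt"), each = 9),
                     expand.grid(trait_row = shared, trait_col = shared),
                     value = c(as.numeric(m_n$M), as.numeric(m_s$M))),
          file.path(out_dir, "m_matrices.csv"), row.names = FALSE)
cat("wrote gencorr.csv, m_matrices.csv\n")
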