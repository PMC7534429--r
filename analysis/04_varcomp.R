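#!/usr/bin/env Rscript
# Stage 4: nested variance components for haploid growth rate.
#
# REML decomposition into diploid parent / tetrad within parent / spore
# strain within tetrad / residual, per treatment, with boundary-corrected
# likelihood-ratio tests of each component against zero and a two-tailed
# LRT comparing the within-tetrad (segregation) proportion between
# treatments on standardized data.

library(mutarch)

out_dir <- "results"
obs <- read_observation_table(file.path(out_dir, "observations.csv"))

fits <- list()
rows <- list()
for (trt in c("normal", "salt")) {
  hg <- obs[obs$treatment == trt & obs$trait == "haploid_growth", ]
  fit <- fit_nested_reml(hg)
  fits[[trt]] <- fit
  p0 <- vapply(c("parent", "tetrad", "spore"), function(cp) {
    lrt_component_zero(hg, cp, full = fit)$p
  }, numeric(1))
  rows[[trt]] <- data.frame(
    treatment = trt, component = names(fit$components),
    variance = unname(fit$components),
    proportion = unname(fit$proportions),
    p_zero = c(unname(p0), NA))
  cat(sprintf("\n%s-MA nested components (haploid growth):\n", trt))
  print(fits[[trt]])
  cat("  LRT p (component = 0): ",
      paste(sprintf("%s %.4g", names(p0), p0), collapse = ", "), "\n")
}
varcomp <- do.call(rbind, rows)
rownames(varcomp) <- NULL
write.csv(varcomp, file.path(out_dir, "varcomp.csv"), row.names = FALSE)

cmp <- compare_proportion_between_treatments(
  obs[obs$treatment == "normal" & obs$trait == "haploid_growth", ],
  obs[obs$treatment == "salt" & obs$trait == "haploid_growth", ],
  "spore")
cat(sprintf("\nwithin-tetrad proportion: normal %.2f vs salt %.2f, LRT p = %.3f\n",
            fits$normal$proportions["spore"], fits$salt$proportions["spore"],
            cmp$p))
cat("wrote varcomp.csv\n")
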