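#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-environment MA experiment.
#
# Produces the replicate-level observation table the rest of the workflow
# consumes: 42 normal-MA lines (1,503 generations) and 47 salt-MA lines
# (1,573 generations) plus a 200-replicate ancestor, with haploids derived
# from 17 / 21 lines by tetrad dissection. Mutational parameters follow the
# treatment-specific estimates for growth rate (see ma_study_configs()).

library(mutarch)

seed <- 20260925L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cfgs <- ma_study_configs(seed = seed)
exp1 <- simulate_ma_experiment(cfgs)
obs <- exp1$observations

write_observation_table(obs, file.path(out_dir, "observations.csv"))
write_mutation_table(exp1$diploid[[1]],
                     file.path(out_dir, "mutations_normal.csv"))
write_mutation_table(exp1$diploid[[2]],
                     file.path(out_dir, "mutations_salt.csv"))

cat("Simulated MA experiment\n")
cat(sprintf("  observations : %d rows, %d traits\n", nrow(obs),
            length(unique(obs$trait))))
for (trt in unique(obs$treatment)) {
  sub <- obs[obs$treatment == trt, ]
  cat(sprintf("  %-9s: %3d lines, %4d observations\n", trt,
              length(unique(sub$line)), nrow(sub)))
}
n_mut <- vapply(attr(exp1$diploid[[1]], "mutations"),
                function(m) length(m$sign), numeric(1))
cat(sprintf("  normal-MA mutations/line: mean %.2f (Poisson mean %.2f)\n",
            mean(n_mut), cfgs$normal$U * cfgs$normal$generations))
n_mut_s <- vapply(attr(exp1$diploid[[2]], "mutations"),
                  function(m) length(m$sign), numeric(1))
cat(sprintf("  salt-MA   mutations/line: mean %.2f (Poisson mean %.2f)\n",
            mean(n_mut_s), cfgs$salt$U * cfgs$salt$generations))
cat("  wrote observations.csv, mutations_normal.csv, mutations_salt.csv\n")
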