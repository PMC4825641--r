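#!/usr/bin/env Rscript
# Stage 1 -- generate the synthetic study that stands in for the strain
# panel's raw measurements: 27 strains x 55 conditions x 2 replicate OD
# curves (48 hr, 10-min sampling), a 27 x 5 x 501 morphological trait table,
# and a 6-subgroup genotype panel (10,000 sites, max divergence ~2.5%).
#
# Usage: Rscript analysis/01_simulate.R [seed]

suppressPackageStartupMessages(library(protophen))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

cfg <- sim_config(seed = seed)
print(cfg)
study <- simulate_study(cfg)
print(study)

paths <- write_simulation(study, "results/data")
cat("\nwrote inputs:\n")
for (p in paths) cat(" ", p, "\n")

truth <- study$truth
cat(sprintf("\nground truth: %d strain x condition parameter triples\n",
            nrow(truth$params)))
cat(sprintf("reference strain (morphology): %s; designated slow strain: %s\n",
            truth$reference_strain, truth$outlier_strain))
lr <- log(truth$params$true_rate)
cat(sprintf("log rate-yield correlation in the truth: %.3f (configured %.2f)\n",
            cor(lr, log(truth$params$true_yield)),
            cfg$rate_yield_correlation))
cat(sprintf("lag decoupling: cor(log lag, log rate) = %.3f\n",
            cor(log(truth$params$true_lag), lr)))
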