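#!/usr/bin/env Rscript
# Stage 6 -- relate genetic divergence to phenotype similarity: per-site
# pairwise diversity from the haploid genotype panel, pairwise Pearson
# correlation of growth and morphology profiles, subgroup-level correlation
# summaries, and the Kendall rank association between genetic distance and
# profile correlation.
#
# Reads results/data/* and results/profile_rate.tsv; writes pairwise tables
# and association JSON.

suppressPackageStartupMessages(library(protophen))

g <- read_genotype_matrix("results/data/genotypes.tsv")
meta <- read_strain_metadata("results/data/strain_metadata.tsv")
div <- pairwise_diversity(g)
write.table(div, "results/pairwise_diversity.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("pairwise diversity over %d sites: max %.3f%%, mean %.3f%%\n",
            ncol(g), 100 * max(div$diversity), 100 * mean(div$diversity)))

prof_df <- read.delim("results/profile_rate.tsv", check.names = FALSE,
                      stringsAsFactors = FALSE)
prof <- as.matrix(prof_df[, -1]); rownames(prof) <- prof_df$strain
pc_growth <- suppressWarnings(pairwise_profile_correlation(prof, "growth"))

traits <- read_trait_table("results/data/morphology_traits.tsv")
std <- reference_standardize(traits, sort(unique(traits$strain))[1])
z <- trait_z_matrix(std)
pc_morph <- pairwise_profile_correlation(z, "morphology")

cat(sprintf("mean pairwise profile correlation: growth %.3f, morphology %.3f\n",
            attr(pc_growth, "mean_r"), attr(pc_morph, "mean_r")))

sub <- setNames(meta$subgroup, meta$strain)
gs <- group_correlation_summary(pc_growth, sub)
write.table(data.frame(subgroup = rownames(gs), round(gs, 3)),
            "results/group_correlation_growth.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("within-subgroup mean growth correlations:",
    paste(sprintf("%s=%.2f", rownames(gs), diag(gs)), collapse = " "), "\n")

a_growth <- diversity_phenotype_association(div, pc_growth)
a_morph <- diversity_phenotype_association(div, pc_morph)
cat(sprintf("growth vs diversity: Kendall tau %.3f, p = %.3g (anticorrelated)\n",
            a_growth$tau, a_growth$p_value))
cat(sprintf("morphology vs diversity: Kendall tau %.3f, p = %.3g (no coupling)\n",
            a_morph$tau, a_morph$p_value))
jsonlite::write_json(
  list(growth = list(tau = a_growth$tau, p = a_growth$p_value,
                     slope = a_growth$slope, n_pairs = a_growth$n_pairs),
       morphology = list(tau = a_morph$tau, p = a_morph$p_value,
                         slope = a_morph$slope, n_pairs = a_morph$n_pairs)),
  "results/diversity_association.json", auto_unbox = TRUE, pretty = TRUE)
cat("association results written to results/diversity_association.json\n")
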