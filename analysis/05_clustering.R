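#!/usr/bin/env Rscript
# Stage 5 -- hierarchical clustering of strains by their growth trait
# profiles (centered Pearson distance, average linkage), a two-cluster cut,
# and a permutation test of whether clusters track geographical or
# ecological origin.
#
# Reads results/profile_rate.tsv and strain metadata; writes the dendrogram
# (Newick), merge table, cluster labels and association results.

suppressPackageStartupMessages(library(protophen))

prof_df <- read.delim("results/profile_rate.tsv", check.names = FALSE,
                      stringsAsFactors = FALSE)
prof <- as.matrix(prof_df[, -1])
rownames(prof) <- prof_df$strain
meta <- read_strain_metadata("results/data/strain_metadata.tsv")

d <- correlation_distance(prof)
h <- hca_average_linkage(d)
write_dendrogram(h, "results/strain_dendrogram.nwk",
                 "results/strain_merges.tsv")
clusters <- cut_clusters(h, k = 2)
write.table(data.frame(strain = names(clusters), cluster = clusters),
            "results/strain_clusters.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("two-cluster cut sizes:", paste(table(clusters), collapse = " / "), "\n")

for (lab in c("geography", "ecology")) {
  origins <- setNames(meta[[lab]], meta$strain)
  res <- origin_association_test(clusters, origins, n_perm = 10000, seed = 1)
  cat(sprintf("%s vs clusters: chi-square %.2f, permutation p = %.3f -> %s\n",
              lab, res$statistic, res$p_value,
              if (res$p_value < 0.05) "associated"
              else "no detectable association"))
  jsonlite::write_json(
    list(label = lab, statistic = res$statistic, p_value = res$p_value,
         n_perm = res$n_perm),
    sprintf("results/origin_association_%s.json", lab), auto_unbox = TRUE)
}

# clustering the conditions by their strain response profiles (the
# reference column is identically 1 and carries no signal, so it is dropped)
dc <- correlation_distance(prof[, colnames(prof) != "YPD"],
                           axis = "conditions")
hc <- hca_average_linkage(dc)
write_dendrogram(hc, "results/condition_dendrogram.nwk")
cat("condition dendrogram written (centered Pearson / average linkage)\n")
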