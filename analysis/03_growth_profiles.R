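#!/usr/bin/env Rscript
# Stage 3 -- normalize the fitted growth parameters to the reference medium,
# classify per-condition resistance by the median ratio, and profile the
# across-strain variance including each strain's leave-one-out contribution.
#
# Reads results/growth_fits.tsv; writes profile and summary tables.

suppressPackageStartupMessages(library(protophen))

fits <- read.delim("results/growth_fits.tsv", stringsAsFactors = FALSE)
fits$flags[is.na(fits$flags)] <- ""

for (p in c("rate", "lag", "yield")) {
  prof <- suppressWarnings(normalize_to_reference(fits, "YPD", p))
  write.table(data.frame(strain = rownames(prof),
                         as.data.frame(unclass(prof)), check.names = FALSE),
              sprintf("results/profile_%s.tsv", p), sep = "\t",
              row.names = FALSE, quote = FALSE)
  cat(sprintf("%s profile: %d strains x %d conditions (%d entries)\n",
              p, nrow(prof), ncol(prof), length(prof)))
}

prof <- suppressWarnings(normalize_to_reference(fits, "YPD", "rate"))
res <- classify_condition_resistance(prof)
write.table(res, "results/condition_resistance.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nresistance classes (by median ratio, boundaries 0.3 / 0.8):\n")
print(table(res$resistance_class))

vp <- condition_variance_profile(prof, leave_one_out = TRUE)
cat(sprintf("\nmean across-condition variance of rate ratios: %.4f\n",
            vp$overall_variance))

# reference-medium variance on the raw (unnormalized) rate scale
raw <- strain_parameter_matrix(fits, "rate")
ypd_vp <- condition_variance_profile(raw[, "YPD", drop = FALSE],
                                     leave_one_out = TRUE)
v_all <- ypd_vp$condition_variance$variance[1]
contrib <- ypd_vp$contribution[, 1]
top <- names(which.max(contrib))
cat(sprintf("raw YPD rate variance: %.4f; removing %s leaves %.4f (%.0f%% of the variance)\n",
            v_all, top, var(raw[rownames(raw) != top, "YPD"]),
            100 * contrib[top]))
write.table(data.frame(strain = names(contrib), contribution = contrib),
            "results/ypd_variance_contributions.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
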