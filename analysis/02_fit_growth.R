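#!/usr/bin/env Rscript
# Stage 2 -- extract specific growth rate, lag time and biomass yield from
# every OD curve with the sliding-window maximum log-linear regression
# (15-point windows, stride 1), after background correction.
#
# Reads results/data/plate_od.csv; writes results/growth_fits.tsv.

suppressPackageStartupMessages(library(protophen))

plate <- read_plate_table("results/data/plate_od.csv")
cat(sprintf("loaded %d OD readings (%d wells)\n", nrow(plate),
            nrow(unique(plate[, c("strain", "condition", "replicate")]))))

fits <- fit_growth_table(plate)
write.table(fits, "results/growth_fits.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat(sprintf("fitted %d curves; flags: %s\n", nrow(fits),
            paste(names(table(fits$flags)), table(fits$flags),
                  sep = "=", collapse = ", ")))

# biological duplicate agreement (fitted rates, replicate 1 vs 2)
r1 <- fits[fits$replicate == 1, ]
r2 <- fits[fits$replicate == 2, ]
r2 <- r2[match(paste(r1$strain, r1$condition),
               paste(r2$strain, r2$condition)), ]
cat(sprintf("replicate reproducibility (Pearson R on rates): %.3f\n",
            cor(r1$rate, r2$rate, use = "complete.obs")))

# coupling between growth rate and biomass yield across all wells
grew <- fits$rate > 0 & fits$yield > 0
cat(sprintf("log rate vs log yield correlation: %.3f over %d growing wells\n",
            cor(log(fits$rate[grew]), log(fits$yield[grew])), sum(grew)))

ypd <- fits[fits$condition == "YPD", ]
med_rate <- median(tapply(ypd$rate, ypd$strain, mean))
cat(sprintf("median reference-medium rate %.3f /hr (doubling time %.2f hr); range %.2f-%.2f /hr\n",
            med_rate, doubling_time(med_rate),
            min(tapply(ypd$rate, ypd$strain, mean)),
            max(tapply(ypd$rate, ypd$strain, mean))))
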