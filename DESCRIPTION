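Package: protophen
Title: Phenomic Variation Analysis for a Protoploid Yeast Population
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveying intraspecific fitness and cell-morphology
    variation in a yeast strain panel. Extracts specific growth rate, lag time
    and biomass yield from microplate optical-density time series with a
    sliding-window maximum log-linear regression, normalizes trait profiles to
    a reference medium and classifies condition resistance, runs
    Kruskal-Wallis scans with Bonferroni control and principal component
    analysis over high-dimensional morphological trait tables, clusters
    strains by centered Pearson distance with average linkage, and associates
    pairwise genetic diversity with pairwise phenotype-profile similarity via
    Kendall rank correlation. Includes a synthetic-data generator with known
    ground truth (growth curves, morphology tables, structured genotype
    panels) so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape
Suggests:
    vcfR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
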