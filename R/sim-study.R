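#' Simulate a complete synthetic phenomics study
#'
#' Convenience wrapper chaining [simulate_truth()],
#' [simulate_growth_curves()], [simulate_morphology()] and
#' [simulate_genotypes()] under one configuration. Identical configurations
#' (including the seed) give bit-identical studies.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_study`: `config`, `truth`, `plate`
#'   (long-format OD table), `morphology` (trait table), `genotypes`
#'   (allele matrix), and `metadata` (strain data frame).
#' @examples
#' study <- simulate_study(sim_config(n_strains = 4, n_conditions = 3,
#'                                    n_sites = 300, n_traits = 20, seed = 7))
#' names(study)
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- simulate_truth(config)
  plate <- simulate_growth_curves(config, truth)
  morphology <- simulate_morphology(config)
  genotypes <- simulate_genotypes(config, truth)
  structure(list(config = config, truth = truth, plate = plate,
                 morphology = morphology, genotypes = genotypes,
                 metadata = truth$strains),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(paste0("Synthetic study: %d strains, %d conditions x %d reps ",
                     "(%d curves), %d traits x %d reps, %d sites\n"),
              x$config$n_strains, x$config$n_conditions,
              x$config$n_growth_replicates,
              x$config$n_strains * x$config$n_conditions *
                x$config$n_growth_replicates,
              x$config$n_traits, x$config$n_morph_replicates,
              x$config$n_sites))
  invisible(x)
}

#' Write all artifacts of a synthetic study to a directory
#'
#' Writes the plate table (CSV), the trait table, genotype matrix, strain
#' metadata and the ground-truth parameter table (TSV) in the formats the
#' package readers consume.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_simulation <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(plate = file.path(dir, "plate_od.csv"),
             traits = file.path(dir, "morphology_traits.tsv"),
             genotypes = file.path(dir, "genotypes.tsv"),
             metadata = file.path(dir, "strain_metadata.tsv"),
             truth = file.path(dir, "true_parameters.tsv"))
  utils::write.csv(study$plate, paths["plate"], row.names = FALSE,
                   quote = FALSE)
  write_trait_table(study$morphology, paths["traits"])
  write_genotype_matrix(study$genotypes, paths["genotypes"])
  utils::write.table(study$metadata, paths["metadata"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(study$truth$params, paths["truth"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(paths)
}
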