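#' Pipeline configuration
#'
#' Collects every parameter of the end-to-end analysis. With the default
#' `simulate = TRUE` the pipeline generates a synthetic study from
#' `sim_config(...)`; otherwise the four input paths must point to existing
#' files.
#'
#' @param out_dir Directory for all artifacts.
#' @param simulate Generate inputs with the synthetic-data module (default
#'   `TRUE`).
#' @param plate_path,traits_path,genotypes_path,metadata_path Input files
#'   (used when `simulate = FALSE`).
#' @param reference_condition Reference growth medium (default "YPD").
#' @param reference_strain Morphology reference strain; default the first
#'   strain in the trait table.
#' @param window,stride,min_r2,min_rate Growth-fit parameters (see
#'   [fit_growth_parameters()]).
#' @param alpha Family-wise level of the trait scan (default 0.05).
#' @param target_cumulative PCA cumulative contribution target
#'   (default 0.90).
#' @param k Number of strain clusters to report (default 2).
#' @param n_perm Permutations for the origin association test
#'   (default 1000).
#' @param seed Master seed (drives the simulation and permutation draws).
#' @param sim Named list of overrides passed to [sim_config()].
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulate = TRUE, plate_path = NULL,
                            traits_path = NULL, genotypes_path = NULL,
                            metadata_path = NULL,
                            reference_condition = "YPD",
                            reference_strain = NULL, window = 15L,
                            stride = 1L, min_r2 = 0.95, min_rate = 0.01,
                            alpha = 0.05, target_cumulative = 0.90, k = 2L,
                            n_perm = 1000L, seed = 1L, sim = list()) {
  if (!simulate) {
    paths <- c(plate_path, traits_path, genotypes_path, metadata_path)
    if (length(paths) != 4L || !all(file.exists(paths)))
      stop("with simulate = FALSE all four input paths must exist")
  }
  if (window < 2L || stride < 1L) stop("invalid window/stride")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (target_cumulative <= 0 || target_cumulative > 1)
    stop("target_cumulative must be in (0, 1]")
  if (k < 2L) stop("k must be >= 2")
  cfg <- list(out_dir = out_dir, simulate = simulate,
              plate_path = plate_path, traits_path = traits_path,
              genotypes_path = genotypes_path, metadata_path = metadata_path,
              reference_condition = reference_condition,
              reference_strain = reference_strain, window = as.integer(window),
              stride = as.integer(stride), min_r2 = min_r2,
              min_rate = min_rate, alpha = alpha,
              target_cumulative = target_cumulative, k = as.integer(k),
              n_perm = as.integer(n_perm), seed = as.integer(seed),
              sim = sim)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  args <- yaml::read_yaml(path)
  do.call(pipeline_config, args)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full phenomic analysis pipeline
#'
#' Chains every stage: simulate (or read) the study inputs, fit growth
#' parameters for every curve, normalize the three parameters to the
#' reference medium, classify condition resistance and variance, run the
#' morphology statistics (reference standardization, Kruskal-Wallis scan,
#' PCA, phenotypic variance), cluster strains and test the origin
#' association, compute pairwise diversity and the diversity-phenotype
#' Kendall association, and write every artifact plus a run manifest and a
#' summary JSON under `config$out_dir`. A failing stage aborts with the
#' stage named; artifacts already written are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  if (config$simulate) {
    sim_args <- utils::modifyList(list(seed = config$seed,
                                       reference_condition =
                                         config$reference_condition),
                                  config$sim)
    study <- .stage("simulate", {
      sc <- do.call(sim_config, sim_args)
      simulate_study(sc)
    })
    .stage("simulate", write_simulation(study, file.path(out, "inputs")))
    plate <- study$plate
    traits <- study$morphology
    genotypes <- study$genotypes
    metadata <- study$metadata
    input_paths <- unname(file.path(out, "inputs",
                                    c("plate_od.csv", "morphology_traits.tsv",
                                      "genotypes.tsv", "strain_metadata.tsv")))
  } else {
    plate <- .stage("read_inputs", read_plate_table(config$plate_path))
    traits <- .stage("read_inputs", read_trait_table(config$traits_path))
    genotypes <- .stage("read_inputs",
                        read_genotype_matrix(config$genotypes_path))
    metadata <- .stage("read_inputs",
                       read_strain_metadata(config$metadata_path))
    input_paths <- c(config$plate_path, config$traits_path,
                     config$genotypes_path, config$metadata_path)
  }

  fits <- .stage("fit_growth",
                 fit_growth_table(plate, window = config$window,
                                  stride = config$stride,
                                  min_r2 = config$min_r2,
                                  min_rate = config$min_rate))
  utils::write.table(fits, file.path(out, "growth_fits.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  profiles <- .stage("normalize", {
    lapply(stats::setNames(c("rate", "lag", "yield"),
                           c("rate", "lag", "yield")), function(p)
      normalize_to_reference(fits, config$reference_condition, p))
  })
  for (p in names(profiles))
    utils::write.table(
      data.frame(strain = rownames(profiles[[p]]),
                 as.data.frame(unclass(profiles[[p]])), check.names = FALSE),
      file.path(out, sprintf("profile_%s.tsv", p)), sep = "\t",
      row.names = FALSE, quote = FALSE)

  resistance <- .stage("classify", classify_condition_resistance(
    profiles$rate, max_missing = 0.51))
  utils::write.table(resistance, file.path(out, "condition_resistance.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  varprof <- .stage("variance",
                    condition_variance_profile(profiles$rate,
                                               leave_one_out = TRUE))

  ref_strain <- config$reference_strain
  if (is.null(ref_strain)) ref_strain <- sort(unique(traits$strain))[1]
  std <- .stage("morphology", reference_standardize(traits, ref_strain))
  scan <- .stage("morphology", kruskal_wallis_scan(std, config$alpha))
  utils::write.table(scan, file.path(out, "trait_tests.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  pca <- .stage("morphology", pca_traits(std, config$target_cumulative))
  morph_var <- .stage("morphology", trait_variance(std))

  morph_profiles <- trait_z_matrix(std)

  d_growth <- .stage("cluster", correlation_distance(profiles$rate))
  h_growth <- .stage("cluster", hca_average_linkage(d_growth))
  clusters <- cut_clusters(h_growth, config$k)
  write_dendrogram(h_growth, file.path(out, "strain_dendrogram.nwk"),
                   file.path(out, "strain_merges.tsv"))
  origins <- stats::setNames(metadata$geography, metadata$strain)
  assoc_origin <- .stage("cluster",
                         origin_association_test(clusters, origins,
                                                 n_perm = config$n_perm,
                                                 seed = config$seed))

  div <- .stage("diversity", pairwise_diversity(genotypes))
  corr_growth <- .stage("diversity",
                        pairwise_profile_correlation(profiles$rate, "growth"))
  corr_morph <- .stage("diversity",
                       pairwise_profile_correlation(morph_profiles,
                                                    "morphology"))
  assoc_growth <- .stage("diversity",
                         diversity_phenotype_association(div, corr_growth))
  assoc_morph <- .stage("diversity",
                        diversity_phenotype_association(div, corr_morph))
  utils::write.table(div, file.path(out, "pairwise_diversity.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  summary <- list(
    n_strains = nrow(metadata),
    n_conditions = ncol(profiles$rate),
    n_curves = nrow(fits),
    n_growth_entries = lapply(profiles, function(p) length(p)),
    n_morphology_records = nrow(traits),
    n_traits_tested = attr(scan, "n_tested"),
    n_significant_traits = sum(scan$significant),
    pca_components_for_target = pca$n_components,
    morphology_variance = morph_var$variance,
    growth_variance = varprof$overall_variance,
    resistance_classes = as.list(table(resistance$resistance_class)),
    cluster_sizes = as.list(table(clusters)),
    cluster_labels = as.list(clusters),
    origin_association_p = assoc_origin$p_value,
    mean_growth_pairwise_r = attr(corr_growth, "mean_r"),
    mean_morphology_pairwise_r = attr(corr_morph, "mean_r"),
    max_pairwise_diversity = max(div$diversity, na.rm = TRUE),
    growth_diversity_tau = assoc_growth$tau,
    growth_diversity_p = assoc_growth$p_value,
    morphology_diversity_tau = assoc_morph$tau,
    morphology_diversity_p = assoc_morph$p_value)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(package = "protophen",
                   version = as.character(utils::packageVersion("protophen")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = config$seed,
                   parameters = config[c("reference_condition", "window",
                                         "stride", "min_r2", "min_rate",
                                         "alpha", "target_cumulative", "k",
                                         "n_perm")],
                   reference_strain = ref_strain,
                   input_md5 = as.list(tools::md5sum(input_paths)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}
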