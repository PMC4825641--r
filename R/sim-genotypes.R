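#' Simulate a block-structured haploid genotype panel
#'
#' Generates a strains x sites 0/1 allele matrix with subgroup structure:
#' every strain descends from a common ancestral haplotype; each subgroup
#' carries shared derived alleles at a subgroup-specific per-site probability
#' (the subgroup "branch length", an increasing ladder across subgroups), and
#' each strain carries additional private derived alleles. Within-subgroup
#' pairwise divergence is therefore much smaller than between-subgroup
#' divergence, and the expected maximum pairwise divergence matches the
#' configured `max_divergence`.
#'
#' @param config A [sim_config()].
#' @param truth Optional [simulate_truth()] result; when supplied, subgroup
#'   assignments and branch lengths are taken from it so genotypes and
#'   phenotype coupling refer to the same population structure. Otherwise a
#'   fresh truth is drawn from `config`.
#' @return An integer matrix (strains x sites, dimnames set) of class
#'   `genotype_matrix` with attributes `subgroup` (named strain assignment)
#'   and `subgroup_branch`.
#' @export
simulate_genotypes <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth)) truth <- simulate_truth(config)
  set.seed(.sub_seed(config, 4L))
  ns <- config$n_strains
  L <- config$n_sites
  pg <- truth$subgroup_branch
  p_ind <- truth$strain_branch
  sub <- truth$strains$subgroup

  ancestor <- stats::rbinom(L, 1L, 0.3)
  g <- matrix(0L, ns, L,
              dimnames = list(truth$strains$strain, paste0("s", seq_len(L))))
  group_flip <- lapply(names(pg), function(gr)
    stats::rbinom(L, 1L, pg[[gr]]))
  names(group_flip) <- names(pg)
  for (i in seq_len(ns)) {
    flips <- (group_flip[[sub[i]]] + stats::rbinom(L, 1L, p_ind)) %% 2L
    g[i, ] <- (ancestor + flips) %% 2L
  }
  structure(g, subgroup = stats::setNames(sub, truth$strains$strain),
            subgroup_branch = pg,
            class = c("genotype_matrix", "matrix", "array"))
}
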