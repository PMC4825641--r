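#' Simulate a replicate-level morphological trait table
#'
#' Produces a strain x replicate x trait table in the style of image-derived
#' morphology phenotyping: each trait value is a trait-specific grand mean
#' plus a strain effect plus replicate noise, on a trait-specific scale. A
#' configured number of traits (default 384 of 501) carries a nonzero strain
#' effect; the remainder are pure replicate noise. Strain effects are drawn
#' independently of the genotype panel, mirroring a population in which
#' morphological variation is not structured by genetic divergence.
#'
#' @param config A [sim_config()].
#' @param effect_sd Strain-effect SD for signal traits in units of the
#'   replicate noise SD; defaults to `config$morph_effect_sd`.
#' @param n_signal Number of traits with a strain effect; defaults to
#'   `config$morph_signal_traits`.
#' @return A data frame with columns `strain`, `replicate`, and
#'   `trait_1` ... `trait_N` (one row per strain x replicate). Ground truth is
#'   attached as attributes: `signal_traits` (indices of traits with strain
#'   effects) and `strain_effects` (strain x trait matrix on the
#'   standardized scale).
#' @export
simulate_morphology <- function(config, effect_sd = NULL, n_signal = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(effect_sd)) effect_sd <- config$morph_effect_sd
  if (is.null(n_signal)) n_signal <- config$morph_signal_traits
  set.seed(.sub_seed(config, 3L))
  ns <- config$n_strains; nr <- config$n_morph_replicates
  nt <- config$n_traits
  strain <- sprintf("LK%02d", seq_len(ns))

  trait_mean <- stats::rnorm(nt, 50, 20)
  trait_scale <- exp(stats::rnorm(nt, 0, 0.6))
  signal <- sort(sample.int(nt, n_signal))
  eff <- matrix(0, ns, nt)
  if (n_signal > 0)
    eff[, signal] <- stats::rnorm(ns * n_signal, 0, effect_sd)

  rows <- ns * nr
  vals <- matrix(stats::rnorm(rows * nt), rows, nt)      # replicate noise, sd 1
  vals <- vals + eff[rep(seq_len(ns), each = nr), ]
  vals <- sweep(vals, 2, trait_scale, "*")
  vals <- sweep(vals, 2, trait_mean, "+")
  colnames(vals) <- paste0("trait_", seq_len(nt))
  out <- data.frame(strain = rep(strain, each = nr),
                    replicate = rep(seq_len(nr), times = ns),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(vals))
  attr(out, "signal_traits") <- signal
  attr(out, "strain_effects") <- eff
  out
}
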