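# Shared fixtures built in code. The default-scale study is expensive enough
# to be worth caching across test files (generated once per test run).

.study_cache <- new.env(parent = emptyenv())

cached_default_study <- function(seed = 101L) {
  key <- paste0("default_", seed)
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- simulate_study(sim_config(seed = seed))
  .study_cache[[key]]
}

cached_default_fits <- function(seed = 101L) {
  key <- paste0("fits_", seed)
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- fit_growth_table(cached_default_study(seed)$plate)
  .study_cache[[key]]
}

# a hand-built ground truth with controlled parameter values (same layout as
# simulate_truth output, minimal fields the growth simulator consumes)
make_truth <- function(rates, lags = 2.5, yields = 1.2,
                       strains = sprintf("T%02d", seq_along(rates)),
                       condition = "YPD") {
  n <- length(rates)
  lags <- rep_len(lags, n); yields <- rep_len(yields, n)
  structure(list(
    strains = data.frame(strain = strains, subgroup = "G1",
                         geography = "Europe", ecology = "unknown",
                         stringsAsFactors = FALSE),
    conditions = data.frame(condition = condition, class_group = "carbon",
                            rate_multiplier = 1, yield_multiplier = 1,
                            lag_multiplier = 1, stringsAsFactors = FALSE),
    params = data.frame(strain = strains, condition = condition,
                        true_rate = rates, true_lag = lags,
                        true_yield = yields, stringsAsFactors = FALSE),
    subgroup_branch = c(G1 = 0.001), strain_branch = 0.001,
    outlier_strain = strains[n], reference_strain = strains[1]),
    class = "sim_truth")
}

# small trait table with explicit strain means and replicate noise
make_trait_table <- function(strain_means, n_rep = 5, noise_sd = 1,
                             seed = 1) {
  set.seed(seed)
  ns <- nrow(strain_means); nt <- ncol(strain_means)
  vals <- strain_means[rep(seq_len(ns), each = n_rep), , drop = FALSE] +
    matrix(rnorm(ns * n_rep * nt, 0, noise_sd), ns * n_rep, nt)
  colnames(vals) <- paste0("trait_", seq_len(nt))
  cbind(data.frame(strain = rep(rownames(strain_means), each = n_rep),
                   replicate = rep(seq_len(n_rep), ns),
                   stringsAsFactors = FALSE),
        as.data.frame(vals))
}
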