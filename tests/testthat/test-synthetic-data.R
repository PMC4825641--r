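# Synthetic-data generator: configuration, determinism, ground-truth
# statistical structure

test_that("configuration validation rejects impossible designs", {
  expect_error(sim_config(n_strains = 0), "counts")
  expect_error(sim_config(n_subgroups = 50), "n_subgroups")
  expect_error(sim_config(rate_yield_correlation = 1.2), "rate_yield")
  expect_error(sim_config(duration = 1, sampling_interval = 30), "20 time")
  expect_error(sim_config(od_noise_sd = -1), "od_noise_sd")
  cfg <- sim_config(n_strains = 4, n_conditions = 3, seed = 3)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_points, 289L)
})

test_that("identical seeds give bit-identical studies, different seeds differ", {
  cfg <- sim_config(n_strains = 4, n_conditions = 3, n_sites = 100,
                    n_traits = 12, n_subgroups = 2, seed = 99)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$plate, s2$plate)
  expect_identical(s1$morphology, s2$morphology)
  expect_identical(s1$genotypes, s2$genotypes)
  s3 <- simulate_study(sim_config(n_strains = 4, n_conditions = 3,
                                  n_sites = 100, n_traits = 12,
                                  n_subgroups = 2, seed = 100))
  expect_false(identical(s1$plate$od, s3$plate$od))
})

test_that("default design produces the study-scale structural counts", {
  study <- cached_default_study()
  rt <- attr(study$plate, "replicate_truth")
  expect_equal(nrow(rt), 27 * 55 * 2)                 # 2970 curves
  expect_equal(nrow(study$truth$params), 27 * 55)     # 1485 pairs
  expect_equal(nrow(study$morphology), 27 * 5)        # 135 image sets
  expect_equal(ncol(study$morphology) - 2L, 501)
  expect_equal(dim(study$genotypes), c(27L, 10000L))
})

test_that("true rate and yield carry the configured log-scale correlation; lag is decoupled", {
  study <- cached_default_study()
  p <- study$truth$params
  expect_equal(cor(log(p$true_rate), log(p$true_yield)), 0.78,
               tolerance = 0.05 / 0.78)
  expect_lt(abs(cor(log(p$true_lag), log(p$true_rate))), 0.15)
  expect_lt(abs(cor(log(p$true_lag), log(p$true_yield))), 0.15)
})

test_that("reference-medium rates span the configured strain panel", {
  study <- cached_default_study()
  p <- study$truth$params
  ypd <- p$true_rate[p$condition == "YPD"]
  expect_true(all(ypd >= 0.17 & ypd <= 0.73))
  expect_equal(min(ypd), 0.18, tolerance = 1e-9)  # designated slow outlier
})

test_that("noiseless curves recover true parameters through the full pipeline", {
  rates <- seq(0.1, 0.8, by = 0.1)
  truth <- make_truth(rates)
  cfg <- sim_config(n_strains = length(rates), n_conditions = 1,
                    n_growth_replicates = 1, od_noise_sd = 0, seed = 2)
  plate <- simulate_growth_curves(cfg, truth, replicate_cv = 0)
  fits <- fit_growth_table(plate)
  fits <- fits[match(truth$params$strain, fits$strain), ]
  expect_true(all(abs(fits$rate / rates - 1) <= 0.02))
  expect_true(all(abs(fits$lag - 2.5) <= 0.25))
  # yield equals the asymptote where the plateau is reached within 48 hr;
  # slow growers are still climbing, so only an upper bound holds there
  fast <- rates >= 0.3
  expect_true(all(abs(fits$yield[fast] - 1.2) <= 0.05))
  expect_true(all(fits$yield <= 1.2 + 0.02))
})

test_that("a zero true rate yields a flat baseline series", {
  truth <- make_truth(c(0, 0.4))
  cfg <- sim_config(n_strains = 2, n_conditions = 1,
                    n_growth_replicates = 1, od_noise_sd = 0, seed = 3)
  plate <- simulate_growth_curves(cfg, truth, replicate_cv = 0)
  flat <- plate$od[plate$strain == "T01"]
  expect_equal(diff(range(flat)), 0)
  grown <- plate$od[plate$strain == "T02"]
  expect_gt(diff(range(grown)), 1)
})

test_that("a missing truth entry is reported by strain and condition", {
  truth <- make_truth(c(0.3, 0.4))
  truth$params <- truth$params[-1, ]
  cfg <- sim_config(n_strains = 2, n_conditions = 1, seed = 4)
  expect_error(simulate_growth_curves(cfg, truth), "T01/YPD")
})

test_that("morphology table has the configured design and ground-truth attributes", {
  cfg <- sim_config(n_strains = 6, n_traits = 40, morph_signal_traits = 25,
                    n_subgroups = 2, seed = 6)
  m <- simulate_morphology(cfg)
  expect_equal(nrow(m), 6 * 5)
  expect_equal(length(attr(m, "signal_traits")), 25)
  eff <- attr(m, "strain_effects")
  expect_equal(dim(eff), c(6L, 40L))
  null_traits <- setdiff(seq_len(40), attr(m, "signal_traits"))
  expect_true(all(eff[, null_traits] == 0))
})

test_that("pure strain signal without replicate noise is called significant", {
  means <- matrix(rep(seq(0, 45, by = 5), 2), nrow = 10,
                  dimnames = list(paste0("s", 1:10), NULL))
  tab <- make_trait_table(means, n_rep = 5, noise_sd = 1e-9)
  scan <- kruskal_wallis_scan(tab)
  expect_true(all(scan$significant))
})

test_that("genotype panel has block structure: within-subgroup pairs are closest", {
  study <- cached_default_study()
  div <- pairwise_diversity(study$genotypes)
  sub <- attr(study$genotypes, "subgroup")
  same <- sub[div$strain_a] == sub[div$strain_b]
  expect_lt(max(div$diversity[same]), min(div$diversity[!same]))
})

test_that("maximum pairwise divergence lands near the configured target", {
  for (seed in c(101, 7, 8)) {
    g <- simulate_genotypes(sim_config(seed = seed, n_sites = 4000))
    div <- pairwise_diversity(g)
    expect_equal(max(div$diversity), 0.025, tolerance = 0.005 / 0.025)
  }
})

test_that("zero branch lengths give an identical panel (all diversities zero)", {
  cfg <- sim_config(n_strains = 5, n_subgroups = 1, n_sites = 500, seed = 9)
  truth <- simulate_truth(cfg)
  truth$subgroup_branch[] <- 0
  truth$strain_branch <- 0
  g <- simulate_genotypes(cfg, truth)
  expect_true(all(pairwise_diversity(g)$diversity == 0))
})
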