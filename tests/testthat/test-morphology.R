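# Morphological trait statistics

test_that("reference standardization maps the reference distribution to (0, 1)", {
  means <- matrix(c(10, 12, 14, 20, 22, 24), nrow = 3, byrow = FALSE,
                  dimnames = list(c("ref", "a", "b"), NULL))
  tab <- make_trait_table(means, n_rep = 5, noise_sd = 2, seed = 11)
  std <- reference_standardize(tab, "ref")
  ref_rows <- std$strain == "ref"
  for (j in c("trait_1", "trait_2")) {
    expect_equal(mean(std[[j]][ref_rows]), 0, tolerance = 1e-12)
    expect_equal(sd(std[[j]][ref_rows]), 1, tolerance = 1e-12)
  }
  # x = mu_ref + 2 sigma_ref maps to 2
  mu <- mean(tab$trait_1[ref_rows]); s <- sd(tab$trait_1[ref_rows])
  tab2 <- tab; tab2$trait_1[!ref_rows][1] <- mu + 2 * s
  std2 <- reference_standardize(tab2, "ref")
  expect_equal(std2$trait_1[!ref_rows][1], 2)
})

test_that("zero-SD reference traits are dropped with a warning", {
  tab <- data.frame(strain = rep(c("ref", "a"), each = 3),
                    replicate = rep(1:3, 2),
                    trait_1 = c(5, 5, 5, 6, 7, 8),
                    trait_2 = rnorm(6))
  expect_warning(std <- reference_standardize(tab, "ref"), "trait_1")
  expect_false("trait_1" %in% names(std))
})

test_that("rank-based scan is unaffected by reference standardization", {
  means <- matrix(rnorm(5 * 4, 0, 1.5), nrow = 5,
                  dimnames = list(paste0("s", 1:5), NULL))
  tab <- make_trait_table(means, n_rep = 4, seed = 12)
  raw <- kruskal_wallis_scan(tab)
  std <- kruskal_wallis_scan(reference_standardize(tab, "s1"))
  expect_equal(std$H, raw$H, tolerance = 1e-12)
  expect_equal(std$p, raw$p, tolerance = 1e-12)
})

test_that("Kruskal-Wallis H matches the rank-formula oracle, with and without ties", {
  # textbook no-ties case: {1,2}, {3,4}, {5,6}
  tab <- data.frame(strain = rep(c("a", "b", "c"), each = 2),
                    replicate = rep(1:2, 3), trait_1 = c(1, 2, 3, 4, 5, 6))
  scan <- kruskal_wallis_scan(tab)
  expect_equal(scan$H, 32 / 7, tolerance = 1e-12)    # 12/42*(9/2+49/2+121/2)-21
  expect_equal(scan$H, oracle_kw_H(tab$trait_1, tab$strain))
  # random small instances with deliberate ties
  set.seed(13)
  for (i in 1:25) {
    n_g <- sample(2:5, 1)
    n_r <- sample(2:4, 1)
    x <- sample(1:6, n_g * n_r, replace = TRUE)  # heavy ties
    g <- rep(paste0("g", seq_len(n_g)), each = n_r)
    tab <- data.frame(strain = g, replicate = rep(seq_len(n_r), n_g),
                      trait_1 = x)
    scan <- kruskal_wallis_scan(tab)
    if (length(unique(x)) == 1L) {
      expect_equal(scan$H, 0)
      expect_equal(scan$p, 1)
    } else {
      expect_equal(scan$H, oracle_kw_H(x, g), tolerance = 1e-12)
      expect_equal(scan$p, pchisq(scan$H, n_g - 1, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  }
})

test_that("identical values across strains give H = 0, p = 1, nonsignificant", {
  tab <- data.frame(strain = rep(c("a", "b"), each = 3),
                    replicate = rep(1:3, 2), trait_1 = rep(4.2, 6))
  scan <- kruskal_wallis_scan(tab)
  expect_equal(scan$H, 0)
  expect_equal(scan$p, 1)
  expect_false(scan$significant)
})

test_that("Bonferroni uses the number of traits actually tested", {
  means <- matrix(rnorm(8), nrow = 2, dimnames = list(c("a", "b"), NULL))
  tab <- make_trait_table(means, n_rep = 3, seed = 14)
  scan <- kruskal_wallis_scan(tab)
  expect_equal(attr(scan, "n_tested"), 4)
  expect_equal(scan$p_bonferroni, pmin(1, scan$p * 4))
  expect_equal(scan$significant, scan$p_bonferroni < 0.05)
})

test_that("strains with fewer than two replicates are excluded with a warning", {
  tab <- data.frame(strain = c("a", "a", "b", "b", "c"),
                    replicate = c(1, 2, 1, 2, 1),
                    trait_1 = c(1, 2, 5, 6, 100))
  expect_warning(scan <- kruskal_wallis_scan(tab), "c")
  expect_equal(scan$H, oracle_kw_H(c(1, 2, 5, 6), c("a", "a", "b", "b")))
})

test_that("sum-of-squares partition satisfies the one-way ANOVA identity", {
  set.seed(15)
  for (i in 1:10) {
    n_g <- sample(3:8, 1); n_r <- sample(2:6, 1)
    means <- matrix(rnorm(n_g * 3, 0, 2), nrow = n_g,
                    dimnames = list(paste0("s", seq_len(n_g)), NULL))
    tab <- make_trait_table(means, n_rep = n_r, seed = i)
    scan <- kruskal_wallis_scan(tab)
    for (j in seq_len(3)) {
      x <- tab[[paste0("trait_", j)]]
      total <- sum((x - mean(x))^2)
      expect_equal(scan$ss_strains[j] + scan$ss_replicates[j], total,
                   tolerance = 1e-9)
    }
  }
})

test_that("PCA contributions match the eigenvalue oracle and reach the target", {
  # two uncorrelated variables with population variances 3 and 1
  set.seed(16)
  n <- 200
  m <- cbind(sqrt(3) * scale(rnorm(n))[, 1], scale(rnorm(n))[, 1])
  m[, 2] <- residuals(lm(m[, 2] ~ m[, 1]))          # exactly uncorrelated
  m[, 1] <- sqrt(3) * m[, 1] / sd(m[, 1]) * sqrt((n - 1) / n)
  m[, 2] <- m[, 2] / sd(m[, 2]) * sqrt((n - 1) / n)
  tab <- cbind(data.frame(strain = paste0("s", 1:n), replicate = 1),
               trait_1 = m[, 1], trait_2 = m[, 2])
  pca <- pca_traits(tab, scale. = FALSE)
  expect_equal(pca$contribution_ratio, c(0.75, 0.25), tolerance = 1e-6)
  expect_equal(pca$contribution_ratio, oracle_pca_contrib(m),
               tolerance = 1e-9)
  # perfectly collinear data: one axis carries everything
  tab1 <- cbind(data.frame(strain = paste0("s", 1:10), replicate = 1),
                trait_1 = 1:10, trait_2 = 2 * (1:10) + 3)
  p1 <- pca_traits(tab1)
  expect_equal(p1$contribution_ratio[1], 1, tolerance = 1e-9)
  expect_equal(p1$n_components, 1L)
  # contribution ratios sum to one and the cumulative curve is nondecreasing
  std <- reference_standardize(simulate_morphology(
    sim_config(n_strains = 8, n_traits = 30, morph_signal_traits = 20,
               n_subgroups = 2, seed = 17)), "LK01")
  p2 <- pca_traits(std)
  expect_equal(sum(p2$contribution_ratio), 1, tolerance = 1e-9)
  expect_true(all(diff(p2$cumulative_contribution) >= -1e-12))
  orc <- oracle_pca_contrib(do.call(cbind,
           lapply(std[, grep("^trait_", names(std))], function(x)
             tapply(x, std$strain, mean))), scale. = TRUE)
  k <- length(p2$contribution_ratio)   # prcomp keeps at most n-1 components
  expect_equal(p2$contribution_ratio, orc[seq_len(k)], tolerance = 1e-8)
  expect_lt(sum(orc[-seq_len(k)]), 1e-12)
})

test_that("phenotypic variance is ~1 under the null and grows with strain effects", {
  cfg0 <- sim_config(n_strains = 20, n_traits = 150, morph_signal_traits = 0,
                     n_subgroups = 2, seed = 18)
  std0 <- reference_standardize(simulate_morphology(cfg0), "LK01")
  v0 <- trait_variance(std0)$variance
  expect_equal(v0, 1, tolerance = 0.15)
  vs <- vapply(c(0.5, 1, 2), function(delta) {
    cfg <- sim_config(n_strains = 20, n_traits = 150,
                      morph_signal_traits = 150, morph_effect_sd = delta,
                      n_subgroups = 2, seed = 19)
    trait_variance(reference_standardize(simulate_morphology(cfg),
                                         "LK01"))$variance
  }, numeric(1))
  expect_true(all(diff(vs) > 0))
  expect_gt(vs[1], v0)
})

test_that("a panel of identical strains has zero phenotypic variance", {
  tab <- data.frame(strain = rep(paste0("s", 1:6), each = 3),
                    replicate = rep(1:3, 6),
                    trait_1 = rep(c(1, 2, 3), 6))
  expect_equal(trait_variance(tab)$variance, 0)
})

test_that("Z-profile matrix is centered so null pairwise correlations average ~ -1/(n-1)", {
  cfg <- sim_config(seed = 20, n_traits = 200, morph_signal_traits = 150,
                    n_strains = 15, n_subgroups = 3)
  std <- reference_standardize(simulate_morphology(cfg), "LK01")
  z <- trait_z_matrix(std)
  expect_equal(dim(z), c(15L, 200L))
  pc <- pairwise_profile_correlation(z, "morphology")
  expect_equal(attr(pc, "mean_r"), -1 / 14, tolerance = 0.06)
})
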