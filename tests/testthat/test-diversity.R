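# Pairwise diversity, profile correlations, Kendall association

test_that("pairwise diversity counts differing sites over shared sites", {
  g <- rbind(a = c(0, 0, 1, 1, 0, 1, 0, 1, 1, 0),
             b = c(0, 1, 1, 0, 0, 1, 0, 1, 1, 0),
             c = c(0, 0, 1, 1, 0, 1, 0, 1, 1, 0))
  div <- pairwise_diversity(g)
  get <- function(x, y) div$diversity[div$strain_a == x & div$strain_b == y]
  expect_equal(get("a", "b"), 0.2)
  expect_equal(get("a", "c"), 0)
  expect_equal(div$n_sites, rep(10, 3))
})

test_that("missing genotypes shrink the shared-site denominator", {
  g <- rbind(a = c(0, 1, NA, 1), b = c(1, 1, 0, NA))
  div <- pairwise_diversity(g)
  expect_equal(div$diversity, 0.5)   # 1 difference over 2 shared sites
  expect_equal(div$n_sites, 2)
  g2 <- rbind(a = c(NA, NA), b = c(0, 1))
  expect_warning(d2 <- pairwise_diversity(g2), "no shared")
  expect_true(is.na(d2$diversity))
})

test_that("invalid allele codes are rejected", {
  expect_error(pairwise_diversity(rbind(a = c(0, 2), b = c(1, 0))),
               "0, 1 or missing")
})

test_that("pairwise diversity satisfies the triangle inequality on complete panels", {
  set.seed(41)
  for (rep in 1:5) {
    g <- matrix(rbinom(6 * 80, 1, 0.4), 6,
                dimnames = list(paste0("s", 1:6), NULL))
    div <- pairwise_diversity(g)
    dm <- matrix(0, 6, 6, dimnames = list(paste0("s", 1:6), paste0("s", 1:6)))
    dm[cbind(div$strain_a, div$strain_b)] <- div$diversity
    dm <- dm + t(dm)
    for (i in 1:6) for (j in 1:6) for (k in 1:6)
      expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-12)
  }
})

test_that("profile correlations match the direct Pearson formula", {
  prof <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(2, 1, 5, 3))
  pc <- pairwise_profile_correlation(prof, "growth")
  get <- function(x, y) pc$r[pc$strain_a == x & pc$strain_b == y]
  expect_equal(get("a", "b"), 1)
  expect_equal(get("a", "c"), cor(prof["a", ], prof["c", ]))
  expect_equal(attr(pc, "mean_r"), mean(pc$r))
})

test_that("zero-variance profiles are skipped with a warning", {
  prof <- rbind(a = c(1, 2, 3), b = c(4, 4, 4), c = c(3, 1, 2))
  expect_warning(pc <- pairwise_profile_correlation(prof, "growth"), "b")
  expect_equal(nrow(pc), 1L)
  expect_setequal(c(pc$strain_a, pc$strain_b), c("a", "c"))
})

test_that("group summary averages within- and between-subgroup pairs", {
  pairs <- data.frame(strain_a = c("a", "a", "a", "b", "b", "c"),
                      strain_b = c("b", "c", "d", "c", "d", "d"),
                      r = c(0.9, 0.1, 0.1, 0.1, 0.1, 0.9),
                      phenotype_class = "growth", stringsAsFactors = FALSE)
  sub <- c(a = "G1", b = "G1", c = "G2", d = "G2")
  m <- group_correlation_summary(pairs, sub)
  expect_equal(m["G1", "G1"], 0.9)
  expect_equal(m["G2", "G2"], 0.9)
  expect_equal(m["G1", "G2"], 0.1)
  expect_equal(m, t(m))
  # singleton subgroup: within-group entry missing
  sub2 <- c(a = "G1", b = "G1", c = "G2", d = "G3")
  m2 <- group_correlation_summary(pairs, sub2)
  expect_true(is.na(m2["G3", "G3"]))
  expect_error(group_correlation_summary(pairs, sub[1:3]), "d")
})

test_that("Kendall tau is +-1 for monotone relations and matches brute force with ties", {
  mk <- function(x, y) {
    n <- length(x)
    sa <- paste0("p", seq_len(n)); sb <- paste0("q", seq_len(n))
    list(div = data.frame(strain_a = sa, strain_b = sb, diversity = x,
                          stringsAsFactors = FALSE),
         corr = data.frame(strain_a = sa, strain_b = sb, r = y,
                           phenotype_class = "growth",
                           stringsAsFactors = FALSE))
  }
  d <- mk(1:10 / 100, seq(0.9, 0.1, length.out = 10))
  expect_equal(diversity_phenotype_association(d$div, d$corr)$tau, -1)
  d2 <- mk(1:10 / 100, seq(0.1, 0.9, length.out = 10))
  expect_equal(diversity_phenotype_association(d2$div, d2$corr)$tau, 1)
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    x <- sample(1:8, n, replace = TRUE) / 10   # ties in x
    y <- round(rnorm(n), 1)                    # occasional ties in y
    d3 <- mk(x, y)
    res <- diversity_phenotype_association(d3$div, d3$corr)
    expect_equal(res$tau, oracle_kendall_tau_b(x, y), tolerance = 1e-12)
  }
})

test_that("association requires matched pairs and at least 3 of them", {
  d <- data.frame(strain_a = c("a", "a"), strain_b = c("b", "c"),
                  diversity = c(0.1, 0.2), stringsAsFactors = FALSE)
  co <- data.frame(strain_a = c("a", "a"), strain_b = c("b", "d"),
                   r = c(0.5, 0.6), phenotype_class = "growth",
                   stringsAsFactors = FALSE)
  expect_error(diversity_phenotype_association(d, co), "same strain pairs")
  co2 <- data.frame(strain_a = c("a", "a"), strain_b = c("b", "c"),
                    r = c(0.5, 0.6), phenotype_class = "growth",
                    stringsAsFactors = FALSE)
  expect_error(diversity_phenotype_association(d, co2), "at least 3")
})

test_that("pair order and orientation do not matter for the matching", {
  d <- data.frame(strain_a = c("b", "c", "c"), strain_b = c("a", "a", "b"),
                  diversity = c(0.1, 0.2, 0.3), stringsAsFactors = FALSE)
  co <- data.frame(strain_a = c("a", "a", "b"), strain_b = c("b", "c", "c"),
                   r = c(0.9, 0.5, 0.1), phenotype_class = "growth",
                   stringsAsFactors = FALSE)
  res <- diversity_phenotype_association(d, co)
  expect_equal(res$tau, -1)
  expect_equal(res$n_pairs, 3L)
})

test_that("the regression slope of correlation on diversity is reported", {
  sa <- paste0("p", 1:6); sb <- paste0("q", 1:6)
  x <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06)
  y <- 1 - 5 * x
  d <- data.frame(strain_a = sa, strain_b = sb, diversity = x,
                  stringsAsFactors = FALSE)
  co <- data.frame(strain_a = sa, strain_b = sb, r = y,
                   phenotype_class = "growth", stringsAsFactors = FALSE)
  expect_equal(diversity_phenotype_association(d, co)$slope, -5,
               tolerance = 1e-9)
})
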