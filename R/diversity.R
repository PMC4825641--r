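#' Pairwise genetic diversity from a haploid allele matrix
#'
#' For every unordered strain pair, the fraction of differing sites among the
#' sites where both strains are genotyped (per-site Hamming distance with
#' pairwise-complete observation).
#'
#' @param g A strains x sites matrix with entries 0, 1 or `NA`
#'   (e.g. from [simulate_genotypes()] or [read_genotype_matrix()]).
#' @return A data frame of class `pairwise_diversity` with columns
#'   `strain_a`, `strain_b`, `diversity`, `n_sites` (pairwise-complete
#'   count). Pairs sharing no genotyped site get `NA` with a warning.
#' @examples
#' g <- rbind(a = c(0, 0, 1, 1), b = c(0, 1, 1, 1))
#' pairwise_diversity(g)$diversity  # 0.25
#' @export
pairwise_diversity <- function(g) {
  g <- as.matrix(g)
  if (nrow(g) < 2L) stop("need at least 2 strains")
  bad <- !(g %in% c(0L, 1L, NA))
  if (any(bad)) stop("alleles must be 0, 1 or missing")
  strains <- rownames(g)
  if (is.null(strains)) strains <- as.character(seq_len(nrow(g)))
  obs <- !is.na(g)
  g0 <- g; g0[!obs] <- 0
  # differing-count via cross products: x(1-y) + y(1-x) over complete sites
  shared <- obs %*% t(obs)
  same1 <- g0 %*% t(g0)                       # both carry allele 1
  ones_in_shared <- g0 %*% t(obs)             # allele-1 count of row i on shared sites
  diff_ct <- ones_in_shared + t(ones_in_shared) - 2 * same1
  idx <- which(upper.tri(shared), arr.ind = TRUE)
  n_shared <- shared[idx]
  div <- ifelse(n_shared > 0, diff_ct[idx] / n_shared, NA_real_)
  if (any(n_shared == 0))
    warning("pair(s) with no shared genotyped site reported as missing")
  out <- data.frame(strain_a = strains[idx[, 1]],
                    strain_b = strains[idx[, 2]],
                    diversity = div, n_sites = n_shared,
                    stringsAsFactors = FALSE)
  class(out) <- c("pairwise_diversity", class(out))
  out
}

#' Pairwise Pearson correlation of strain phenotype profiles
#'
#' Pearson correlation between every unordered pair of strains' profiles:
#' growth-parameter ratios over conditions, or standardized trait means over
#' traits. Pairs involving a zero-variance profile are skipped with a
#' warning.
#'
#' @param profiles Strains x variables numeric matrix (rows are strains).
#' @param phenotype_class Label carried to the output, `"growth"` or
#'   `"morphology"`.
#' @return A data frame of class `pairwise_phenotype_correlation` with
#'   columns `strain_a`, `strain_b`, `r`, `phenotype_class`; the grand mean
#'   correlation is attached as attribute `mean_r`.
#' @export
pairwise_profile_correlation <- function(profiles,
                                         phenotype_class = c("growth",
                                                             "morphology")) {
  phenotype_class <- match.arg(phenotype_class)
  m <- as.matrix(profiles)
  if (nrow(m) < 2L) stop("need at least 2 strains")
  strains <- rownames(m)
  if (is.null(strains)) strains <- as.character(seq_len(nrow(m)))
  sds <- apply(m, 1, stats::sd, na.rm = TRUE)
  zero <- !is.na(sds) & sds == 0
  if (any(zero))
    warning("skipping zero-variance profile(s): ",
            paste(strains[zero], collapse = ", "))
  r <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
  r[zero, ] <- NA_real_; r[, zero] <- NA_real_
  idx <- which(upper.tri(r), arr.ind = TRUE)
  out <- data.frame(strain_a = strains[idx[, 1]],
                    strain_b = strains[idx[, 2]],
                    r = r[idx], phenotype_class = phenotype_class,
                    stringsAsFactors = FALSE)
  skip <- out$strain_a %in% strains[zero] | out$strain_b %in% strains[zero]
  out <- out[!skip, ]
  rownames(out) <- NULL
  attr(out, "mean_r") <- mean(out$r, na.rm = TRUE)
  class(out) <- c("pairwise_phenotype_correlation", class(out))
  out
}

#' Subgroup-level mean correlation matrix
#'
#' Averages pairwise strain-profile correlations within and between genetic
#' subgroups: entry (a, b) is the mean r over pairs with one strain in a and
#' the other in b; diagonal entries average the pairs inside a subgroup (and
#' are missing for singleton subgroups).
#'
#' @param pairs A [pairwise_profile_correlation()] result.
#' @param subgroups Named character vector mapping every strain to its
#'   subgroup.
#' @return A symmetric subgroup x subgroup matrix of mean correlations.
#' @export
group_correlation_summary <- function(pairs, subgroups) {
  strains <- union(pairs$strain_a, pairs$strain_b)
  if (!all(strains %in% names(subgroups)))
    stop("every strain needs a subgroup assignment; missing: ",
         paste(setdiff(strains, names(subgroups)), collapse = ", "))
  ga <- as.character(subgroups[pairs$strain_a])
  gb <- as.character(subgroups[pairs$strain_b])
  groups <- sort(unique(as.character(subgroups[strains])))
  m <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (i in seq_along(groups)) for (j in i:length(groups)) {
    sel <- (ga == groups[i] & gb == groups[j]) |
           (ga == groups[j] & gb == groups[i])
    if (any(sel)) m[i, j] <- m[j, i] <- mean(pairs$r[sel], na.rm = TRUE)
  }
  m
}

#' Kendall association between genetic diversity and phenotype similarity
#'
#' Kendall's tau-b between pairwise genetic diversity and pairwise
#' phenotype-profile correlation over matched strain pairs, with the
#' normal-approximation p-value. A negative tau means genetically more
#' distant pairs have less similar phenotype profiles.
#'
#' Note that the strain pairs are not independent (each strain appears in
#' many pairs), so the analytic p-value is anti-conservative; a
#' strain-label permutation p-value is available via `n_perm`.
#'
#' @param div A [pairwise_diversity()] result.
#' @param corr A [pairwise_profile_correlation()] result over the same
#'   strain pairs.
#' @param n_perm If > 0, additionally compute a permutation p-value by
#'   relabeling strains (default 0 = off).
#' @param seed Seed for the permutation draw.
#' @return A list of class `diversity_association`: `tau`, `p_value`
#'   (normal approximation, two-sided), `slope` (linear regression of
#'   correlation on diversity, descriptive), `n_pairs`, and optionally
#'   `p_permutation`.
#' @export
diversity_phenotype_association <- function(div, corr, n_perm = 0L,
                                            seed = 1L) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  kd <- key(div$strain_a, div$strain_b)
  kc <- key(corr$strain_a, corr$strain_b)
  if (!setequal(kd, kc) || anyDuplicated(kd) || anyDuplicated(kc))
    stop("div and corr must cover the same strain pairs exactly once")
  x <- div$diversity[match(kc, kd)]
  y <- corr$r
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 matched pairs")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                         exact = FALSE))
  fit <- stats::lm.fit(cbind(1, x), y)
  out <- list(tau = unname(ct$estimate), p_value = ct$p.value,
              slope = unname(fit$coefficients[2]), n_pairs = length(x))
  if (n_perm > 0) {
    strains <- union(corr$strain_a, corr$strain_b)
    set.seed(seed)
    obs <- abs(out$tau)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      relab <- stats::setNames(sample(strains), strains)
      ka <- relab[corr$strain_a]; kb <- relab[corr$strain_b]
      xp <- div$diversity[match(key(ka, kb), kd)][keep]
      tp <- stats::cor(xp, y, method = "kendall", use = "complete.obs")
      if (is.finite(tp) && abs(tp) >= obs - 1e-12) hits <- hits + 1L
    }
    out$p_permutation <- (1 + hits) / (n_perm + 1)
  }
  class(out) <- "diversity_association"
  out
}

#' @export
print.diversity_association <- function(x, ...) {
  cat(sprintf("Kendall tau-b = %.3f over %d pairs, p = %.3g (normal approx.)\n",
              x$tau, x$n_pairs, x$p_value))
  if (!is.null(x$p_permutation))
    cat(sprintf("  strain-permutation p = %.3g\n", x$p_permutation))
  invisible(x)
}
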