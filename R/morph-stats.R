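# internal: validate a trait table and list its trait columns
.trait_cols <- function(table) {
  if (!all(c("strain", "replicate") %in% names(table)))
    stop("trait table needs 'strain' and 'replicate' columns")
  tc <- setdiff(names(table), c("strain", "replicate"))
  if (!length(tc)) stop("trait table has no trait columns")
  tc
}

#' Standardize a trait table against a reference strain
#'
#' Transforms every trait value x to (x - mu_ref) / sigma_ref, where mu_ref
#' and sigma_ref are the mean and standard deviation of that trait across the
#' reference strain's replicates. Traits whose reference SD is zero cannot be
#' standardized and are dropped with a warning. Rank-based statistics
#' downstream are unaffected by this transform; it only fixes the scale.
#'
#' @param table A trait table (columns `strain`, `replicate`, then traits).
#' @param reference_strain Identifier of the reference strain; it must be
#'   present with at least 2 replicates.
#' @return The standardized table, with attribute `dropped_traits` naming any
#'   zero-SD exclusions.
#' @export
reference_standardize <- function(table, reference_strain) {
  tc <- .trait_cols(table)
  ref <- table[table$strain == reference_strain, tc, drop = FALSE]
  if (nrow(ref) < 2L)
    stop(sprintf("reference strain '%s' needs >= 2 replicates",
                 reference_strain))
  mu <- vapply(ref, mean, numeric(1))
  sigma <- vapply(ref, stats::sd, numeric(1))
  bad <- sigma == 0 | !is.finite(sigma)
  if (any(bad)) {
    warning("dropping trait(s) with zero reference SD: ",
            paste(tc[bad], collapse = ", "))
    tc <- tc[!bad]
  }
  out <- table[, c("strain", "replicate", tc)]
  for (j in tc) out[[j]] <- (out[[j]] - mu[[j]]) / sigma[[j]]
  attr(out, "dropped_traits") <- names(bad)[bad]
  out
}

#' Kruskal-Wallis significance scan over all traits
#'
#' For every trait, runs a tie-corrected Kruskal-Wallis test of the strain
#' effect (chi-square approximation) and applies a Bonferroni correction over
#' the number of traits actually tested. Alongside the test, the one-way
#' sum-of-squares partition is computed on the supplied values: the pooled
#' within-strain (replicate) sum of squares and the between-strain sum of
#' squares, which add up to the total sum of squares about the grand mean.
#'
#' @param table A trait table, typically reference-standardized first (the
#'   test itself is rank-based and unaffected by standardization; the
#'   sums of squares are on the supplied scale).
#' @param alpha Family-wise significance level (default 0.05).
#' @return A data frame with one row per trait: `trait`, `H`, `p`,
#'   `p_bonferroni`, `significant`, `ss_replicates`, `ss_strains`. The
#'   Bonferroni denominator is attached as attribute `n_tested`.
#' @export
kruskal_wallis_scan <- function(table, alpha = 0.05) {
  tc <- .trait_cols(table)
  reps_per <- table(table$strain)
  drop_strains <- names(reps_per)[reps_per < 2L]
  if (length(drop_strains)) {
    warning("excluding strain(s) with < 2 replicates: ",
            paste(drop_strains, collapse = ", "))
    table <- table[!table$strain %in% drop_strains, ]
  }
  if (length(unique(table$strain)) < 2L)
    stop("need at least 2 strains with >= 2 replicates")
  g <- factor(table$strain)
  n_tested <- length(tc)
  res <- lapply(tc, function(j) {
    x <- table[[j]]
    if (length(unique(x)) == 1L) {
      # complete ties: no evidence of any strain effect
      kw <- list(statistic = 0, p.value = 1)
    } else {
      kw <- stats::kruskal.test(x, g)
    }
    gm <- tapply(x, g, mean)
    ss_strains <- sum(tabulate(g) * (gm - mean(x))^2)
    ss_reps <- sum((x - gm[g])^2)
    data.frame(trait = j, H = unname(kw$statistic), p = kw$p.value,
               ss_replicates = ss_reps, ss_strains = ss_strains,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p * n_tested)
  out$significant <- out$p_bonferroni < alpha
  out <- out[, c("trait", "H", "p", "p_bonferroni", "significant",
                 "ss_replicates", "ss_strains")]
  rownames(out) <- NULL
  attr(out, "n_tested") <- n_tested
  out
}

#' PCA over strain-level trait means
#'
#' Computes strain means per trait, drops zero-variance traits, standardizes
#' the remaining traits to unit variance, and runs a principal component
#' analysis. The contribution ratio of each component (normalized variance)
#' and the smallest number of components reaching a target cumulative
#' contribution are returned.
#'
#' @param table A trait table (typically reference-standardized).
#' @param target_cumulative Cumulative contribution ratio to reach
#'   (default 0.90).
#' @param use_replicates If `TRUE`, run the PCA on replicate-level rows
#'   instead of strain means (default `FALSE`).
#' @param scale. Standardize traits to unit variance before the
#'   decomposition (default `TRUE`); set `FALSE` for a covariance PCA on the
#'   supplied scale.
#' @return A list of class `trait_pca`: `scores` (strain x component),
#'   `loadings` (trait x component), `contribution_ratio`,
#'   `cumulative_contribution`, `n_components` (the index k reaching the
#'   target), and `dropped_traits`.
#' @export
pca_traits <- function(table, target_cumulative = 0.90,
                       use_replicates = FALSE, scale. = TRUE) {
  tc <- .trait_cols(table)
  if (length(unique(table$strain)) < 2L) stop("need at least 2 strains")
  if (use_replicates) {
    m <- as.matrix(table[, tc])
    rownames(m) <- paste(table$strain, table$replicate, sep = "_")
  } else {
    m <- do.call(cbind, lapply(table[, tc], function(x)
      tapply(x, table$strain, mean)))
    colnames(m) <- tc
  }
  v <- apply(m, 2, stats::var)
  dropped <- colnames(m)[v == 0 | !is.finite(v)]
  m <- m[, !(colnames(m) %in% dropped), drop = FALSE]
  pc <- stats::prcomp(m, center = TRUE, scale. = scale.)
  ev <- pc$sdev^2
  contrib <- ev / sum(ev)
  cum <- cumsum(contrib)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 contribution_ratio = contrib,
                 cumulative_contribution = cum,
                 n_components = which(cum >= target_cumulative)[1],
                 dropped_traits = dropped),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat(sprintf("Trait PCA: %d components; %d reach %.0f%% cumulative contribution\n",
              length(x$contribution_ratio), x$n_components,
              100 * x$cumulative_contribution[x$n_components]))
  invisible(x)
}

#' Model-based phenotypic variance of a trait table
#'
#' Per trait, fits the one-way strain-effect linear model and converts each
#' strain's deviation from the grand mean into a Z value (deviation divided
#' by the standard error of the strain mean, using the pooled residual SD).
#' The trait's variance is the sample variance of those Z values across
#' strains, and the phenotype-level variance is the mean over traits. Under
#' no strain effect the Z values are approximately standard normal, so the
#' null reference value is about 1; strain effects inflate it.
#'
#' @param table A trait table (reference-standardized scale recommended).
#' @return A list of class `phenotypic_variance`: `variance` (the scalar
#'   phenotype variance), `per_trait` (named vector), `n_strains`.
#' @export
trait_variance <- function(table) {
  tc <- .trait_cols(table)
  g <- factor(table$strain)
  k <- nlevels(g)
  n_per <- tabulate(g)
  per_trait <- vapply(tc, function(j) {
    x <- table[[j]]
    gm <- tapply(x, g, mean)
    resid_ss <- sum((x - gm[g])^2)
    df <- length(x) - k
    if (df <= 0) return(NA_real_)
    s2 <- resid_ss / df
    if (s2 == 0) return(if (stats::var(gm) == 0) 0 else Inf)
    z <- (gm - mean(x)) / sqrt(s2 / n_per)
    stats::var(z)
  }, numeric(1))
  structure(list(variance = mean(per_trait[is.finite(per_trait)]),
                 per_trait = per_trait, n_strains = k),
            class = "phenotypic_variance")
}

#' Strain-by-trait matrix of Z values
#'
#' Builds the strain profile matrix used for morphology pairwise
#' comparisons: per trait, each strain's mean is expressed as a Z value, the
#' deviation from the grand mean divided by the standard error of the strain
#' mean (pooled residual SD). Z profiles are centered across strains by
#' construction, so under independent strain effects the expected pairwise
#' profile correlation is close to -1/(n_strains - 1), i.e. near zero.
#'
#' @param table A trait table (reference-standardized scale recommended).
#' @return A strains x traits numeric matrix; traits with zero residual
#'   variance are dropped.
#' @export
trait_z_matrix <- function(table) {
  tc <- .trait_cols(table)
  g <- factor(table$strain)
  k <- nlevels(g)
  n_per <- tabulate(g)
  cols <- lapply(tc, function(j) {
    x <- table[[j]]
    gm <- tapply(x, g, mean)
    df <- length(x) - k
    s2 <- sum((x - gm[g])^2) / df
    if (!is.finite(s2) || s2 <= 0) return(NULL)
    (gm - mean(x)) / sqrt(s2 / n_per)
  })
  keep <- !vapply(cols, is.null, logical(1))
  m <- do.call(cbind, cols[keep])
  colnames(m) <- tc[keep]
  m
}

#' @export
print.phenotypic_variance <- function(x, ...) {
  cat(sprintf("Phenotypic variance (Z scale): %.3f over %d traits, %d strains\n",
              x$variance, length(x$per_trait), x$n_strains))
  invisible(x)
}
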