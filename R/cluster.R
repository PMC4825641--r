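#' Centered Pearson correlation distance
#'
#' Distance d(i, j) = 1 - r(i, j), with r the Pearson correlation between the
#' two items' profiles; it ranges over [0, 2] (0 identical shape, 2 exactly
#' anticorrelated). Missing entries are handled by pairwise-complete
#' observation. Items can be the rows (strains) or the columns (conditions or
#' traits) of the profile matrix.
#'
#' @param profiles A numeric matrix, e.g. a `trait_profile` from
#'   [normalize_to_reference()] or a strain x trait mean matrix.
#' @param axis `"strains"` to compare rows (default), `"conditions"` to
#'   compare columns.
#' @param min_complete Minimum number of pairwise-complete observations
#'   required per pair (default 3).
#' @return A [stats::dist] object with attribute `metric_name =
#'   "centered_pearson"`.
#' @export
correlation_distance <- function(profiles, axis = c("strains", "conditions"),
                                 min_complete = 3L) {
  axis <- match.arg(axis)
  m <- as.matrix(profiles)
  if (axis == "conditions") m <- t(m)
  if (nrow(m) < 3L) stop("need at least 3 items")
  sds <- apply(m, 1, stats::sd, na.rm = TRUE)
  zero <- !is.na(sds) & sds == 0
  if (any(zero))
    stop("zero-variance profile(s): undefined correlation for: ",
         paste(rownames(m)[zero], collapse = ", "))
  nc <- tcrossprod(!is.na(m))
  if (any(nc[upper.tri(nc)] < min_complete))
    stop("some pairs share fewer than ", min_complete,
         " complete observations")
  r <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
  if (any(!is.finite(r)))
    stop("correlation undefined for some pair (constant overlap values)")
  d <- stats::as.dist(1 - r)
  attr(d, "metric_name") <- "centered_pearson"
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering with the unweighted average-linkage update: the
#' distance between two clusters is the mean over all cross-pair item
#' distances. Ties between candidate merges are broken deterministically in
#' favor of the pair whose items come first in lexicographic label order.
#' Average linkage on a metric distance yields nondecreasing merge heights;
#' any violation (possible with non-metric input) is flagged.
#'
#' @param d A [stats::dist] object (e.g. from [correlation_distance()]).
#' @return An [stats::hclust] object with an extra logical attribute
#'   `monotone` (TRUE when merge heights are nondecreasing).
#' @export
hca_average_linkage <- function(d) {
  if (!inherits(d, "dist")) stop("d must be a 'dist' object")
  labs <- attr(d, "Labels")
  n <- attr(d, "Size")
  if (is.null(labs)) labs <- as.character(seq_len(n))
  # reorder items lexicographically so stats::hclust's internal tie-breaking
  # (lowest index first) matches the documented label-order rule
  ord <- order(labs)
  dm <- as.matrix(d)[ord, ord]
  h <- stats::hclust(stats::as.dist(dm), method = "average")
  attr(h, "monotone") <- !is.unsorted(h$height)
  h
}

#' Cut a dendrogram into k clusters
#'
#' @param h An [stats::hclust] object.
#' @param k Number of clusters.
#' @return Named integer vector of cluster labels.
#' @export
cut_clusters <- function(h, k = 2L) {
  stats::cutree(h, k = k)
}

#' Permutation test for association between clusters and strain origin
#'
#' Tests whether cluster membership is associated with a categorical strain
#' label (geographical or ecological origin) using the chi-square statistic
#' of the cluster x origin contingency table, with the null distribution
#' obtained by randomly permuting the origin labels across strains.
#'
#' @param clusters Named cluster labels (e.g. from [cut_clusters()]).
#' @param origins Named categorical labels for the same strains.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the permutation draw.
#' @return A list of class `origin_association`: `statistic` (observed
#'   chi-square), `p_value` (permutation p, `(1 + #{perm >= obs}) /
#'   (n_perm + 1)`), `table` (the contingency table), `n_perm`. If the
#'   clustering is degenerate (a single cluster) the test is skipped with an
#'   explanatory message and `p_value = NA`.
#' @export
origin_association_test <- function(clusters, origins, n_perm = 10000L,
                                    seed = 1L) {
  if (!is.null(names(clusters)) && !is.null(names(origins))) {
    if (!setequal(names(clusters), names(origins)))
      stop("clusters and origins must cover the same strains")
    origins <- origins[names(clusters)]
  } else if (length(clusters) != length(origins)) {
    stop("clusters and origins must have the same length")
  }
  if (!is.factor(origins)) origins <- factor(origins)
  empty <- levels(origins)[table(origins) == 0]
  if (length(empty)) {
    warning("dropping empty origin categor(ies): ",
            paste(empty, collapse = ", "))
    origins <- droplevels(origins)
  }
  if (length(unique(clusters)) < 2L) {
    message("single cluster: origin association test skipped")
    return(structure(list(statistic = NA_real_, p_value = NA_real_,
                          table = table(clusters, origins),
                          n_perm = n_perm, skipped = TRUE),
                     class = "origin_association"))
  }
  stat <- function(cl, or)
    suppressWarnings(stats::chisq.test(table(cl, or),
                                       correct = FALSE)$statistic)
  obs <- stat(clusters, origins)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i)
    stat(clusters, sample(origins)), numeric(1))
  p <- (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
  structure(list(statistic = unname(obs), p_value = p,
                 table = table(clusters, origins), n_perm = n_perm,
                 skipped = FALSE),
            class = "origin_association")
}

#' @export
print.origin_association <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat("Origin association test skipped (single cluster)\n")
  } else {
    cat(sprintf("Origin association: chi-square = %.3f, permutation p = %.4g (%d permutations)\n",
                x$statistic, x$p_value, x$n_perm))
  }
  invisible(x)
}
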