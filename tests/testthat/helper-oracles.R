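# Independent reference implementations used to validate the package's fast
# paths. Deliberately naive: plain loops and textbook formulas.

# exhaustive sliding-window regression via lm() on every window
oracle_window_fit <- function(times, od, window = 15L, stride = 1L) {
  ly <- log(od)
  starts <- seq(1L, length(od) - window + 1L, by = stride)
  best <- NULL
  for (s in starts) {
    idx <- s:(s + window - 1L)
    m <- stats::lm(ly[idx] ~ times[idx])
    sl <- unname(coef(m)[2])
    if (is.null(best) || sl > best$slope + 1e-12) {
      best <- list(slope = sl, intercept = unname(coef(m)[1]),
                   start = s, end = s + window - 1L,
                   r2 = summary(m)$r.squared)
    }
  }
  best
}

# Kruskal-Wallis H by the rank-sum formula with tie correction
oracle_kw_H <- function(x, g) {
  g <- factor(g)
  r <- rank(x)
  N <- length(x)
  rj <- tapply(r, g, sum)
  nj <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(rj^2 / nj) - 3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# brute-force UPGMA: merges tracked as item-index sets; returns heights and
# the partition after each merge (as sorted signature strings)
oracle_upgma <- function(dm) {
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      d <- mean(dm[clusters[[i]], clusters[[j]]])
      if (d < best[1] - 1e-12) best <- c(d, i, j)
    }
    merged <- sort(c(clusters[[best[2]]], clusters[[best[3]]]))
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    heights <- c(heights, best[1])
    partitions <- c(partitions, list(sort(vapply(clusters, function(cl)
      paste(sort(cl), collapse = "-"), character(1)))))
  }
  list(heights = heights, partitions = partitions)
}

# partition signature of an hclust cut at k clusters, by original item index
hclust_partition_at <- function(h, labels, k) {
  cl <- stats::cutree(h, k = k)[labels]      # back to original item order
  unname(sort(vapply(split(seq_along(cl), cl), function(ix)
    paste(sort(ix), collapse = "-"), character(1))))
}

# Kendall tau-b by explicit concordant/discordant pair enumeration
oracle_kendall_tau_b <- function(x, y) {
  n <- length(x)
  C <- D <- 0
  tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  tie_x <- table(x); tie_y <- table(y)
  n1 <- sum(tie_x * (tie_x - 1) / 2)
  n2 <- sum(tie_y * (tie_y - 1) / 2)
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

# PCA contribution ratios via an explicit eigen-decomposition
oracle_pca_contrib <- function(m, scale. = FALSE) {
  m <- scale(m, center = TRUE, scale = scale.)
  ev <- eigen(stats::cov(m), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  ev / sum(ev)
}
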