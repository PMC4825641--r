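#' Ground-truth strain and condition parameters for a synthetic study
#'
#' Draws the latent quantities the rest of the generator consumes: strain
#' metadata (genetic subgroup, geography, ecology), per-strain growth
#' parameters in the reference medium, per-condition effects, and the full
#' strain x condition table of true specific growth rate, lag time and yield.
#'
#' The parameter model is multiplicative (lognormal layers): log rate =
#' strain + condition + interaction, and the log yield layers are built
#' proportional to the log rate layers with the configured
#' `rate_yield_correlation` imposed on every layer, so the log-scale
#' correlation between true rate and true yield across the whole table equals
#' the configured value. Lag is drawn from independent layers and is
#' therefore uncorrelated with both. The interaction layer carries the
#' genotype coupling: each subgroup shares a condition-response component
#' whose magnitude grows with that subgroup's divergence from the panel
#' ancestor, scaled by `diversity_effect`, so genetically distant strains
#' have less correlated growth profiles (and `diversity_effect = 0` removes
#' the coupling).
#'
#' Reference-medium rates mimic a natural panel: one designated slow outlier
#' strain at 0.18 per hour and the rest drawn between 0.25 and 0.72 per hour.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_truth`: list with `strains` (data frame:
#'   strain, subgroup, geography, ecology), `conditions` (data frame:
#'   condition, class_group, and the latent multipliers), `params` (data
#'   frame: strain, condition, true_rate, true_lag, true_yield),
#'   `subgroup_branch` (named per-subgroup divergence from the ancestor),
#'   `strain_branch` (private divergence per strain), `outlier_strain`, and
#'   `reference_strain` (the morphology reference).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.sub_seed(config, 1L))
  ns <- config$n_strains; nc <- config$n_conditions; k <- config$n_subgroups

  strain <- sprintf("LK%02d", seq_len(ns))
  # contiguous, nearly equal subgroup blocks
  cuts <- round(seq(0, ns, length.out = k + 1))
  subgroup <- paste0("G", rep(seq_len(k), times = diff(cuts)))
  # branch lengths: per-strain private divergence plus a subgroup ladder
  # chosen so the expected maximum pairwise divergence hits the target
  p_ind <- 0.06 * config$max_divergence
  p_min <- 0.06 * config$max_divergence
  top_sum <- config$max_divergence - 2 * p_ind
  p_max <- if (k >= 2) (top_sum * (k - 1) + p_min) / (2 * (k - 1) - 1)
           else top_sum / 2
  pg <- if (k >= 2) seq(p_min, p_max, length.out = k) else p_max
  names(pg) <- paste0("G", seq_len(k))

  geography <- rep("Asia", ns)
  geography[subgroup == "G1"] <- "America"
  geography[subgroup == names(pg)[k]] <- "Europe"
  mid <- !(subgroup %in% c("G1", names(pg)[k]))
  geography[mid] <- sample(c("Europe", "America", "Asia"), sum(mid),
                           replace = TRUE, prob = c(0.35, 0.3, 0.35))
  ecology <- sample(c("tree exudate", "soil", "insect gut", "unknown"), ns,
                    replace = TRUE, prob = c(0.4, 0.25, 0.15, 0.2))
  strains <- data.frame(strain = strain, subgroup = subgroup,
                        geography = geography, ecology = ecology,
                        stringsAsFactors = FALSE)

  # reference-medium (YPD) rates: slow outlier + truncated normal panel
  outlier_strain <- strain[ns]
  r_ypd <- numeric(ns)
  for (i in seq_len(ns)) {
    repeat {
      x <- stats::rnorm(1, 0.48, 0.10)
      if (x >= 0.25 && x <= 0.72) break
    }
    r_ypd[i] <- x
  }
  r_ypd[ns] <- 0.18

  rho <- config$rate_yield_correlation
  kap <- 0.35  # log-yield layers are this fraction of the log-rate layers
  mix <- function(z, rho) rho * z + sqrt(1 - rho^2) * stats::rnorm(length(z))
  safe_sd <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s)) 0 else s
  }
  standardize <- function(v) {
    s <- safe_sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }

  # strain layer
  lr_s <- log(r_ypd)
  ly_s <- log(1.25) + kap * safe_sd(lr_s) * mix(standardize(lr_s), rho)
  ll_s <- log(2.3) + 0.15 * stats::rnorm(ns)  # lag: independent chain

  # condition layer (reference condition is the identity)
  condition <- c(config$reference_condition,
                 sprintf("C%02d", seq_len(nc - 1L) + 1L))
  class_group <- c("carbon",
                   sample(c("carbon", "environment-metabolites", "toxins"),
                          nc - 1L, replace = TRUE, prob = c(0.4, 0.3, 0.3)))
  lm_c <- pmin(pmax(stats::rnorm(nc - 1L, log(0.55), 0.8),
                    log(0.05)), log(1.15))
  lw_c <- kap * safe_sd(lm_c) * mix(standardize(lm_c), rho)
  lg_c <- log(1.1) + 0.25 * stats::rnorm(nc - 1L)
  lm_c <- c(0, lm_c); lw_c <- c(0, lw_c); lg_c <- c(0, lg_c)

  # interaction layer with genotype coupling (shared within subgroup)
  u_tot <- pg[k] + p_ind
  sigma_div <- 0.15; sigma0 <- 0.17
  Zg <- matrix(stats::rnorm(k * nc), k, nc, dimnames = list(names(pg), NULL))
  Zs <- matrix(stats::rnorm(ns * nc), ns, nc)
  W <- matrix(stats::rnorm(ns * nc), ns, nc)
  gi <- match(subgroup, names(pg))
  amp_g <- sqrt(pg / u_tot); amp_s <- sqrt(p_ind / u_tot)
  e_rate <- config$diversity_effect * sigma_div *
    (Zg[gi, , drop = FALSE] * amp_g[gi] + Zs * amp_s) + sigma0 * W
  z_e <- (e_rate - mean(e_rate)) / max(stats::sd(e_rate), 1e-12)
  e_yield <- kap * stats::sd(e_rate) *
    (rho * z_e + sqrt(1 - rho^2) * matrix(stats::rnorm(ns * nc), ns, nc))
  e_lag <- 0.10 * matrix(stats::rnorm(ns * nc), ns, nc)
  # interactions vanish in the reference column so ratios are anchored there
  e_rate[, 1] <- 0; e_yield[, 1] <- 0; e_lag[, 1] <- 0

  lrate <- outer(lr_s, lm_c, "+") + e_rate
  lyield <- outer(ly_s, lw_c, "+") + e_yield
  llag <- outer(ll_s, lg_c, "+") + e_lag

  params <- data.frame(strain = rep(strain, times = nc),
                       condition = rep(condition, each = ns),
                       true_rate = as.vector(exp(lrate)),
                       true_lag = as.vector(exp(llag)),
                       true_yield = as.vector(exp(lyield)),
                       stringsAsFactors = FALSE)

  conditions <- data.frame(condition = condition, class_group = class_group,
                           rate_multiplier = exp(lm_c),
                           yield_multiplier = exp(lw_c),
                           lag_multiplier = exp(lg_c),
                           stringsAsFactors = FALSE)

  structure(list(strains = strains, conditions = conditions, params = params,
                 subgroup_branch = pg, strain_branch = p_ind,
                 outlier_strain = outlier_strain,
                 reference_strain = strain[1]),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d strains x %d conditions (%d subgroups)\n",
              nrow(x$strains), nrow(x$conditions),
              length(unique(x$strains$subgroup))))
  cat(sprintf("  reference strain %s, slow outlier %s\n",
              x$reference_strain, x$outlier_strain))
  invisible(x)
}
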