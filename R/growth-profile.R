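#' Strain-by-condition matrix of mean fitted parameter values
#'
#' Averages replicate fits per strain and condition for one growth parameter.
#' Curves flagged `no_growth` contribute `rate = 0`, an undefined (missing)
#' lag, and a yield of 0 on the grounds that no biomass accumulated.
#'
#' @param fits A `growth_fit` table (see [fit_growth_table()]).
#' @param parameter One of `"rate"`, `"lag"`, `"yield"`.
#' @return A numeric matrix, strains in rows and conditions in columns, with
#'   a logical attribute `no_growth` marking strain x condition cells where
#'   every replicate was flagged.
#' @export
strain_parameter_matrix <- function(fits, parameter = c("rate", "lag", "yield")) {
  parameter <- match.arg(parameter)
  strains <- sort(unique(fits$strain))
  conditions <- sort(unique(fits$condition))
  val <- fits[[parameter]]
  ng <- grepl("no_growth", fits$flags)
  if (parameter == "yield") val[ng] <- 0
  m <- matrix(NA_real_, length(strains), length(conditions),
              dimnames = list(strains, conditions))
  ngm <- matrix(FALSE, length(strains), length(conditions),
                dimnames = list(strains, conditions))
  mean_tab <- tapply(val, list(fits$strain, fits$condition),
                     function(v) mean(v, na.rm = TRUE))
  ng_tab <- tapply(ng, list(fits$strain, fits$condition), all)
  m[rownames(mean_tab), colnames(mean_tab)] <- mean_tab
  ngm[rownames(ng_tab), colnames(ng_tab)] <- ng_tab %in% TRUE
  m[is.nan(m)] <- NA_real_
  attr(m, "no_growth") <- ngm
  attr(m, "parameter") <- parameter
  m
}

#' Normalize growth fits to a reference condition
#'
#' Replicate fits are first averaged per strain x condition; each strain's
#' mean value in every condition is then divided by that strain's mean value
#' in the reference medium, so the reference column is identically 1 and a
#' ratio of 1 means "no change relative to the reference". Strain x condition
#' cells where no replicate grew get a ratio of 0 for rate and yield and a
#' missing lag; strains whose reference culture did not grow are set entirely
#' to missing with a warning.
#'
#' @inheritParams strain_parameter_matrix
#' @param reference_condition Identifier of the reference medium
#'   (default `"YPD"`).
#' @return A `trait_profile` matrix (strains x conditions) of ratios, with
#'   attributes `parameter` and `reference`.
#' @examples
#' # a strain growing at 0.3/hr in a condition and 0.6/hr in the reference
#' # gets a ratio of 0.5 in that condition
#' @export
normalize_to_reference <- function(fits, reference_condition = "YPD",
                                   parameter = c("rate", "lag", "yield")) {
  parameter <- match.arg(parameter)
  m <- strain_parameter_matrix(fits, parameter)
  if (!reference_condition %in% colnames(m))
    stop(sprintf("no fits for reference condition '%s'", reference_condition))
  ngm <- attr(m, "no_growth")
  ref <- m[, reference_condition]
  ref_ng <- ngm[, reference_condition]
  if (any(is.na(ref) & !ref_ng))
    stop("some strains lack a reference-condition fit: ",
         paste(rownames(m)[is.na(ref) & !ref_ng], collapse = ", "))
  bad_ref <- ref_ng | is.na(ref)
  zero_ref <- !bad_ref & ref == 0
  if (any(zero_ref))
    stop("reference value is 0 without a no_growth flag for: ",
         paste(rownames(m)[zero_ref], collapse = ", "))
  prof <- sweep(m, 1, ref, "/")
  if (parameter %in% c("rate", "yield")) {
    prof[ngm] <- 0
  } else {
    prof[ngm] <- NA_real_
  }
  prof[, reference_condition] <- 1
  if (any(bad_ref)) {
    warning("reference culture flagged no_growth; strain(s) set to missing: ",
            paste(rownames(m)[bad_ref], collapse = ", "))
    prof[bad_ref, ] <- NA_real_
  }
  structure(prof, parameter = parameter, reference = reference_condition,
            no_growth = NULL, class = c("trait_profile", "matrix", "array"))
}

#' Classify conditions by median resistance
#'
#' Summarizes a normalized strain-by-condition profile per condition: the
#' median ratio across strains, the across-strain sample variance, and a
#' resistance class with boundaries median < 0.3 (low), 0.3 to 0.8 inclusive
#' (mid), and > 0.8 (high). Conditions are returned ranked by median.
#'
#' @param profile A `trait_profile` matrix from [normalize_to_reference()].
#' @param condition_groups Optional named character vector mapping condition
#'   identifiers to categories (e.g. carbon / environment-metabolites /
#'   toxins); carried through to the output.
#' @param max_missing Conditions with a larger fraction of missing strains
#'   are dropped with a warning (default 0.5).
#' @return Data frame with columns `condition`, `median_ratio`, `variance`,
#'   `resistance_class`, `class_group`, ordered by increasing median.
#' @export
classify_condition_resistance <- function(profile, condition_groups = NULL,
                                          max_missing = 0.5) {
  miss <- colMeans(is.na(profile))
  if (any(miss >= max_missing)) {
    warning("dropping conditions with >= ", max_missing * 100,
            "% missing strains: ",
            paste(colnames(profile)[miss >= max_missing], collapse = ", "))
    profile <- profile[, miss < max_missing, drop = FALSE]
  }
  med <- apply(profile, 2, stats::median, na.rm = TRUE)
  v <- apply(profile, 2, stats::var, na.rm = TRUE)
  cls <- ifelse(med < 0.3, "low", ifelse(med <= 0.8, "mid", "high"))
  out <- data.frame(condition = colnames(profile), median_ratio = med,
                    variance = v, resistance_class = cls,
                    class_group = if (is.null(condition_groups)) NA_character_
                                  else unname(condition_groups[colnames(profile)]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$median_ratio), ]
  rownames(out) <- NULL
  out
}

#' Per-condition variance and leave-one-out strain contributions
#'
#' Computes the across-strain sample variance of a strain-by-condition value
#' matrix per condition, and optionally the contribution of each strain to
#' each condition's variance as `(Var_all - Var_without_strain) / Var_all` --
#' the fraction of the variance explained by that strain. The overall growth
#' phenotypic variance is the average of the per-condition variances.
#'
#' @param profile A strain-by-condition numeric matrix (normalized ratios or
#'   raw parameter values).
#' @param leave_one_out If `TRUE`, also compute per-strain contributions.
#' @return A list with `condition_variance` (data frame: condition,
#'   variance), `overall_variance` (mean of per-condition variances), and,
#'   when requested, `contribution` (strain x condition matrix; missing where
#'   the full variance is 0).
#' @export
condition_variance_profile <- function(profile, leave_one_out = FALSE) {
  if (nrow(profile) < 3L) stop("need at least 3 strains")
  v <- apply(profile, 2, stats::var, na.rm = TRUE)
  out <- list(condition_variance = data.frame(condition = colnames(profile),
                                              variance = unname(v),
                                              stringsAsFactors = FALSE),
              overall_variance = mean(v, na.rm = TRUE))
  if (leave_one_out) {
    contrib <- matrix(NA_real_, nrow(profile), ncol(profile),
                      dimnames = dimnames(profile))
    for (s in seq_len(nrow(profile))) {
      v_wo <- apply(profile[-s, , drop = FALSE], 2, stats::var, na.rm = TRUE)
      contrib[s, ] <- (v - v_wo) / v
    }
    contrib[, v == 0 | is.na(v)] <- NA_real_
    out$contribution <- contrib
  }
  out
}
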