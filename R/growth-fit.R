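#' Construct a growth curve
#'
#' A growth curve is one well's background-uncorrected OD time series together
#' with its identity (strain, condition, replicate) and an optional blank
#' (medium-only) reading.
#'
#' @param strain,condition Identifiers.
#' @param replicate Replicate index.
#' @param times Time points in hours, strictly increasing.
#' @param od Optical density readings (same length as `times`), nonnegative.
#' @param blank Optional blank OD, either a single value or one per time
#'   point.
#' @return An object of class `growth_curve`.
#' @examples
#' gc <- growth_curve("S1", "YPD", 1, times = 0:25 / 2, od = 0.1 * exp(0:25 / 8))
#' @export
growth_curve <- function(strain, condition, replicate, times, od, blank = NULL) {
  times <- as.numeric(times)
  od <- as.numeric(od)
  if (length(times) != length(od))
    stop("times and od must have the same length")
  if (length(times) < 2L) stop("a growth curve needs at least 2 points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(od)) || any(od < 0))
    stop("od must be finite and nonnegative")
  if (!is.null(blank)) {
    if (!length(blank) %in% c(1L, length(od)))
      stop("blank must be length 1 or length(od)")
    blank <- as.numeric(blank)
  }
  structure(list(strain = as.character(strain),
                 condition = as.character(condition),
                 replicate = replicate,
                 times = times, od = od, blank = blank,
                 corrected = FALSE, correction = NULL),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("Growth curve %s / %s / rep %s: %d points over %.1f hr%s\n",
              x$strain, x$condition, as.character(x$replicate),
              length(x$times), max(x$times) - min(x$times),
              if (isTRUE(x$corrected)) sprintf(" (corrected: %s)", x$correction)
              else ""))
  invisible(x)
}

#' Background-correct an OD curve
#'
#' Subtracts the blank reading when one is available, otherwise the minimum of
#' the first five readings, then clamps the corrected series below at
#' `epsilon` so that logarithms exist everywhere. The method used is recorded
#' on the returned curve.
#'
#' @param curve A [growth_curve()].
#' @param epsilon Lower clamp for the corrected OD, in OD units
#'   (default 0.01).
#' @return The corrected `growth_curve`; `$correction` records the method and
#'   `$clamped_fraction` the fraction of points that hit the clamp. If every
#'   point was clamped (e.g. a blank larger than all readings) a warning is
#'   raised and the `all_clamped` flag is set.
#' @examples
#' gc <- growth_curve("S1", "YPD", 1, times = 0:3, od = c(0.10, 0.10, 0.50, 1.00))
#' correct_background(gc)$od  # 0.01 0.01 0.40 0.90
#' @export
correct_background <- function(curve, epsilon = 0.01) {
  stopifnot(inherits(curve, "growth_curve"))
  if (epsilon <= 0) stop("epsilon must be positive")
  if (!is.null(curve$blank)) {
    odc <- curve$od - curve$blank
    method <- "blank"
  } else {
    k <- min(5L, length(curve$od))
    odc <- curve$od - min(curve$od[seq_len(k)])
    method <- "min_first5"
  }
  clamped <- odc < epsilon
  odc[clamped] <- epsilon
  curve$od <- odc
  curve$corrected <- TRUE
  curve$correction <- method
  curve$clamped_fraction <- mean(clamped)
  curve$all_clamped <- all(clamped)
  if (curve$all_clamped)
    warning(sprintf("curve %s/%s/rep %s: all points clamped at epsilon",
                    curve$strain, curve$condition, as.character(curve$replicate)))
  curve
}

# Sliding-window OLS of y on t over windows of `window` consecutive points
# advanced by `stride`. Cumulative-sum formulation, O(n); t and y are centered
# globally first to keep the normal-equation differences well conditioned.
# Returns per-window slope, intercept (original coordinates) and r-squared.
# Zero-variance-in-y windows get slope 0 and r2 0 by convention.
.window_regression <- function(t, y, window, stride = 1L) {
  n <- length(t)
  if (length(y) != n) stop("t and y must have the same length")
  if (window > n) stop("fewer points than the regression window")
  if (window < 2L) stop("window must be >= 2")
  tc <- t - mean(t); yc <- y - mean(y)
  cs <- function(v) cumsum(c(0, v))
  St <- cs(tc); Sy <- cs(yc); Stt <- cs(tc * tc)
  Sty <- cs(tc * yc); Syy <- cs(yc * yc)
  starts <- seq.int(1L, n - window + 1L, by = stride)
  ends <- starts + window - 1L
  w <- as.numeric(window)
  st <- St[ends + 1L] - St[starts]
  sy <- Sy[ends + 1L] - Sy[starts]
  stt <- Stt[ends + 1L] - Stt[starts]
  sty <- Sty[ends + 1L] - Sty[starts]
  syy <- Syy[ends + 1L] - Syy[starts]
  vart <- stt - st * st / w
  vary <- syy - sy * sy / w
  covty <- sty - st * sy / w
  slope <- covty / vart
  r2 <- ifelse(vary > 0, (covty * covty) / (vart * vary), 0)
  flat <- vary <= .Machine$double.eps * w
  slope[flat] <- 0
  r2[flat] <- 0
  icept_c <- sy / w - slope * st / w               # centered coordinates
  intercept <- icept_c + mean(y) - slope * mean(t) # back to original
  data.frame(start = starts, end = ends, slope = slope,
             intercept = intercept, r_squared = pmin(pmax(r2, 0), 1))
}

#' Extract growth parameters from one background-corrected curve
#'
#' Implements the sliding-window maximum-regression estimator: an ordinary
#' least-squares line of ln(OD) on time is fitted in every window of `window`
#' consecutive readings (advanced by `stride` points), the specific growth
#' rate is the maximum slope over all windows (earliest window on ties), the
#' lag time is where that regression line meets the baseline log-absorbance
#' level (the median of the first five corrected readings), and the yield is
#' the maximal corrected OD reached over the whole cultivation.
#'
#' @param curve A background-corrected [growth_curve()] (see
#'   [correct_background()]); all OD values must be positive.
#' @param window Number of consecutive readings per regression window
#'   (default 15).
#' @param stride Window advance in points (default 1). `stride = 10`
#'   reproduces a coarser non-overlapping reading of the sliding window.
#' @param min_r2 Windows whose best fit falls below this r-squared are flagged
#'   `poor_fit` (default 0.95).
#' @param min_rate Maximum slopes below this value (per hour) are treated as
#'   no growth: the rate is set to 0 and the lag is undefined (default 0.01).
#' @param clamp_negative_lag If `TRUE` (default) negative lag estimates are
#'   clamped to 0 and flagged `negative_lag_clamped`.
#' @return A one-row data frame of class `growth_fit`: `strain`, `condition`,
#'   `replicate`, `rate` (per hour), `lag` (hours, `NA` when no growth),
#'   `yield` (OD units), `window_start`, `window_end`, `r_squared`,
#'   `baseline`, and `flags` (comma-separated among `no_growth`, `poor_fit`,
#'   `negative_lag_clamped`, or empty).
#' @examples
#' tt <- seq(0, 10, by = 1 / 6)
#' gc <- growth_curve("S1", "YPD", 1, tt, 0.05 * exp(0.4 * tt))
#' gc$corrected <- TRUE  # already on the corrected scale
#' fit_growth_parameters(gc)$rate  # 0.4
#' @export
fit_growth_parameters <- function(curve, window = 15L, stride = 1L,
                                  min_r2 = 0.95, min_rate = 0.01,
                                  clamp_negative_lag = TRUE) {
  stopifnot(inherits(curve, "growth_curve"))
  if (any(curve$od <= 0))
    stop("nonpositive OD: background-correct the curve first (epsilon clamp)")
  if (length(curve$od) < window)
    stop(sprintf("curve %s/%s has fewer points (%d) than the window (%d)",
                 curve$strain, curve$condition, length(curve$od), window))
  wr <- .window_regression(curve$times, log(curve$od), window, stride)
  best <- which.max(wr$slope)  # which.max takes the earliest on exact ties
  rate <- wr$slope[best]
  r2 <- wr$r_squared[best]
  k <- min(5L, length(curve$od))
  baseline <- stats::median(curve$od[seq_len(k)])
  flags <- character(0)
  if (rate < min_rate) {
    flags <- c(flags, "no_growth")
    rate <- 0
    lag <- NA_real_
  } else {
    lag <- (log(baseline) - wr$intercept[best]) / rate
    if (clamp_negative_lag && lag < 0) {
      flags <- c(flags, "negative_lag_clamped")
      lag <- 0
    }
  }
  if (r2 < min_r2) flags <- c(flags, "poor_fit")
  out <- data.frame(strain = curve$strain, condition = curve$condition,
                    replicate = curve$replicate, rate = rate, lag = lag,
                    yield = max(curve$od), window_start = wr$start[best],
                    window_end = wr$end[best], r_squared = r2,
                    baseline = baseline,
                    flags = paste(flags, collapse = ","),
                    stringsAsFactors = FALSE)
  class(out) <- c("growth_fit", class(out))
  out
}

#' Fit growth parameters for every curve of a plate table
#'
#' Applies [correct_background()] and [fit_growth_parameters()] to each
#' (strain, condition, replicate) series of a long-format plate table.
#'
#' @param plate Data frame with columns `strain`, `condition`, `replicate`,
#'   `time_hr`, `od` and optionally `blank` (see [read_plate_table()]).
#' @param epsilon Clamp passed to [correct_background()].
#' @inheritParams fit_growth_parameters
#' @return A `growth_fit` data frame with one row per curve.
#' @export
fit_growth_table <- function(plate, window = 15L, stride = 1L, min_r2 = 0.95,
                             min_rate = 0.01, epsilon = 0.01,
                             clamp_negative_lag = TRUE) {
  req <- c("strain", "condition", "replicate", "time_hr", "od")
  if (!all(req %in% names(plate)))
    stop("plate table must have columns: ", paste(req, collapse = ", "))
  key <- interaction(plate$strain, plate$condition, plate$replicate,
                     drop = TRUE, lex.order = TRUE)
  fits <- lapply(split(seq_len(nrow(plate)), key), function(idx) {
    sub <- plate[idx, ]
    sub <- sub[order(sub$time_hr), ]
    gc <- growth_curve(sub$strain[1], sub$condition[1], sub$replicate[1],
                       sub$time_hr, sub$od,
                       blank = if ("blank" %in% names(sub)) sub$blank else NULL)
    fit_growth_parameters(correct_background(gc, epsilon), window = window,
                          stride = stride, min_r2 = min_r2,
                          min_rate = min_rate,
                          clamp_negative_lag = clamp_negative_lag)
  })
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  class(out) <- c("growth_fit", class(out))
  out
}

#' Population doubling time from a specific growth rate
#'
#' @param rate Specific growth rate in per-hour units; must be positive.
#' @return Doubling time in hours, `log(2) / rate`.
#' @examples
#' doubling_time(log(2))  # 1 hour
#' @export
doubling_time <- function(rate) {
  if (any(!is.finite(rate)) || any(rate <= 0))
    stop("doubling time is undefined for rate <= 0")
  log(2) / rate
}
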