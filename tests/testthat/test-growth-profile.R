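# Reference normalization, resistance classification, variance profiles

fits_row <- function(strain, condition, replicate, rate, lag = 2, yield = 1,
                     flags = "") {
  data.frame(strain = strain, condition = condition, replicate = replicate,
             rate = rate, lag = lag, yield = yield, window_start = 1L,
             window_end = 15L, r_squared = 0.99, baseline = 0.05,
             flags = flags, stringsAsFactors = FALSE)
}

test_that("normalization divides strain means by the strain's reference value", {
  fits <- rbind(fits_row("a", "YPD", 1, 0.6), fits_row("a", "YPD", 2, 0.6),
                fits_row("a", "X", 1, 0.3), fits_row("a", "X", 2, 0.3),
                fits_row("b", "YPD", 1, 0.4), fits_row("b", "X", 1, 0.5))
  prof <- normalize_to_reference(fits, "YPD", "rate")
  expect_equal(prof["a", "X"], 0.5)
  expect_equal(prof["b", "X"], 1.25)
  expect_equal(unname(prof[, "YPD"]), c(1, 1))
})

test_that("replicates are averaged before forming ratios", {
  fits <- rbind(fits_row("a", "YPD", 1, 0.5), fits_row("a", "YPD", 2, 0.7),
                fits_row("a", "X", 1, 0.2), fits_row("a", "X", 2, 0.4))
  prof <- normalize_to_reference(fits, "YPD", "rate")
  expect_equal(prof["a", "X"], 0.3 / 0.6)
})

test_that("no-growth handling: zero ratio for rate/yield, missing lag, missing strain when reference fails", {
  fits <- rbind(fits_row("a", "YPD", 1, 0.5),
                fits_row("a", "X", 1, 0, flags = "no_growth"),
                fits_row("b", "YPD", 1, 0, flags = "no_growth"),
                fits_row("b", "X", 1, 0.3))
  expect_warning(prof <- normalize_to_reference(fits, "YPD", "rate"),
                 "no_growth")
  expect_equal(prof["a", "X"], 0)
  expect_true(all(is.na(prof["b", ])))
  expect_warning(lagp <- normalize_to_reference(fits, "YPD", "lag"))
  expect_true(is.na(lagp["a", "X"]))
})

test_that("normalizing an already-normalized profile is the identity", {
  fits <- cached_default_fits()
  prof <- normalize_to_reference(fits, "YPD", "rate")
  # re-normalize: build a fits table from the profile values
  again <- data.frame(strain = rep(rownames(prof), ncol(prof)),
                      condition = rep(colnames(prof), each = nrow(prof)),
                      replicate = 1L, rate = as.vector(prof), lag = 1,
                      yield = 1, window_start = 1L, window_end = 15L,
                      r_squared = 0.99, baseline = 0.05, flags = "",
                      stringsAsFactors = FALSE)
  again <- again[!is.na(again$rate) & again$rate > 0, ]
  prof2 <- normalize_to_reference(again, "YPD", "rate")
  for (s in rownames(prof2)) for (cc in colnames(prof2)) {
    v1 <- prof[s, cc]
    if (!is.na(v1) && v1 > 0)
      expect_equal(prof2[s, cc], v1, tolerance = 1e-12)
  }
})

test_that("missing reference fits raise an error naming strains", {
  fits <- rbind(fits_row("a", "YPD", 1, 0.5), fits_row("b", "X", 1, 0.3))
  expect_error(normalize_to_reference(fits, "YPD", "rate"), "b")
})

test_that("resistance classes follow the 0.3/0.8 median boundaries", {
  prof <- structure(cbind(YPD = rep(1, 5),
                          lo = rep(0.25, 5), edge = rep(0.30, 5),
                          mid = rep(0.8, 5), hi = rep(0.81, 5)),
                    dimnames = list(paste0("s", 1:5),
                                    c("YPD", "lo", "edge", "mid", "hi")))
  res <- classify_condition_resistance(prof)
  cls <- setNames(res$resistance_class, res$condition)
  expect_equal(unname(cls[c("lo", "edge", "mid", "hi", "YPD")]),
               c("low", "mid", "mid", "high", "high"))
  expect_equal(res$condition, res$condition[order(res$median_ratio)])
  expect_equal(res$variance[res$condition == "YPD"], 0)
})

test_that("leave-one-out variance contributions match direct recomputation", {
  prof <- cbind(c1 = c(1, 1, 1, 0.2), c2 = c(0.5, 0.7, 0.9, 1.1))
  rownames(prof) <- paste0("s", 1:4)
  vp <- condition_variance_profile(prof, leave_one_out = TRUE)
  expect_equal(vp$condition_variance$variance,
               unname(apply(prof, 2, var)))
  for (s in 1:4) for (cc in 1:2) {
    direct <- (var(prof[, cc]) - var(prof[-s, cc])) / var(prof[, cc])
    expect_equal(vp$contribution[s, cc], direct)
  }
  expect_equal(vp$overall_variance, mean(apply(prof, 2, var)))
})

test_that("zero-variance conditions report missing contributions", {
  prof <- cbind(c1 = rep(1, 4), c2 = 1:4)
  rownames(prof) <- paste0("s", 1:4)
  vp <- condition_variance_profile(prof, leave_one_out = TRUE)
  expect_equal(vp$condition_variance$variance[1], 0)
  expect_true(all(is.na(vp$contribution[, "c1"])))
})

test_that("an engineered slow outlier explains roughly half the variance", {
  set.seed(21)
  vals <- c(rnorm(26, 1, 0.09), 0.45)   # one strain far below the pack
  prof <- cbind(cond = vals)
  rownames(prof) <- paste0("s", 1:27)
  vp <- condition_variance_profile(prof, leave_one_out = TRUE)
  expect_gt(vp$contribution[27, 1], 0.4)
  expect_lt(vp$contribution[27, 1], 0.6)
  expect_equal(which.max(vp$contribution[, 1]), c(s27 = 27L))
})
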