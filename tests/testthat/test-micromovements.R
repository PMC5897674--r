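test_that("extrema of a sinusoid alternate and exclude boundaries", {
  ts <- timeseries(sin(2 * pi * (0:199) / 100), fs = 100)
  pt <- detect_extrema(ts)
  expect_length(pt$peak_idx, 2)
  expect_true(length(pt$valley_idx) %in% 1:2)
  ext <- sort(c(pt$peak_idx, pt$valley_idx))
  kinds <- ifelse(ext %in% pt$peak_idx, "max", "min")
  expect_true(all(kinds[-1] != kinds[-length(kinds)]))  # strict alternation
  expect_false(1 %in% ext || length(ts) %in% ext)
})

test_that("monotone ramps and short series yield no extrema", {
  expect_length(detect_extrema(timeseries(1:50, fs = 10))$peak_idx, 0)
  expect_error(detect_extrema(timeseries(c(1, 2), fs = 10)), "3 samples")
})

test_that("plateaus contribute their first sample", {
  ts <- timeseries(c(0, 1, 2, 2, 2, 1, 0), fs = 10)
  pt <- detect_extrema(ts)
  expect_equal(pt$peak_idx, 3L)
})

test_that("detection matches the brute-force sliding-window oracle", {
  set.seed(17)
  for (rep in 1:5) {
    v <- cumsum(rnorm(400))
    pt <- detect_extrema(timeseries(v, fs = 100))
    expect_equal(pt$peak_idx, brute_force_peaks(v, w = 1))
  }
})

test_that("planted bumps are recovered at their exact indices", {
  sim <- fixture_session(seed = 7, n_trials = 4)
  tr1 <- sim$ground_truth$trials[[1]]
  acc <- sim$session$channels$ang_rate
  # differentiate the stored angular rate back to acceleration
  accel <- timeseries(abs(differentiate(acc)$v), t = acc$t, fs = acc$fs)
  pt <- detect_extrema(accel, min_prominence = 1)
  for (idx in tr1$peak_idx)
    expect_true(min(abs(pt$peak_idx - idx)) <= 1)
})

test_that("prominence pruning removes sub-threshold wiggles only", {
  v <- c(0, 5, 0.2, 0.4, 0.2, 5, 0, 5, 0)
  pt0 <- detect_extrema(timeseries(v, fs = 10), min_prominence = 0)
  pt1 <- detect_extrema(timeseries(v, fs = 10), min_prominence = 1)
  expect_length(pt0$peak_idx, 4)
  expect_length(pt1$peak_idx, 3)
  expect_false(4 %in% pt1$peak_idx)
})

test_that("AM normalization matches hand arithmetic and stays in (0,1)", {
  # interior peak 3 with window [1,2,3,2,1]: flank average 1.8
  ts <- timeseries(c(2, 1, 2, 3, 2, 1, 2), fs = 10)
  pt <- detect_extrema(ts)
  am <- compute_am(pt)
  expect_equal(am$values, 3 / (3 + 1.8))
  expect_equal(am$raw_values, 3)
  expect_true(all(am$values > 0 & am$values < 1))
  expect_equal(am$raw_median, median(am$raw_values))
})

test_that("AM equals 0.5 when the peak equals its flanking average", {
  # flat-but-for-dip window is impossible with a strict peak, so check
  # the algebraic midpoint via the formula path on a constructed train
  pt <- structure(list(peak_idx = 2L, valley_idx = c(1L, 3L),
                       peak_amp = 2, flank_avg = 2, peak_times = 0.1,
                       units = "", fs = 10), class = "peak_train")
  expect_equal(compute_am(pt)$values, 0.5)
})

test_that("AM is scale-invariant and decreasing in the flanking average", {
  sim <- fixture_session(seed = 11, n_trials = 3)
  acc <- sim$session$channels$ang_rate
  accel <- timeseries(abs(differentiate(acc)$v), t = acc$t, fs = acc$fs)
  am1 <- compute_am(detect_extrema(accel, min_prominence = 1))
  scaled <- timeseries(7.3 * accel$v, t = acc$t, fs = acc$fs)
  am2 <- compute_am(detect_extrema(scaled, min_prominence = 7.3))
  expect_equal(am2$values, am1$values, tolerance = 1e-12)
  # monotonicity in the denominator
  p <- 3; flanks <- seq(0.5, 2.9, by = 0.2)
  vals <- p / (p + flanks)
  expect_true(all(diff(vals) < 0))
})

test_that("AM rejects negative-valued waveforms and drops zero denominators", {
  ts <- timeseries(c(0, -1, 2, -1, 0, 1, -2), fs = 10)
  expect_error(compute_am(detect_extrema(ts)), "non-negative")
  pt <- structure(list(peak_idx = c(2L, 4L), valley_idx = c(1L, 3L, 5L),
                       peak_amp = c(0, 2), flank_avg = c(0, 1),
                       peak_times = c(0.1, 0.3), units = "", fs = 10),
                  class = "peak_train")
  expect_warning(am <- compute_am(pt), "zero denominator")
  expect_length(am$values, 1)
})

test_that("TM is the consecutive peak-time differences", {
  pt <- structure(list(peak_idx = c(5L, 10L, 18L), valley_idx = c(3L, 7L, 14L, 20L),
                       peak_amp = c(1, 2, 1.5), flank_avg = c(0.5, 0.6, 0.7),
                       peak_times = c(0.5, 1.0, 1.75), units = "", fs = 10),
                  class = "peak_train")
  expect_equal(as.numeric(compute_tm(pt)), c(0.5, 0.75))
  one <- structure(list(peak_idx = 5L, valley_idx = integer(0),
                        peak_amp = 1, flank_avg = NA_real_, peak_times = 0.5,
                        units = "", fs = 10), class = "peak_train")
  expect_warning(tm <- compute_tm(one), "fewer than 2")
  expect_length(tm, 0)
})

test_that("NTM series_minima matches hand arithmetic on [1,3,1]", {
  ntm <- compute_ntm(c(1, 3, 1))
  expect_equal(ntm$values, 0.75)
  expect_equal(ntm$raw_values, 3)
})

test_that("NTM global_mean gives 0.5 on constant intervals", {
  expect_equal(compute_ntm(rep(0.37, 6), mode = "global_mean")$values,
               rep(0.5, 6))
})

test_that("constant TM under series_minima is empty with a warning", {
  expect_warning(ntm <- compute_ntm(rep(1, 5)), "no interior TM maxima")
  expect_length(ntm$values, 0)
})

test_that("NTM is scale-invariant in both modes", {
  set.seed(4)
  tm <- rgamma(50, 4, scale = 0.05)
  for (mode in c("series_minima", "global_mean")) {
    a <- compute_ntm(tm, mode = mode)
    b <- compute_ntm(tm * 3.7, mode = mode)
    expect_equal(b$values, a$values, tolerance = 1e-12)
  }
})

test_that("micro-movement CSV export has the documented columns", {
  am <- compute_am(detect_extrema(timeseries(c(2, 1, 2, 3, 2, 1, 2), fs = 10)))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_micromovements_csv(am, tmp)
  df <- read.csv(tmp)
  expect_named(df, c("peak_time_s", "raw_value", "mm_value", "kind", "units"))
  expect_equal(df$mm_value, am$values)
})
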