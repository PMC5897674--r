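test_that("smoothing differentiation is exact on polynomials", {
  t <- seq(0, 1, by = 1 / 240)
  d2 <- differentiate(differentiate(timeseries(t^2, t = t)))
  expect_lt(max(abs(d2$v[15:227] - 2)), 1e-6)
  # closed-form sinusoid derivative, interior within 0.1%
  s <- timeseries(sin(2 * pi * t), t = t)
  ds <- differentiate(s)
  rel <- max(abs(ds$v[30:210] - 2 * pi * cos(2 * pi * t[30:210]))) / (2 * pi)
  expect_lt(rel, 1e-3)
})

test_that("smoothed derivative is quieter than the naive difference", {
  set.seed(9)
  t <- (0:999) / 240
  noise <- rnorm(1000)
  smooth <- differentiate(timeseries(noise, t = t))$v
  naive <- diff(noise) * 240
  expect_lt(var(smooth[11:990]), var(naive))
})

test_that("differentiation argument contract", {
  ts <- timeseries(rnorm(100), fs = 240)
  expect_error(differentiate(ts, smooth_window = 20), "odd")
  expect_error(differentiate(ts, smooth_window = 3, poly_order = 3),
               "poly_order")
  expect_error(differentiate(ts, smooth_window = 201), "longer")
})

test_that("speed is the norm of the velocity (3-4-5 check)", {
  t <- (0:499) / 240
  traj <- trajectory(t, cbind(3 * t, 4 * t, 0 * t))
  sp <- compute_speed(traj)
  expect_equal(sp$v[50:450], rep(5, 401), tolerance = 1e-9)
  still <- trajectory(t, cbind(t * 0 + 1, t * 0, t * 0))
  expect_equal(max(compute_speed(still)$v), 0, tolerance = 1e-12)
})

test_that("angular acceleration has closed-form amplitude for a sinusoid", {
  t <- (0:2399) / 240
  A <- 50; f <- 3
  traj <- trajectory(t, cbind(t, t, t), ang_rate = A + A * sin(2 * pi * f * t))
  acc <- compute_angular_acceleration(traj)
  expect_equal(max(acc$v[100:2300]), 2 * pi * f * A, tolerance = 0.01 * 2 * pi * f * A)
  # constant rate -> zero acceleration
  flatr <- trajectory(t, cbind(t, t, t), ang_rate = rep(30, length(t)))
  expect_lt(max(compute_angular_acceleration(flatr)$v), 1e-9)
  expect_error(compute_angular_acceleration(trajectory(t, cbind(t, t, t))),
               "angular-rate")
})

test_that("minimum-jerk reaches have a single interior speed maximum", {
  sim <- fixture_session(seed = 2, n_trials = 1)
  ex <- suppressWarnings(extract_session(sim$session, min_prominence = 1))
  seg <- ex$segments[[1]]$forward
  sp <- ex$speed$v[seg$start:(seg$end - 1)]
  pk <- brute_force_peaks(sp, w = length(sp))
  expect_length(pk, 1)
})

test_that("trials split at the planted touch sample and partition cleanly", {
  sim <- fixture_session(seed = 5, n_trials = 8)
  ex <- suppressWarnings(extract_session(sim$session, min_prominence = 1))
  for (k in 1:8) {
    seg <- ex$segments[[k]]
    truth <- sim$ground_truth$trials[[k]]
    expect_lte(abs(seg$forward$end - truth$split_idx), 1)
    # half-open partition: forward ends where backward starts
    expect_identical(seg$forward$end, seg$backward$start)
    expect_gt(seg$forward$movement_time, 0)
    expect_gt(seg$backward$movement_time, 0)
    # speed at the split is near zero relative to the trial peak
    sp <- ex$speed$v
    win <- seg$forward$start:(seg$backward$end - 1)
    expect_lt(sp[seg$forward$end] / max(sp[win]), 0.05)
  }
})

test_that("time-reversing an out-and-back trial mirrors the segments", {
  sim <- fixture_session(seed = 13, n_trials = 1)
  ch <- sim$session$channels
  n <- length(ch$pos_x$v)
  t <- ch$pos_x$t
  fwd_traj <- trajectory(t, cbind(ch$pos_x$v, ch$pos_y$v, ch$pos_z$v))
  rev_traj <- trajectory(t, cbind(rev(ch$pos_x$v), rev(ch$pos_y$v),
                                  rev(ch$pos_z$v)))
  tr <- sim$session$trials[[1]]
  sg_f <- segment_trial(fwd_traj, tr, c(12, 30.5, 22))
  # reversed trial: events mirrored around the recording
  tr_rev <- trial_record(0, "control",
                         list(prompt = t[n] - tr$event_times$response))
  sg_r <- segment_trial(rev_traj, tr_rev, c(12, 30.5, 22))
  expect_equal(n + 1 - sg_r$backward$start, sg_f$forward$end, tolerance = 2)
  expect_equal(sg_r$backward$end - sg_r$backward$start,
               sg_f$forward$end - sg_f$forward$start, tolerance = 15)
})

test_that("an edge distance minimum raises a segmentation error", {
  t <- (0:499) / 240
  # hand approaches but never reaches the target: minimum at window edge
  traj <- trajectory(t, cbind(t, 2 * t, t))
  tr <- trial_record(0, "control", list(prompt = 0.05))
  expect_error(segment_trial(traj, tr, c(12, 30.5, 22)), "window edge")
})

test_that("behavioral metrics match events and planted peak counts", {
  sim <- fixture_session(seed = 5, n_trials = 12)
  ex <- suppressWarnings(extract_session(sim$session, min_prominence = 1))
  m <- ex$metrics
  for (k in 1:12) {
    tr <- sim$session$trials[[k]]
    truth <- sim$ground_truth$trials[[k]]
    expect_equal(m$movement_time[k],
                 tr$event_times$touch - tr$event_times$prompt)
    expect_equal(m$n_accel_peaks_forward[k] + m$n_accel_peaks_backward[k],
                 truth$n_peaks)
  }
  # control condition has no slider response
  expect_true(all(is.na(m$time_estimation_error)))
  # reordering trials leaves per-trial metrics unchanged
  perm <- c(4, 1, 3, 2, 5:12)
  sess2 <- session_record(sim$session$participant_id, sim$session$condition,
                          sim$session$trials[perm], sim$session$channels)
  m2 <- behavioral_metrics(sess2, ex$segments[perm], ex$accel,
                           min_prominence = 1)
  expect_equal(m2$movement_time, m$movement_time[perm])
  expect_equal(m2$n_accel_peaks_forward, m$n_accel_peaks_forward[perm])
})

test_that("time-estimation error maps the slider to seconds", {
  sim <- simulate_pointing_session(condition = "time_estimation",
                                   n_trials = 6, seed = 19)
  ex <- suppressWarnings(extract_session(sim$session, min_prominence = 1))
  m <- ex$metrics
  for (k in 1:6) {
    tr <- sim$session$trials[[k]]
    expect_equal(m$time_estimation_error[k],
                 abs(tr$response_value * 1.0 - tr$tone_delay))
  }
})

test_that("paired t test matches stats::t.test and guards degeneracy", {
  a <- c(1.42, 1.31, 1.55, 1.2, 1.48, 1.6, 1.33, 1.51, 1.45)  # n = 9
  b <- c(1.31, 1.25, 1.40, 1.22, 1.35, 1.49, 1.30, 1.38, 1.39)
  res <- paired_condition_test(a, b)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$df, unname(ref$parameter))
  expect_equal(res$p, ref$p.value)
  expect_equal(res$df, 8)                  # nine participants -> df 8
  same <- paired_condition_test(a, a)
  expect_true(same$degenerate)
  shift <- paired_condition_test(c(1, 2, 3), c(2, 3, 4))
  expect_true(shift$degenerate)            # zero-variance differences
})

test_that("trajectory CSV reader accepts scalar and 3-axis angular rate", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  t <- (0:99) / 240
  df <- data.frame(time_s = t, x = t, y = 2 * t, z = 0, w = sin(t))
  write.csv(df, tmp, row.names = FALSE)
  tr <- read_trajectory_csv(tmp)
  expect_equal(ncol(tr$ang_rate), 1)
  df$w <- NULL
  write.csv(df, tmp, row.names = FALSE)
  expect_null(read_trajectory_csv(tmp)$ang_rate)
})
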