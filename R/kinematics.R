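#' Smoothing differentiation of a sampled signal
#'
#' Numerical differentiation of position/orientation traces amplifies
#' instrumentation noise, and the effect grows with derivative order.
#' This routine therefore couples smoothing and differentiation: a
#' local polynomial (Savitzky-Golay) filter of odd window length
#' `smooth_window` and order `poly_order` is fit around every sample
#' and its analytic derivative is evaluated at the sample; endpoints
#' use the corresponding one-sided fits. Polynomials up to
#' `poly_order` are differentiated exactly.
#'
#' @param ts a [timeseries()].
#' @param smooth_window odd window length in samples (default 21,
#'   about 87 ms at 240 Hz).
#' @param poly_order local polynomial order (default 3); must satisfy
#'   `smooth_window >= poly_order + 2`.
#' @param deriv derivative order (1 = velocity, 2 = acceleration).
#' @return A `timeseries` of the derivative, same length and time
#'   base, units suffixed with `/s`.
#' @examples
#' t <- seq(0, 1, by = 1 / 240)
#' a <- differentiate(differentiate(timeseries(t^2, t = t)))
#' range(a$v[20:220])   # == 2 (second derivative of t^2)
#' @export
differentiate <- function(ts, smooth_window = 21, poly_order = 3, deriv = 1) {
  stopifnot(inherits(ts, "timeseries"))
  if (smooth_window %% 2 == 0) stop("'smooth_window' must be odd", call. = FALSE)
  if (smooth_window < poly_order + 2)
    stop("'smooth_window' must be at least poly_order + 2", call. = FALSE)
  if (smooth_window > length(ts$v))
    stop("smoothing window longer than the series", call. = FALSE)
  if (deriv > poly_order)
    stop("'deriv' cannot exceed 'poly_order'", call. = FALSE)
  dv <- signal::sgolayfilt(ts$v, p = poly_order, n = smooth_window,
                           m = deriv, ts = 1 / ts$fs)
  units <- if (nzchar(ts$units))
    paste0(ts$units, strrep("/s", deriv)) else ""
  timeseries(dv, t = ts$t, fs = ts$fs, units = units,
             channel_id = paste0(ts$channel_id, "_d", deriv))
}

#' Construct a trajectory
#'
#' Positional (and optionally angular-rate) recording of a hand
#' marker: uniformly sampled 3-component position in cm, plus an
#' optional angular-rate channel in deg/s (either a scalar magnitude
#' or three components).
#'
#' @param t sample times, seconds.
#' @param pos n x 3 matrix of positions (cm).
#' @param ang_rate optional n-vector (deg/s magnitude) or n x 3 matrix.
#' @param fs sampling rate (inferred from `t` when `NULL`).
#' @return Object of class `"trajectory"`.
#' @export
trajectory <- function(t, pos, ang_rate = NULL, fs = NULL) {
  pos <- as.matrix(pos)
  stopifnot(ncol(pos) == 3, nrow(pos) == length(t), all(is.finite(pos)))
  if (!is.null(ang_rate)) {
    ang_rate <- if (is.matrix(ang_rate)) as.matrix(ang_rate)
                else matrix(ang_rate, ncol = 1)
    stopifnot(nrow(ang_rate) == length(t), all(is.finite(ang_rate)))
  }
  if (is.null(fs)) fs <- 1 / stats::median(diff(t))
  structure(list(t = as.numeric(t), pos = pos, ang_rate = ang_rate,
                 fs = as.numeric(fs)),
            class = "trajectory")
}

#' Read a trajectory from CSV
#'
#' Expects columns `time_s`, `x`, `y`, `z` and optionally `wx`, `wy`,
#' `wz` (angular rate, deg/s) or a scalar `w`.
#'
#' @param path path to the CSV file.
#' @return A [trajectory()].
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("time_s", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("format error: trajectory needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  ang <- if (all(c("wx", "wy", "wz") %in% names(df)))
    as.matrix(df[, c("wx", "wy", "wz")])
  else if ("w" %in% names(df)) df$w
  trajectory(df$time_s, as.matrix(df[, c("x", "y", "z")]), ang_rate = ang)
}

#' Hand speed profile
#'
#' Euclidean norm of the smoothed first derivative of the 3-component
#' position.
#'
#' @param traj a [trajectory()].
#' @param smooth_window,poly_order see [differentiate()].
#' @return A `timeseries` in cm/s.
#' @export
compute_speed <- function(traj, smooth_window = 21, poly_order = 3) {
  stopifnot(inherits(traj, "trajectory"))
  d <- sapply(1:3, function(j)
    differentiate(timeseries(traj$pos[, j], t = traj$t, fs = traj$fs),
                  smooth_window, poly_order)$v)
  timeseries(sqrt(rowSums(d^2)), t = traj$t, fs = traj$fs,
             units = "cm/s", channel_id = "speed")
}

#' Angular acceleration magnitude
#'
#' Smoothed derivative of the angular-speed magnitude, returned as a
#' non-negative magnitude waveform so that its peaks can be fed to the
#' amplitude micro-movement normalization. Among the kinematic
#' derivatives, angular acceleration yields the largest number of
#' peaks per trial and hence the highest statistical power for
#' empirical distribution estimation.
#'
#' @param traj a [trajectory()] with an angular-rate channel.
#' @param smooth_window,poly_order see [differentiate()].
#' @return A `timeseries` in deg/s^2 (magnitude).
#' @export
compute_angular_acceleration <- function(traj, smooth_window = 21,
                                         poly_order = 3) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(traj$ang_rate))
    stop("configuration error: trajectory has no angular-rate channel",
         call. = FALSE)
  w <- if (ncol(traj$ang_rate) == 3) sqrt(rowSums(traj$ang_rate^2))
       else abs(traj$ang_rate[, 1])
  acc <- differentiate(timeseries(w, t = traj$t, fs = traj$fs),
                       smooth_window, poly_order)
  timeseries(abs(acc$v), t = traj$t, fs = traj$fs,
             units = "deg/s^2", channel_id = "ang_accel")
}

#' Split a pointing trial into forward and backward segments
#'
#' The deliberate, goal-directed forward reach and the spontaneous,
#' uninstructed backward retraction are split at the sample where the
#' hand-to-target distance is minimal (where the fingertip touches the
#' screen; linear velocity is near-instantaneously zero there).
#' Movement onset is the first sample where speed exceeds
#' `rest_speed_frac` times the trial's maximum speed sustained for at
#' least `sustain_s`; movement offset is found symmetrically after the
#' split. Segments are half-open `[start, end)` in 1-based sample
#' indices, so forward and backward partition the movement exactly.
#'
#' @param traj a [trajectory()] covering (at least) the trial window.
#' @param trial a [trial_record()]; its `prompt` opens the search
#'   window.
#' @param target_pos 3-vector, target position in cm.
#' @param t_end end of the search window in seconds (the retraction
#'   outlasts the response event, so this should be the next trial's
#'   prompt or the recording end — the default).
#' @param rest_speed_frac rest threshold as a fraction of the trial's
#'   peak speed.
#' @param sustain_s minimum duration the threshold crossing must be
#'   sustained, seconds.
#' @param speed precomputed speed `timeseries` (optional; computed
#'   from `traj` when `NULL`).
#' @return List with elements `forward` and `backward`, each a
#'   `movement_segment`: list with `trial_index`, `kind`, `start`,
#'   `end` (half-open sample indices into `traj`), `movement_time`
#'   (seconds).
#' @export
segment_trial <- function(traj, trial, target_pos, rest_speed_frac = 0.05,
                          sustain_s = 0.05, speed = NULL, t_end = NULL) {
  stopifnot(inherits(traj, "trajectory"), length(target_pos) == 3)
  if (is.null(speed)) speed <- compute_speed(traj)
  t0 <- trial$event_times$prompt %||% traj$t[1]
  t1 <- t_end %||% traj$t[length(traj$t)]
  win <- which(traj$t >= t0 & traj$t <= t1)
  if (length(win) < 5) stop("trial window too short", call. = FALSE)
  dist <- sqrt(colSums((t(traj$pos[win, ]) - target_pos)^2))
  split_rel <- which.min(dist)
  if (split_rel == 1 || split_rel == length(win))
    stop("segmentation error: hand-target distance minimum at window edge",
         call. = FALSE)
  split <- win[split_rel]
  thr <- rest_speed_frac * max(speed$v[win])
  k <- max(1L, round(sustain_s * traj$fs))
  above <- speed$v[win] > thr
  onset_rel <- first_sustained(above, k)
  if (is.na(onset_rel)) {
    warning("no sustained movement onset found; segment extends to trial start")
    onset_rel <- 1L
  }
  # the hand may dwell at the target before retracting, so look for the
  # backward movement first (sustained above-threshold after the split)
  # and only then for the sustained rest that ends it
  after <- seq(split_rel, length(win))
  bwd_on <- first_sustained(above[after], k)
  search_from <- if (is.na(bwd_on)) 1L else bwd_on
  tail_above <- above[after][search_from:length(after)]
  offset_rel <- first_sustained(!tail_above, k)
  if (is.na(offset_rel)) {
    warning("no sub-threshold rest found after the reach; segment extends to trial end")
    offset_rel <- length(tail_above)
  }
  onset <- win[onset_rel]
  offset <- win[after[offset_rel + search_from - 1L]]
  fwd <- movement_segment(trial$trial_index, "forward", onset, split, traj$fs)
  bwd <- movement_segment(trial$trial_index, "backward", split, offset + 1L,
                          traj$fs)
  list(forward = fwd, backward = bwd)
}

# index of the first element of x starting a run of >= k TRUEs, or NA
first_sustained <- function(x, k) {
  if (!any(x)) return(NA_integer_)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  ok <- which(r$values & r$lengths >= k)
  if (!length(ok)) return(NA_integer_)
  ends[ok[1]] - r$lengths[ok[1]] + 1L
}

movement_segment <- function(trial_index, kind, start, end, fs) {
  stopifnot(end > start)
  structure(list(trial_index = trial_index, kind = kind,
                 start = as.integer(start), end = as.integer(end),
                 movement_time = (end - start) / fs),
            class = "movement_segment")
}

#' Per-trial behavioral validation metrics
#'
#' Computes, per trial: movement time (touch minus prompt), the
#' time-estimation error (absolute difference between the slider
#' response mapped to seconds and the true tone delay), and the number
#' of angular-acceleration peaks inside the forward and backward
#' segments. Missing events yield `NA`, never zero.
#'
#' @param session a [session_record()].
#' @param segments list (one element per trial) of
#'   `list(forward =, backward =)` as returned by [segment_trial()].
#' @param accel angular-acceleration `timeseries` for the session
#'   (sample-aligned with the segment indices).
#' @param scale_max_s full-scale value of the 0-1 response slider in
#'   seconds (the mapping from slider units to seconds; default 1 s).
#' @param min_prominence forwarded to [detect_extrema()] for the peak
#'   counts.
#' @return A data.frame with one row per trial: `trial`, `condition`,
#'   `movement_time`, `time_estimation_error`, `n_accel_peaks_forward`,
#'   `n_accel_peaks_backward`.
#' @export
behavioral_metrics <- function(session, segments, accel, scale_max_s = 1.0,
                               min_prominence = 0) {
  stopifnot(inherits(session, "session_record"),
            length(segments) == length(session$trials))
  count_peaks <- function(seg) {
    if (is.null(seg)) return(NA_integer_)
    idx <- seg$start:(seg$end - 1L)
    if (length(idx) < 3) return(0L)
    sub <- timeseries(accel$v[idx], t = accel$t[idx], fs = accel$fs,
                      units = accel$units)
    length(detect_extrema(sub, min_prominence = min_prominence)$peak_idx)
  }
  rows <- lapply(seq_along(session$trials), function(i) {
    tr <- session$trials[[i]]
    mt <- if (!is.null(tr$event_times$touch) && !is.null(tr$event_times$prompt))
      tr$event_times$touch - tr$event_times$prompt else NA_real_
    te <- if (!is.na(tr$response_value) && !is.na(tr$tone_delay))
      abs(tr$response_value * scale_max_s - tr$tone_delay) else NA_real_
    data.frame(trial = tr$trial_index, condition = tr$condition,
               movement_time = mt, time_estimation_error = te,
               n_accel_peaks_forward = count_peaks(segments[[i]]$forward),
               n_accel_peaks_backward = count_peaks(segments[[i]]$backward))
  })
  do.call(rbind, rows)
}

#' Paired two-sided t test across participants
#'
#' Classical paired comparison of per-participant means between two
#' conditions, with `df = n - 1`. When the paired differences have
#' zero variance the statistic is undefined and the result is returned
#' with `degenerate = TRUE` rather than an error, so batch reports can
#' carry on.
#'
#' @param metric_a,metric_b equal-length numeric vectors of
#'   per-participant means.
#' @return List with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @examples
#' paired_condition_test(c(1.2, 1.4, 1.1), c(1.0, 1.1, 0.9))
#' @export
paired_condition_test <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) == length(metric_b), length(metric_a) >= 2)
  d <- metric_a - metric_b
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(list(t = NA_real_, df = n - 1L, p = NA_real_,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tval <- mean(d) / (s / sqrt(n))
  list(t = tval, df = n - 1L, p = 2 * stats::pt(-abs(tval), n - 1),
       mean_diff = mean(d), degenerate = FALSE)
}
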