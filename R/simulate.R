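#' Condition presets for the pointing-task generator
#'
#' Default generative parameters per condition. Amplitude
#' micro-fluctuations of the angular acceleration follow a Gamma law
#' whose shape decreases and scale (noise-to-signal ratio) increases
#' with cognitive load, and inter-peak gaps shorten under load so that
#' loaded trials carry more acceleration peaks — the direction of the
#' effects the platform is designed to resolve. The condition laws are
#' separated enough (Kolmogorov distance ~0.13-0.28 between adjacent
#' loads) that a session of 60 trials suffices to flag the shift with
#' the pairwise KS test, mirroring a study-sized recording.
#'
#' @param condition one of `"control"`, `"low_load"`, `"high_load"`,
#'   `"time_estimation"`.
#' @return List with `amp_shape`, `amp_scale` (deg/s^2),
#'   `gap_mean` (s).
#' @export
condition_preset <- function(condition) {
  presets <- list(
    control         = list(amp_shape = 3.0, amp_scale = 50, gap_mean = 0.28),
    low_load        = list(amp_shape = 2.2, amp_scale = 90, gap_mean = 0.22),
    high_load       = list(amp_shape = 1.6, amp_scale = 160, gap_mean = 0.16),
    time_estimation = list(amp_shape = 2.7, amp_scale = 60, gap_mean = 0.26))
  if (!condition %in% names(presets))
    stop("unknown condition preset: ", condition, call. = FALSE)
  presets[[condition]]
}

#' Simulate a pointing-task session with known ground truth
#'
#' Generates one participant x condition block of out-and-back
#' pointing trials emulating the study structure: 60 trials per
#' condition, kinematics sampled at 240 Hz, forward and backward
#' motions of about 1.5 s each. Every trial comprises
#'
#' * a minimum-jerk reach from the rest position to the target and a
#'   minimum-jerk retraction back (bell-shaped speed profiles, the
#'   hand-to-target distance minimal exactly at the touch sample);
#' * an angular-rate channel whose derivative (the angular
#'   acceleration) is a train of narrow Gaussian bumps: bump
#'   amplitudes are i.i.d. draws from the condition's Gamma law and
#'   inter-bump gaps follow a shifted-Gamma positive law (shift
#'   `gap_min` guarantees resolvable, non-merging peaks);
#' * trial events (prompt, touch, tone, response) satisfying the trial
#'   invariants, with tone delays drawn from \{0.1, 0.4, 0.7\} s and,
#'   under `"time_estimation"`, a noisy 0-1 slider response.
#'
#' The returned ground truth fully determines the data given the seed
#' and carries the planted Gamma parameters, bump times/amplitudes,
#' per-trial (forward/backward) peak counts and split indices, so
#' every pipeline stage can be checked against truth.
#'
#' @param participant_id,condition labels; the condition selects a
#'   [condition_preset()] unless `amp_shape`/`amp_scale`/`gap_mean`
#'   are given.
#' @param n_trials trials per session (default 60).
#' @param fs kinematic sampling rate, Hz (default 240).
#' @param movement_s nominal duration of each motion half, s
#'   (default 1.5: forward ~1.5 s, backward ~1.5 s).
#' @param trial_s total trial duration, s.
#' @param amp_shape,amp_scale Gamma law of the planted acceleration
#'   peak amplitudes (deg/s^2).
#' @param gap_shape,gap_mean,gap_min shifted-Gamma law of inter-peak
#'   gaps: `gap_min + Gamma(gap_shape, (gap_mean - gap_min)/gap_shape)`.
#' @param bump_sigma_s Gaussian bump width, s.
#' @param target_pos 3-vector, target position (cm).
#' @param rest_pos 3-vector, rest position (cm).
#' @param seed integer seed (required; all randomness flows from it).
#' @return List with `session` (a [session_record()] with channels
#'   `pos_x`, `pos_y`, `pos_z`, `ang_rate`) and `ground_truth` (list
#'   with the planted parameters, per-trial truth and the seed).
#' @export
simulate_pointing_session <- function(participant_id = "P1",
                                      condition = "control",
                                      n_trials = 60, fs = 240,
                                      movement_s = 1.5, trial_s = 4.0,
                                      amp_shape = NULL, amp_scale = NULL,
                                      gap_shape = 3, gap_mean = NULL,
                                      gap_min = 0.10, bump_sigma_s = 0.03,
                                      target_pos = c(12, 30.5, 22),
                                      rest_pos = c(0, 0, 0),
                                      seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  preset <- condition_preset(condition)
  amp_shape <- amp_shape %||% preset$amp_shape
  amp_scale <- amp_scale %||% preset$amp_scale
  gap_mean <- gap_mean %||% preset$gap_mean
  stopifnot(amp_shape > 0, amp_scale > 0, gap_mean > gap_min)
  if (gap_mean < 4 * bump_sigma_s)
    stop("parameter error: mean inter-peak gap too small for the bump width at this fs",
         call. = FALSE)
  set.seed(seed)
  n_total <- round(n_trials * trial_s * fs)
  tt <- (seq_len(n_total) - 1) / fs
  acc <- numeric(n_total)
  pos <- matrix(rep(rest_pos, each = n_total), ncol = 3)
  trials <- vector("list", n_trials)
  truth_trials <- vector("list", n_trials)
  min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  half_w <- ceiling(5 * bump_sigma_s * fs)
  for (k in seq_len(n_trials)) {
    t0 <- (k - 1) * trial_s
    prompt <- t0 + 0.25
    onset <- prompt + 0.25
    fwd_dur <- max(0.8, movement_s - 0.1 + stats::rnorm(1, 0, 0.08))
    touch <- onset + fwd_dur
    hold <- 0.10
    bwd_dur <- max(0.8, movement_s - 0.1 + stats::rnorm(1, 0, 0.08))
    offset <- touch + hold + bwd_dur
    tone_delay <- sample(c(0.1, 0.4, 0.7), 1)
    tone <- touch + tone_delay
    response <- tone + stats::runif(1, 0.3, 0.7)
    response_value <- if (condition == "time_estimation")
      min(1, max(0, tone_delay + stats::rnorm(1, 0, 0.05))) else NA_real_
    # minimum-jerk forward reach and backward retraction
    fwd_idx <- which(tt >= onset & tt < touch)
    tau <- (tt[fwd_idx] - onset) / fwd_dur
    pos[fwd_idx, ] <- matrix(rest_pos, length(fwd_idx), 3, byrow = TRUE) +
      outer(min_jerk(tau), target_pos - rest_pos)
    hold_idx <- which(tt >= touch & tt < touch + hold)
    pos[hold_idx, ] <- matrix(target_pos, length(hold_idx), 3, byrow = TRUE)
    bwd_idx <- which(tt >= touch + hold & tt < offset)
    tau <- (tt[bwd_idx] - touch - hold) / bwd_dur
    pos[bwd_idx, ] <- matrix(target_pos, length(bwd_idx), 3, byrow = TRUE) +
      outer(min_jerk(tau), rest_pos - target_pos)
    # planted angular-acceleration bumps over the movement window
    gaps <- gap_min + stats::rgamma(80, shape = gap_shape,
                                    scale = (gap_mean - gap_min) / gap_shape)
    # keep bumps inside the detectable movement window: the rest-speed
    # threshold truncates the last ~0.1 s of the retraction
    ptimes <- onset + 2 * bump_sigma_s + cumsum(gaps)
    ptimes <- ptimes[ptimes < offset - 0.15]
    # the touch instant is a standstill between the two motions and also
    # the forward/backward boundary sample: keep bumps clear of it
    near_touch <- abs(ptimes - touch) < 0.02
    ptimes[near_touch] <- touch + 0.025
    amps <- stats::rgamma(length(ptimes), shape = amp_shape,
                          scale = amp_scale)
    pidx <- round(ptimes * fs) + 1L
    ptimes <- tt[pidx]                     # snap truth to the sample grid
    for (j in seq_along(pidx)) {
      w <- max(1L, pidx[j] - half_w):min(n_total, pidx[j] + half_w)
      acc[w] <- acc[w] + amps[j] * exp(-((tt[w] - ptimes[j])^2) /
                                         (2 * bump_sigma_s^2))
    }
    split_idx <- which.min(abs(tt - touch))
    trials[[k]] <- trial_record(
      k - 1L, condition,
      list(prompt = prompt, touch = touch, tone = tone, response = response),
      tone_delay = tone_delay, response_value = response_value, fs = fs)
    truth_trials[[k]] <- list(
      peak_times = ptimes, peak_idx = pidx, peak_amps = amps,
      n_peaks = length(pidx),
      n_peaks_forward = sum(ptimes <= touch),
      n_peaks_backward = sum(ptimes > touch),
      split_idx = split_idx, onset_s = onset, offset_s = offset)
  }
  ang_rate <- cumsum(acc) / fs
  channels <- list(
    pos_x = timeseries(pos[, 1], t = tt, fs = fs, units = "cm",
                       channel_id = "pos_x"),
    pos_y = timeseries(pos[, 2], t = tt, fs = fs, units = "cm",
                       channel_id = "pos_y"),
    pos_z = timeseries(pos[, 3], t = tt, fs = fs, units = "cm",
                       channel_id = "pos_z"),
    ang_rate = timeseries(ang_rate, t = tt, fs = fs, units = "deg/s",
                          channel_id = "ang_rate"))
  session <- session_record(participant_id, condition, trials, channels)
  ground_truth <- list(
    participant_id = participant_id, condition = condition, seed = seed,
    fs = fs, n_trials = n_trials, trial_s = trial_s,
    amp_shape = amp_shape, amp_scale = amp_scale,
    gap_shape = gap_shape, gap_mean = gap_mean, gap_min = gap_min,
    bump_sigma_s = bump_sigma_s, target_pos = target_pos,
    rest_pos = rest_pos, trials = truth_trials)
  list(session = session, ground_truth = ground_truth)
}

#' Simulate an ECG record with known beat times
#'
#' Renders a QRS-like train: beat times accumulate from
#' Gamma-distributed inter-beat intervals (or a fixed interval), each
#' beat is a symmetric biphasic difference-of-Gaussians pulse of about
#' 80 ms support (spectral content inside the 5-30 Hz QRS band), plus
#' optional additive white noise at a prescribed SNR and a 0.3 Hz
#' sinusoidal baseline wander.
#'
#' @param duration_s record length, s.
#' @param ibi_shape,ibi_scale Gamma law of the inter-beat intervals;
#'   the mean `ibi_shape * ibi_scale` must lie in `[0.3, 2]` s.
#' @param ibi_fixed if non-`NULL`, a constant IBI in seconds
#'   (overrides the Gamma law).
#' @param fs sampling rate, Hz (default 256).
#' @param snr_db white-noise level as signal-to-noise ratio in dB
#'   (`Inf` = clean).
#' @param baseline_amp,baseline_hz baseline-wander amplitude (mV) and
#'   frequency (Hz).
#' @param r_amp_mv R-peak amplitude, mV.
#' @param seed integer seed (required).
#' @return List with `ecg` (a [timeseries()], mV) and `ground_truth`
#'   (planted `beat_times`, `ibi`, the parameters and the seed).
#' @export
simulate_ecg <- function(duration_s, ibi_shape = 40, ibi_scale = 0.02,
                         ibi_fixed = NULL, fs = 256, snr_db = Inf,
                         baseline_amp = 0.2, baseline_hz = 0.3,
                         r_amp_mv = 1.0, seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (fs <= 60) stop("'fs' must exceed 60 Hz", call. = FALSE)
  mean_ibi <- if (!is.null(ibi_fixed)) ibi_fixed else ibi_shape * ibi_scale
  if (mean_ibi < 0.3 || mean_ibi > 2.0)
    stop("mean IBI must lie in [0.3, 2] s", call. = FALSE)
  set.seed(seed)
  n_max <- ceiling(1.5 * duration_s / mean_ibi) + 10
  ibi <- if (!is.null(ibi_fixed)) rep(ibi_fixed, n_max)
         else stats::rgamma(n_max, shape = ibi_shape, scale = ibi_scale)
  beat_times <- 0.5 + cumsum(c(0, ibi))
  beat_times <- beat_times[beat_times < duration_s - 0.5]
  n <- round(duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  # snap planted beats to the sample grid so truth is sample-exact
  bidx <- round(beat_times * fs) + 1L
  beat_times <- tt[bidx]
  sig1 <- 0.011; sig2 <- 2 * sig1         # biphasic DoG, ~80 ms support
  half_w <- ceiling(4 * sig2 * fs)
  v <- numeric(n)
  for (j in seq_along(bidx)) {
    w <- max(1L, bidx[j] - half_w):min(n, bidx[j] + half_w)
    dt <- tt[w] - beat_times[j]
    v[w] <- v[w] + r_amp_mv * (exp(-dt^2 / (2 * sig1^2)) -
                                 0.5 * exp(-dt^2 / (2 * sig2^2))) / 0.5
  }
  if (is.finite(snr_db)) {
    noise_sd <- sqrt(mean(v^2)) / 10^(snr_db / 20)
    v <- v + stats::rnorm(n, 0, noise_sd)
  }
  if (baseline_amp > 0)
    v <- v + baseline_amp * sin(2 * pi * baseline_hz * tt +
                                  stats::runif(1, 0, 2 * pi))
  ecg <- timeseries(v, t = tt, fs = fs, units = "mV", channel_id = "ecg")
  list(ecg = ecg,
       ground_truth = list(beat_times = beat_times, beat_idx = bidx,
                           ibi = diff(beat_times), seed = seed,
                           ibi_shape = if (is.null(ibi_fixed)) ibi_shape else NA,
                           ibi_scale = if (is.null(ibi_fixed)) ibi_scale else NA,
                           ibi_fixed = ibi_fixed, fs = fs,
                           snr_db = snr_db, baseline_amp = baseline_amp))
}

#' Simulate a cohort of participants
#'
#' Draws per-participant Gamma parameters for the planted acceleration
#' amplitudes and generates one session per participant x condition.
#' Shapes are drawn log-uniformly over `shape_range`; scales are drawn
#' so the amplitude mean varies by `mean_spread` around `common_mean`,
#' or — with `equal_mean = TRUE` — are set to `common_mean / shape`
#' exactly, so all participants share one amplitude mean and the
#' log-log Gamma-plane scatter of the fitted parameters must fall on a
#' line of slope -1 and intercept `log(common_mean)`.
#'
#' @param n_participants default 9.
#' @param conditions character vector of conditions per participant.
#' @param n_trials trials per session.
#' @param shape_range range of per-participant amplitude shapes.
#' @param common_mean central amplitude mean, deg/s^2.
#' @param mean_spread relative spread of per-participant means
#'   (ignored when `equal_mean = TRUE`).
#' @param equal_mean constrain all participants' amplitude means to
#'   `common_mean` exactly.
#' @param seed integer seed; per-session seeds are derived from it.
#' @param ... forwarded to [simulate_pointing_session()].
#' @return List with `sessions` (flat list, one per participant x
#'   condition) and `ground_truth` (per-participant parameters, the
#'   per-session truths and the seed).
#' @export
make_cohort <- function(n_participants = 9,
                        conditions = c("control", "low_load", "high_load"),
                        n_trials = 60, shape_range = c(1.5, 6),
                        common_mean = 150, mean_spread = 0.1,
                        equal_mean = FALSE, seed, ...) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot(n_participants >= 1, shape_range[1] > 0,
            shape_range[2] > shape_range[1])
  set.seed(seed)
  shapes <- exp(stats::runif(n_participants, log(shape_range[1]),
                             log(shape_range[2])))
  means <- if (equal_mean) rep(common_mean, n_participants)
           else common_mean * exp(stats::rnorm(n_participants, 0, mean_spread))
  scales <- means / shapes
  pids <- sprintf("P%02d", seq_len(n_participants))
  sessions <- list()
  truths <- list()
  for (i in seq_len(n_participants)) {
    for (j in seq_along(conditions)) {
      sub_seed <- (seed + i * 1009L + j * 101L) %% .Machine$integer.max
      sim <- simulate_pointing_session(
        participant_id = pids[i], condition = conditions[j],
        n_trials = n_trials, amp_shape = shapes[i], amp_scale = scales[i],
        seed = sub_seed, ...)
      key <- paste(pids[i], conditions[j], sep = ".")
      sessions[[key]] <- sim$session
      truths[[key]] <- sim$ground_truth
    }
  }
  list(sessions = sessions,
       ground_truth = list(seed = seed, participant_ids = pids,
                           amp_shapes = shapes, amp_scales = scales,
                           amp_means = means, equal_mean = equal_mean,
                           conditions = conditions, sessions = truths))
}
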