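#' Band-pass filter specification for QRS isolation
#'
#' Default is the 2nd-order Butterworth IIR band pass at 5-30 Hz: the
#' QRS complex of the electrocardiogram carries most of its energy in
#' that band, so the filter suppresses baseline wander (below ~0.5 Hz)
#' and high-frequency noise while leaving the R deflection intact.
#'
#' @param low_hz lower -3 dB edge, Hz.
#' @param high_hz upper -3 dB edge, Hz.
#' @param order filter order per band edge.
#' @return Object of class `"filter_spec"`.
#' @export
filter_spec <- function(low_hz = 5, high_hz = 30, order = 2) {
  stopifnot(low_hz > 0, high_hz > low_hz, order >= 1)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order)),
            class = "filter_spec")
}

#' Design the Butterworth band-pass filter
#'
#' Bilinear-transform Butterworth design. For a single (forward) pass
#' the magnitude response is -3 dB at both band edges and exactly zero
#' at DC. The package applies the filter bidirectionally (see
#' [preprocess_ecg()]), which squares the magnitude response (-6 dB at
#' the edges) but cancels the phase, keeping R-peak times unshifted.
#'
#' @param spec a [filter_spec()].
#' @param fs sampling rate, Hz; must exceed `2 * high_hz`.
#' @return List with numerator `b` and denominator `a` polynomial
#'   coefficients (in `z^-1`), plus `spec` and `fs`.
#' @export
design_bandpass <- function(spec = filter_spec(), fs) {
  stopifnot(inherits(spec, "filter_spec"))
  if (fs <= 2 * spec$high_hz)
    stop(sprintf("sampling rate %g Hz too low for a %g Hz band edge",
                 fs, spec$high_hz), call. = FALSE)
  bf <- signal::butter(spec$order,
                       c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  list(b = as.numeric(bf$b), a = as.numeric(bf$a), spec = spec, fs = fs)
}

#' Evaluate a digital filter's frequency response
#'
#' Direct polynomial evaluation of `H(z) = B(z^-1)/A(z^-1)` on the unit
#' circle at the requested frequencies.
#'
#' @param filt list with `b`, `a`, `fs` as from [design_bandpass()].
#' @param freq_hz frequencies at which to evaluate, Hz.
#' @return Complex response values, one per frequency.
#' @export
filter_response <- function(filt, freq_hz) {
  w <- 2 * pi * freq_hz / filt$fs
  vapply(w, function(wi) {
    z <- exp(-1i * wi * (seq_along(filt$b) - 1))
    num <- sum(filt$b * z)
    z <- exp(-1i * wi * (seq_along(filt$a) - 1))
    num / sum(filt$a * z)
  }, complex(1))
}

#' Zero-phase band-pass filtering of an ECG channel
#'
#' Applies the Butterworth band pass forward and backward
#' (zero-phase), preserving the timing of the R peaks that the
#' inter-beat-interval analysis depends on. Output has the same length
#' and time base as the input.
#'
#' @param ts a validated [timeseries()] holding the raw ECG (mV).
#' @param spec a [filter_spec()].
#' @return Filtered `timeseries`.
#' @export
preprocess_ecg <- function(ts, spec = filter_spec()) {
  stopifnot(inherits(ts, "timeseries"))
  filt <- design_bandpass(spec, ts$fs)
  startup <- 3 * (max(length(filt$a), length(filt$b)) - 1)
  if (length(ts$v) < 3 * startup)
    stop("ECG record too short for stable zero-phase filtering", call. = FALSE)
  out <- signal::filtfilt(signal::Arma(b = filt$b, a = filt$a), ts$v)
  timeseries(out, t = ts$t, fs = ts$fs, units = ts$units,
             channel_id = paste0(ts$channel_id, "_bp"))
}

#' Detect R-peaks in a filtered ECG
#'
#' Simple amplitude-threshold peak detection: candidate peaks are
#' interior local maxima exceeding `min_height_frac` times a rolling
#' 5-s amplitude envelope (the envelope adapts the threshold to slow
#' gain drifts); candidates are then greedily accepted in order of
#' decreasing amplitude subject to a refractory separation of
#' `refractory_s` (default 250 ms, i.e. a physiological ceiling of
#' about 240 bpm). Polarity is auto-corrected: when the large
#' deflections are predominantly negative the signal is inverted
#' before detection.
#'
#' @param ts_filtered band-passed ECG [timeseries()].
#' @param refractory_s minimum separation between accepted beats, s.
#' @param min_height_frac threshold as a fraction of the local
#'   amplitude envelope.
#' @param envelope_s envelope window length, s.
#' @return Numeric vector of beat times (seconds); empty, with a
#'   warning, when nothing crosses the threshold.
#' @export
detect_rpeaks <- function(ts_filtered, refractory_s = 0.25,
                          min_height_frac = 0.5, envelope_s = 5) {
  stopifnot(inherits(ts_filtered, "timeseries"))
  v <- ts_filtered$v
  fs <- ts_filtered$fs
  n <- length(v)
  if (n < 3 || all(v == 0) || stats::sd(v) == 0) {
    warning("no R-peaks found")
    return(numeric(0))
  }
  # polarity: compare the extreme tails
  hi <- stats::quantile(v, 0.999, names = FALSE)
  lo <- stats::quantile(v, 0.001, names = FALSE)
  if (abs(lo) > abs(hi)) v <- -v
  # rolling amplitude envelope: block maxima of |v| over envelope_s
  # windows, linearly interpolated to a per-sample threshold
  blk <- ceiling(envelope_s * fs)
  starts <- seq(1L, n, by = blk)
  centers <- pmin(starts + (blk - 1L) / 2, n)
  env <- vapply(starts, function(s0) max(abs(v[s0:min(s0 + blk - 1L, n)])),
                numeric(1))
  thr <- if (length(env) > 1)
    stats::approx(centers, env, xout = seq_len(n), rule = 2)$y
  else rep(env, n)
  thr <- min_height_frac * thr
  interior <- 2:(n - 1)
  cand <- interior[v[interior] > v[interior - 1] & v[interior] >= v[interior + 1] &
                     v[interior] > thr[interior]]
  if (!length(cand)) {
    warning("no R-peaks found")
    return(numeric(0))
  }
  # greedy refractory enforcement, tallest candidate first
  ord <- cand[order(v[cand], decreasing = TRUE)]
  kept <- integer(0)
  min_gap <- refractory_s * fs
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  sort(ts_filtered$t[kept])
}

#' Inter-beat intervals from beat times
#'
#' Consecutive differences of the R-peak times. Intervals larger than
#' twice the running median (window `runmed_k` intervals) are flagged
#' as suspected missed beats; they are never silently deleted, so the
#' analyst can inspect them (see [plot_ibi_inspection()]) and decide.
#'
#' @param beat_times numeric vector of beat times, seconds.
#' @param runmed_k odd window size for the running median.
#' @return Object of class `"ibi_series"`: list with `beat_times`,
#'   `ibi` (seconds), and logical `flags` (one per interval). Empty,
#'   with a warning, for fewer than 2 beats.
#' @export
compute_ibi <- function(beat_times, runmed_k = 11) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) < 2) {
    warning("fewer than 2 beats: empty IBI series")
    return(structure(list(beat_times = beat_times, ibi = numeric(0),
                          flags = logical(0)), class = "ibi_series"))
  }
  ibi <- diff(beat_times)
  if (any(ibi <= 0)) stop("beat times must be strictly increasing", call. = FALSE)
  # running median over a window of neighbours, excluding the tested
  # interval itself so that one long dropout cannot mask itself
  n <- length(ibi)
  half <- runmed_k %/% 2
  med <- vapply(seq_len(n), function(i) {
    w <- setdiff(max(1, i - half):min(n, i + half), i)
    if (length(w)) stats::median(ibi[w]) else ibi[i]
  }, numeric(1))
  structure(list(beat_times = beat_times, ibi = ibi, flags = ibi >= 2 * med),
            class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series: %d beats, %d intervals, %d flagged>\n",
              length(x$beat_times), length(x$ibi), sum(x$flags)))
  invisible(x)
}

#' Diagnostic plot of beats over the filtered ECG
#'
#' Replaces manual plotting-and-eyeballing for missed beats with a
#' reproducible inspection figure: filtered trace, detected beats, and
#' flagged intervals highlighted.
#'
#' @param ts_filtered filtered ECG [timeseries()].
#' @param ibi an [`ibi_series`][compute_ibi()].
#' @param out output file (PDF); `NULL` plots to the active device.
#' @return `out`, invisibly.
#' @export
plot_ibi_inspection <- function(ts_filtered, ibi, out = NULL) {
  if (!is.null(out)) {
    grDevices::pdf(out, width = 10, height = 4)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(ts_filtered$t, ts_filtered$v, type = "l", col = "grey40",
                 xlab = "time (s)", ylab = ts_filtered$units,
                 main = "R-peak inspection")
  graphics::abline(v = ibi$beat_times, col = "#cc000055")
  if (any(ibi$flags)) {
    bad <- which(ibi$flags)
    graphics::rect(ibi$beat_times[bad], graphics::par("usr")[3],
                   ibi$beat_times[bad + 1], graphics::par("usr")[4],
                   col = "#ffaa0033", border = NA)
  }
  invisible(out)
}

#' Export an IBI series to CSV
#'
#' Columns `beat_time_s`, `ibi_s`, `flag` (the interval closing at
#' each beat; the first beat has no interval).
#'
#' @param ibi an [`ibi_series`][compute_ibi()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ibi_csv <- function(ibi, path) {
  df <- data.frame(beat_time_s = ibi$beat_times,
                   ibi_s = c(NA, ibi$ibi),
                   flag = c(NA, ibi$flags))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
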