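#' Construct a micro-movement series
#'
#' Internal constructor for the unit-less spike-train data type: every
#' value lies strictly in (0, 1) and is paired with the raw physical
#' quantity it was derived from (peak amplitude in native units, or an
#' inter-peak interval in seconds). The median of the raw values is
#' kept alongside, since plots color-code each participant/condition by
#' the median physical value to preserve the individual's native scale
#' after normalization.
#'
#' @param values normalized values, strictly in (0, 1).
#' @param kind `"AM"` (amplitude) or `"NTM"` (timing).
#' @param raw_values underlying physical values, same length.
#' @param peak_times seconds, same length (or `NA`).
#' @param units unit label of `raw_values`.
#' @return Object of class `"micromovement_series"`.
#' @keywords internal
new_micromovement_series <- function(values, kind, raw_values, peak_times,
                                     units) {
  stopifnot(length(values) == length(raw_values),
            kind %in% c("AM", "NTM"))
  if (length(values) && (any(values <= 0) || any(values >= 1)))
    stop("micro-movement values must lie strictly in (0, 1)", call. = FALSE)
  structure(
    list(values = as.numeric(values), kind = kind,
         raw_values = as.numeric(raw_values),
         raw_median = if (length(raw_values)) stats::median(raw_values)
                      else NA_real_,
         peak_times = as.numeric(peak_times), units = units),
    class = "micromovement_series"
  )
}

#' @export
print.micromovement_series <- function(x, ...) {
  cat(sprintf("<micromovements %s: n = %d, raw median %.4g %s>\n",
              x$kind, length(x$values), x$raw_median, x$units))
  invisible(x)
}

#' Amplitude micro-movements (AM)
#'
#' Normalizes each local peak amplitude by the sum of the peak
#' amplitude and the average of the signal over the window spanned by
#' the two flanking local minima:
#' \deqn{AM_i = \frac{peak_i}{peak_i + \overline{minToMin}_i}}
#' The result is unit-less and strictly inside (0, 1); multiplying the
#' whole waveform by any positive constant leaves it unchanged, which
#' removes allometric (body-size / instrument-gain) effects so that
#' participants can be compared on a common scale. For a fixed peak,
#' higher flanking averages give lower AM, i.e. high AM flags peaks
#' standing far above their local baseline.
#'
#' The normalization presumes a non-negative magnitude waveform (speed,
#' angular acceleration magnitude, inter-beat intervals); peaks whose
#' flanking window contains negative samples raise an error, and peaks
#' with a zero denominator are dropped with a warning. Peaks without
#' two flanking minima (first/last extremum) are discarded, as the
#' normalization is undefined there.
#'
#' @param pt a [`peak_train`][detect_extrema()].
#' @return A `micromovement_series` of kind `"AM"`; `raw_values` are
#'   the native peak amplitudes.
#' @examples
#' ts <- timeseries(c(0, 1, 2, 3, 2, 1, 0, 2, 0), fs = 240)
#' am <- compute_am(detect_extrema(ts))
#' am$values
#' @export
compute_am <- function(pt) {
  stopifnot(inherits(pt, "peak_train"))
  has_flank <- !is.na(pt$flank_avg)
  amp <- pt$peak_amp[has_flank]
  flank <- pt$flank_avg[has_flank]
  times <- pt$peak_times[has_flank]
  wmin <- if (!is.null(pt$window_min)) pt$window_min[has_flank]
          else pmin(amp, flank)
  if (any(amp < 0) || any(wmin < 0))
    stop("AM normalization requires a non-negative magnitude waveform",
         call. = FALSE)
  denom <- amp + flank
  zero <- denom == 0
  if (any(zero)) {
    warning(sum(zero), " peak(s) with zero denominator dropped")
    amp <- amp[!zero]; flank <- flank[!zero]; times <- times[!zero]
  }
  new_micromovement_series(amp / (amp + flank), "AM", amp, times, pt$units)
}

#' Inter-peak timings (TM)
#'
#' The time elapsed between consecutive peaks, in seconds. This is the
#' raw timing counterpart of the peak amplitudes; its normalized form
#' is produced by [compute_ntm()].
#'
#' @param pt a [`peak_train`][detect_extrema()].
#' @return Numeric vector of length `n_peaks - 1` (empty, with a
#'   warning, when fewer than 2 peaks are present), with attribute
#'   `"times"` giving the time of the closing peak of each interval.
#' @export
compute_tm <- function(pt) {
  stopifnot(inherits(pt, "peak_train"))
  if (length(pt$peak_idx) < 2) {
    warning("fewer than 2 peaks: empty TM series")
    return(structure(numeric(0), times = numeric(0)))
  }
  structure(diff(pt$peak_times), times = pt$peak_times[-1])
}

#' Timing micro-movements (NTM)
#'
#' Applies the same peak normalization used for amplitudes to the
#' sequence of inter-peak intervals (TM), yielding unit-less timing
#' fluctuations in (0, 1). Two conventions are provided, because
#' mapping a min-to-min window onto a *sequence of intervals* admits
#' more than one reading:
#'
#' * `"series_minima"` (default): treat the TM sequence as a discrete
#'   signal, locate its interior local maxima, and normalize each TM
#'   peak by itself plus the average of its two flanking minima (the
#'   smallest TM value on each side of the peak; the sequence boundary
#'   may supply a flank). A constant TM sequence has no interior
#'   extrema and yields an empty series with a warning.
#' * `"global_mean"`: normalize every interval by itself plus the mean
#'   of all intervals, `NTM_i = tm_i / (tm_i + mean(tm))`.
#'
#' Both are scale-invariant: multiplying all intervals by a positive
#' constant leaves the NTM values unchanged.
#'
#' @param tm numeric vector of inter-peak intervals (seconds), e.g.
#'   from [compute_tm()]; an attribute `"times"` is carried through
#'   when present.
#' @param mode `"series_minima"` or `"global_mean"`.
#' @return A `micromovement_series` of kind `"NTM"`; `raw_values` are
#'   the TM intervals that were normalized, in seconds.
#' @examples
#' compute_ntm(c(1, 3, 1))$values                      # 3/(3+1) = 0.75
#' compute_ntm(rep(2, 5), mode = "global_mean")$values # all 0.5
#' @export
compute_ntm <- function(tm, mode = c("series_minima", "global_mean")) {
  mode <- match.arg(mode)
  times <- attr(tm, "times")
  tm <- as.numeric(tm)
  if (any(tm <= 0)) stop("TM intervals must be positive", call. = FALSE)
  if (mode == "global_mean") {
    if (length(tm) < 1) stop("need at least 1 interval", call. = FALSE)
    vals <- tm / (tm + mean(tm))
    return(new_micromovement_series(vals, "NTM", tm,
                                    times %||% rep(NA_real_, length(tm)), "s"))
  }
  if (length(tm) < 3)
    stop("series_minima mode needs at least 3 intervals", call. = FALSE)
  n <- length(tm)
  is_peak <- vapply(2:(n - 1), function(i)
    tm[i] > tm[i - 1] && tm[i] >= tm[i + 1], logical(1))
  pk <- (2:(n - 1))[is_peak]
  if (!length(pk)) {
    warning("no interior TM maxima (constant or monotone TM sequence): empty NTM series")
    return(new_micromovement_series(numeric(0), "NTM", numeric(0),
                                    numeric(0), "s"))
  }
  vals <- raw <- tms <- numeric(length(pk))
  bounds <- c(0L, pk, n + 1L)
  for (j in seq_along(pk)) {
    i <- pk[j]
    left <- min(tm[max(bounds[j] + 1L, 1L):(i - 1L)])
    right <- min(tm[(i + 1L):min(bounds[j + 2L] - 1L, n)])
    flank <- (left + right) / 2
    vals[j] <- tm[i] / (tm[i] + flank)
    raw[j] <- tm[i]
    tms[j] <- if (!is.null(times)) times[i] else NA_real_
  }
  new_micromovement_series(vals, "NTM", raw, tms, "s")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a micro-movement series to CSV
#'
#' Columns: `peak_time_s`, `raw_value`, `mm_value`, `kind`, `units`.
#'
#' @param mm a `micromovement_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_micromovements_csv <- function(mm, path) {
  stopifnot(inherits(mm, "micromovement_series"))
  df <- data.frame(peak_time_s = mm$peak_times,
                   raw_value = mm$raw_values,
                   mm_value = mm$values,
                   kind = rep(mm$kind, length(mm$values)),
                   units = rep(mm$units, length(mm$values)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
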