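#' Construct a uniformly sampled time series
#'
#' The basic container for a single biophysical channel: a strictly
#' increasing, uniformly sampled time base `t` (seconds), real-valued
#' samples `v` in some physical unit, and the sampling rate `fs` (Hz).
#' Segments elsewhere in the package are half-open `[start, end)` in
#' 1-based sample indices of this container.
#'
#' Either `t` or `fs` must be given. When only `fs` is given, the time
#' base is synthesized as `(k - 1) / fs` for `k = 1..n` (i.e. starting
#' at 0 s). When only `t` is given, `fs` is estimated as the reciprocal
#' of the median sampling interval.
#'
#' @param v numeric vector of samples.
#' @param t numeric vector of sample times in seconds, or `NULL`.
#' @param fs sampling rate in Hz, or `NULL`.
#' @param units free-text label for the physical unit of `v`
#'   (e.g. `"deg/s^2"`, `"mV"`, `"cm"`).
#' @param channel_id label for the channel.
#' @return An object of class `"timeseries"`: a list with elements
#'   `t`, `v`, `fs`, `units`, `channel_id`.
#' @seealso [validate_timeseries()], [read_timeseries_csv()]
#' @examples
#' ts <- timeseries(sin(2 * pi * (0:239) / 240), fs = 240, units = "cm")
#' ts$fs
#' @export
timeseries <- function(v, t = NULL, fs = NULL, units = "", channel_id = "ch") {
  v <- as.numeric(v)
  if (is.null(t) && is.null(fs))
    stop("either 't' or 'fs' must be supplied", call. = FALSE)
  if (is.null(t)) {
    if (fs <= 0) stop("'fs' must be positive", call. = FALSE)
    t <- (seq_along(v) - 1) / fs
  } else {
    t <- as.numeric(t)
    if (length(t) != length(v))
      stop("'t' and 'v' must have the same length", call. = FALSE)
    if (is.null(fs)) {
      if (length(t) < 2)
        stop("cannot infer 'fs' from fewer than 2 samples", call. = FALSE)
      fs <- 1 / stats::median(diff(t))
    }
  }
  structure(
    list(t = t, v = v, fs = as.numeric(fs),
         units = as.character(units), channel_id = as.character(channel_id)),
    class = "timeseries"
  )
}

#' @export
print.timeseries <- function(x, ...) {
  cat(sprintf("<timeseries '%s': %d samples @ %.6g Hz, %.4g-%.4g s%s>\n",
              x$channel_id, length(x$v), x$fs, x$t[1], x$t[length(x$t)],
              if (nzchar(x$units)) paste0(", ", x$units) else ""))
  invisible(x)
}

#' @export
length.timeseries <- function(x) length(x$v)

#' Validate a time series and apply a missing-value policy
#'
#' Checks the container invariants: matching lengths, strictly
#' increasing time, positive sampling rate, and uniform sampling with
#' every interval within 1% of the nominal `1/fs` (files violating
#' this are rejected rather than silently resampled, because the
#' derivative estimators downstream assume uniform sampling). `NaN`/`NA`
#' samples are handled per `nan_policy`: `"reject"` raises on any
#' missing value; `"interpolate"` replaces *interior* runs of missing
#' values by linear interpolation (leading/trailing missing values
#' cannot be interpolated and always raise).
#'
#' @param ts a [timeseries()].
#' @param nan_policy `"reject"` (default) or `"interpolate"`.
#' @return The validated (possibly interpolated) `timeseries`, with an
#'   attribute `"validation"`, a list with `n_missing` (missing samples
#'   found) and `n_interpolated` (samples filled in). Validation is
#'   idempotent on the data fields.
#' @examples
#' ts <- timeseries(c(1, NA, 3), fs = 10)
#' out <- validate_timeseries(ts, nan_policy = "interpolate")
#' out$v                       # 1 2 3
#' attr(out, "validation")$n_interpolated
#' @export
validate_timeseries <- function(ts, nan_policy = c("reject", "interpolate")) {
  nan_policy <- match.arg(nan_policy)
  stopifnot(inherits(ts, "timeseries"))
  n <- length(ts$v)
  if (n == 0) stop("empty time series", call. = FALSE)
  if (length(ts$t) != n)
    stop("time base and samples differ in length", call. = FALSE)
  if (n >= 2 && any(diff(ts$t) <= 0))
    stop("time base must be strictly increasing (duplicate or reversed timestamps)",
         call. = FALSE)
  if (!is.finite(ts$fs) || ts$fs <= 0)
    stop("sampling rate must be a positive finite number", call. = FALSE)
  if (n >= 2) {
    dt <- diff(ts$t)
    if (any(abs(dt - 1 / ts$fs) > 0.01 / ts$fs))
      stop(sprintf(
        "non-uniform sampling: max |dt - 1/fs| = %.3g s exceeds 1%% of the sampling interval",
        max(abs(dt - 1 / ts$fs))), call. = FALSE)
  }
  bad <- !is.finite(ts$v)
  n_missing <- sum(bad)
  n_interp <- 0L
  if (n_missing > 0) {
    if (nan_policy == "reject")
      stop(sprintf("%d missing/non-finite sample(s) under nan_policy = 'reject'",
                   n_missing), call. = FALSE)
    if (bad[1] || bad[n])
      stop("leading/trailing missing values cannot be interpolated", call. = FALSE)
    ts$v <- stats::approx(ts$t[!bad], ts$v[!bad], xout = ts$t,
                          method = "linear")$y
    n_interp <- n_missing
  }
  attr(ts, "validation") <- list(n_missing = n_missing,
                                 n_interpolated = n_interp)
  ts
}

#' Read a time series from a CSV/TSV file
#'
#' Expects a header row, comma (or tab) separation, decimal point and
#' UTF-8 encoding. The file must either contain a time column (seconds)
#' or the sampling rate must be declared via `fs`, in which case the
#' time base is synthesized starting at 0 s.
#'
#' @param path path to the file.
#' @param time_col name of the time column (seconds), or `NULL` when
#'   `fs` is given.
#' @param value_col name of the value column.
#' @param fs sampling rate in Hz, required when `time_col` is `NULL`
#'   or absent from the file.
#' @param units,channel_id metadata labels, see [timeseries()].
#' @param nan_policy forwarded to [validate_timeseries()].
#' @param sep field separator; `","` (default) or `"\t"`.
#' @return A validated [timeseries()].
#' @export
read_timeseries_csv <- function(path, time_col = "time_s", value_col = "value",
                                fs = NULL, units = "", channel_id = NULL,
                                nan_policy = "reject", sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                          fileEncoding = "UTF-8", check.names = FALSE)
  if (nrow(df) < 2)
    stop("input file must contain at least 2 data rows", call. = FALSE)
  if (!value_col %in% names(df))
    stop(sprintf("format error: missing value column '%s'", value_col),
         call. = FALSE)
  has_time <- !is.null(time_col) && time_col %in% names(df)
  if (!has_time && is.null(fs))
    stop("format error: no time column and no 'fs' declared", call. = FALSE)
  if (is.null(channel_id))
    channel_id <- sub("\\.[^.]*$", "", basename(path))
  ts <- timeseries(df[[value_col]],
                   t = if (has_time) df[[time_col]] else NULL,
                   fs = fs, units = units, channel_id = channel_id)
  validate_timeseries(ts, nan_policy = nan_policy)
}

#' Write a time series to CSV
#'
#' Writes columns `time_s` and `value` so that
#' `read_timeseries_csv(write_timeseries_csv(ts))` round-trips exactly
#' (values are written with 17 significant digits, enough to restore
#' every double bit-for-bit).
#'
#' @param ts a [timeseries()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(ts, path) {
  stopifnot(inherits(ts, "timeseries"))
  df <- data.frame(time_s = sprintf("%.17g", ts$t),
                   value = sprintf("%.17g", ts$v))
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
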