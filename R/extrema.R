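#' Detect alternating local maxima and minima of a waveform
#'
#' Finds the interior local extrema of a sampled waveform so that
#' maxima and minima strictly alternate. Boundary samples are never
#' extrema; plateaus (runs of equal samples) contribute their first
#' sample. With `min_prominence = 0` (the default) every strict sign
#' change of the first difference counts, so the raw peak count can be
#' used directly as a movement-intensity metric; with a positive
#' `min_prominence`, adjacent peak/valley pairs whose amplitude span is
#' below the threshold are pruned (smallest span first) until every
#' remaining adjacent pair spans at least `min_prominence`.
#'
#' For every peak that has a local minimum on both sides, the
#' *flanking-window average* is computed: the mean of all samples from
#' the left minimum to the right minimum inclusive (the peak itself
#' included). This is the local baseline that the amplitude
#' micro-movement normalization divides by; the inclusive convention is
#' deterministic and keeps the normalized values strictly below 1.
#' First/last extrema lacking two flanking minima carry `NA` flanking
#' averages and are dropped by [compute_am()].
#'
#' @param ts a [timeseries()] (validated).
#' @param min_prominence minimum amplitude span (units of `v`) between
#'   adjacent retained extrema; `0` keeps everything.
#' @return An object of class `"peak_train"`: list with `peak_idx`,
#'   `valley_idx` (1-based sample indices), `peak_amp`, `flank_avg`
#'   and `window_min` (the minimum sample of the same window; both
#'   `NA` where undefined), `peak_times`, `units`, `fs`.
#' @examples
#' ts <- timeseries(sin(2 * pi * 1 * (0:199) / 100), fs = 100)
#' pt <- detect_extrema(ts)
#' length(pt$peak_idx)   # 2 maxima of the 1 Hz sinusoid over 2 s
#' @export
detect_extrema <- function(ts, min_prominence = 0) {
  stopifnot(inherits(ts, "timeseries"), min_prominence >= 0)
  v <- ts$v
  n <- length(v)
  if (n < 3) stop("need at least 3 samples to detect interior extrema",
                  call. = FALSE)
  d <- diff(v)
  s <- sign(d)
  # plateau rule: fill zero slopes with the next nonzero slope so a
  # flat-topped extremum is attributed to its first sample
  nz <- s != 0
  if (!any(nz)) {
    return(new_peak_train(integer(0), integer(0), ts))
  }
  idx <- seq_along(s)
  # backward fill: for each position, the next nonzero sign at or after it;
  # trailing flat tail takes the last nonzero sign (no extremum arises there)
  tmp <- ifelse(nz, idx, length(s) + 1L)
  nxt <- rev(cummin(rev(tmp)))
  last_nz <- max(idx[nz])
  s_filled <- s[ifelse(nxt > length(s), last_nz, nxt)]
  chg <- which(s_filled[-length(s_filled)] != s_filled[-1])
  ext_idx <- chg + 1L                    # sample index of the extremum
  ext_kind <- ifelse(s_filled[chg] > 0, "max", "min")
  if (min_prominence > 0 && length(ext_idx) >= 2) {
    keep <- prune_extrema(v, ext_idx, min_prominence)
    ext_idx <- ext_idx[keep]
    ext_kind <- ext_kind[keep]
  }
  new_peak_train(ext_idx[ext_kind == "max"], ext_idx[ext_kind == "min"], ts)
}

# Iteratively remove the adjacent extrema pair with the smallest
# amplitude span until all spans >= min_prominence.  Removing a pair
# (one max, one min) preserves alternation.
prune_extrema <- function(v, ext_idx, min_prominence) {
  alive <- rep(TRUE, length(ext_idx))
  repeat {
    cur <- which(alive)
    if (length(cur) < 2) break
    spans <- abs(diff(v[ext_idx[cur]]))
    j <- which.min(spans)
    if (spans[j] >= min_prominence) break
    alive[cur[c(j, j + 1L)]] <- FALSE
  }
  alive
}

new_peak_train <- function(peak_idx, valley_idx, ts) {
  peak_idx <- as.integer(peak_idx)
  valley_idx <- as.integer(valley_idx)
  flank <- window_min <- rep(NA_real_, length(peak_idx))
  for (i in seq_along(peak_idx)) {
    left <- valley_idx[valley_idx < peak_idx[i]]
    right <- valley_idx[valley_idx > peak_idx[i]]
    if (length(left) && length(right)) {
      lo <- max(left); hi <- min(right)
      flank[i] <- mean(ts$v[lo:hi])
      window_min[i] <- min(ts$v[lo:hi])
    }
  }
  structure(
    list(peak_idx = peak_idx, valley_idx = valley_idx,
         peak_amp = ts$v[peak_idx], flank_avg = flank,
         window_min = window_min,
         peak_times = ts$t[peak_idx], units = ts$units, fs = ts$fs),
    class = "peak_train"
  )
}

#' @export
print.peak_train <- function(x, ...) {
  cat(sprintf("<peak_train: %d peaks, %d valleys%s>\n",
              length(x$peak_idx), length(x$valley_idx),
              if (nzchar(x$units)) paste0(", ", x$units) else ""))
  invisible(x)
}
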