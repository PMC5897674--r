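# Brute-force oracles kept independent of the package internals.

# O(n*w) sliding-window extrema scan: a sample is a maximum (minimum)
# iff it is >= (<=) everything in a +-w window, strictly greater
# (smaller) than at least one side, and not a plateau continuation.
brute_force_peaks <- function(v, w = length(v)) {
  n <- length(v)
  out <- integer(0)
  for (i in 2:(n - 1)) {
    lo <- max(1, i - w); hi <- min(n, i + w)
    win <- v[lo:hi]
    if (v[i] == max(win) && v[i] > v[i - 1] && v[i] >= v[i + 1])
      out <- c(out, i)
  }
  out
}

# sup |ECDF_x - ECDF_y| over the pooled sample
brute_force_ks2 <- function(x, y) {
  pool <- sort(unique(c(x, y)))
  max(abs(vapply(pool, function(q) mean(x <= q) - mean(y <= q), numeric(1))))
}

# sup |ECDF - Phi((x - m)/s)| for the one-sample statistic (both
# one-sided envelopes around each jump)
brute_force_ks1 <- function(x, m, s) {
  xs <- sort(x)
  n <- length(xs)
  cdf <- pnorm(xs, m, s)
  max(abs(seq_len(n) / n - cdf), abs((seq_len(n) - 1) / n - cdf))
}

# deterministic mid-sized session used by several test files
fixture_session <- function(seed = 5, n_trials = 12, condition = "control") {
  simulate_pointing_session(condition = condition, n_trials = n_trials,
                            seed = seed)
}
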