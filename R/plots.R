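#' Plot the Gamma parameter plane
#'
#' One marker per participant x condition at the fitted (shape,
#' scale), with confidence-interval crosshairs (a horizontal segment
#' over the shape CI and a vertical one over the scale CI). The scale
#' axis reads as the noise-to-signal ratio; the vertical line at
#' shape 1 marks the memoryless Exponential boundary. An optional
#' log-log mode overlays the least-squares power-law line from
#' [loglog_power_fit()].
#'
#' @param points list of [plane_point()]s (>= 1).
#' @param out output file (PDF); `NULL` draws on the active device.
#' @param log_log if `TRUE`, draw on log axes with the fitted line
#'   (needs >= 3 points).
#' @param col_by_condition color markers by condition.
#' @return Invisibly, the `power_law_fit` when `log_log`, else `NULL`.
#' @export
plot_gamma_plane <- function(points, out = NULL, log_log = FALSE,
                             col_by_condition = TRUE) {
  stopifnot(length(points) >= 1,
            all(vapply(points, inherits, logical(1), "plane_point")))
  if (!is.null(out)) {
    grDevices::pdf(out, width = 6, height = 5)
    on.exit(grDevices::dev.off())
  }
  a <- vapply(points, `[[`, numeric(1), "shape")
  b <- vapply(points, `[[`, numeric(1), "scale")
  alo <- vapply(points, function(p) p$ci_shape[1], numeric(1))
  ahi <- vapply(points, function(p) p$ci_shape[2], numeric(1))
  blo <- vapply(points, function(p) p$ci_scale[1], numeric(1))
  bhi <- vapply(points, function(p) p$ci_scale[2], numeric(1))
  conds <- vapply(points, `[[`, character(1), "condition")
  cols <- if (col_by_condition)
    grDevices::hcl.colors(max(1L, length(unique(conds))), "Dark 3")[
      as.integer(factor(conds))]
  else rep("black", length(a))
  graphics::plot(a, b, log = if (log_log) "xy" else "",
                 xlim = range(alo, ahi), ylim = range(blo, bhi),
                 pch = 19, col = cols,
                 xlab = "shape a", ylab = "scale b  (NSR)",
                 main = "Gamma parameter plane")
  graphics::segments(alo, b, ahi, b, col = cols)
  graphics::segments(a, blo, a, bhi, col = cols)
  if (!log_log) graphics::abline(v = 1, lty = 3, col = "grey50")
  fit <- NULL
  if (log_log && length(points) >= 3) {
    fit <- loglog_power_fit(points)
    graphics::curve(exp(fit$intercept) * x^fit$slope, add = TRUE,
                    col = "grey30", lty = 2)
    graphics::legend("topright", bty = "n",
                     legend = sprintf("slope %.2f, intercept %.2f",
                                      fit$slope, fit$intercept))
  }
  if (col_by_condition && length(unique(conds)) > 1)
    graphics::legend("bottomleft", bty = "n", pch = 19,
                     col = grDevices::hcl.colors(length(unique(conds)),
                                                 "Dark 3"),
                     legend = levels(factor(conds)))
  invisible(fit)
}

#' Four-moment scatter of fitted Gamma distributions
#'
#' Projects (mean, variance, skewness) into a 3D scatter where the
#' marker area encodes kurtosis (linear mapping from the kurtosis
#' range to `cex_range`) and the face color encodes the median raw
#' physical value of the underlying peaks; arrows connect each
#' participant's markers in the declared condition order, tracing the
#' stochastic shift.
#'
#' @param entries list of lists, each with `moments` (a
#'   [`gamma_moments`][gamma_moments()]), `raw_median`, `condition`,
#'   and optionally `participant_id`.
#' @param out output file (PDF); `NULL` draws on the active device.
#' @param condition_order order in which arrows connect conditions.
#' @param cex_range marker size range mapped onto the kurtosis range.
#' @return `out`, invisibly.
#' @export
plot_moments_scatter <- function(entries, out = NULL,
                                 condition_order = NULL,
                                 cex_range = c(1, 3)) {
  stopifnot(length(entries) >= 1)
  if (!is.null(out)) {
    grDevices::pdf(out, width = 6, height = 6)
    on.exit(grDevices::dev.off())
  }
  mx <- vapply(entries, function(e) e$moments$mean, numeric(1))
  my <- vapply(entries, function(e) e$moments$variance, numeric(1))
  mz <- vapply(entries, function(e) e$moments$skewness, numeric(1))
  kur <- vapply(entries, function(e) e$moments$kurtosis, numeric(1))
  med <- vapply(entries, function(e) e$raw_median, numeric(1))
  conds <- vapply(entries, function(e) e$condition, character(1))
  pid <- vapply(entries, function(e) e$participant_id %||% "", character(1))
  cex <- if (diff(range(kur)) == 0) rep(mean(cex_range), length(kur))
         else cex_range[1] + diff(cex_range) *
           (kur - min(kur)) / diff(range(kur))
  pal <- grDevices::hcl.colors(64, "Viridis")
  fcol <- if (diff(range(med, na.rm = TRUE)) == 0 || all(is.na(med)))
    rep(pal[32], length(med))
  else pal[1 + round(63 * (med - min(med, na.rm = TRUE)) /
                       diff(range(med, na.rm = TRUE)))]
  pad <- function(r) r + c(-1, 1) * max(diff(r), 1e-6) * 0.15
  pmat <- graphics::persp(x = pad(range(mx)), y = pad(range(my)),
                          z = matrix(rep(pad(range(mz)), 2), 2),
                          theta = 35, phi = 20, border = NA, col = NA,
                          xlab = "mean", ylab = "variance",
                          zlab = "skewness", ticktype = "detailed",
                          main = "Gamma moments (size = kurtosis)")
  pr <- grDevices::trans3d(mx, my, mz, pmat)
  ecol <- grDevices::hcl.colors(max(1L, length(unique(conds))), "Dark 3")[
    as.integer(factor(conds))]
  order_c <- condition_order %||% unique(conds)
  for (p in unique(pid)) {
    sel <- which(pid == p)
    sel <- sel[order(match(conds[sel], order_c))]
    if (length(sel) > 1)
      graphics::arrows(pr$x[sel[-length(sel)]], pr$y[sel[-length(sel)]],
                       pr$x[sel[-1]], pr$y[sel[-1]],
                       length = 0.08, col = "grey40")
  }
  graphics::points(pr$x, pr$y, pch = 21, bg = fcol, col = ecol, cex = cex)
  invisible(out)
}
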