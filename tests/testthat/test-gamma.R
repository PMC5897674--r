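test_that("Freedman-Diaconis width follows 2*IQR*n^(-1/3)", {
  set.seed(1)
  x <- runif(1000)
  h <- fd_histogram(x)
  expect_equal(h$width, 2 * IQR(x) * 1000^(-1 / 3), tolerance = 0.02)
  expect_equal(h$width, 0.1, tolerance = 0.05)      # known uniform(0,1) IQR
  expect_equal(sum(h$counts), 1000)
})

test_that("histogram counts are conserved and degenerate input falls back", {
  set.seed(2)
  for (x in list(rgamma(50, 2, scale = 1), rnorm(200), rexp(31))) {
    h <- fd_histogram(x)
    expect_equal(sum(h$counts), length(x))
    expect_gte(length(h$counts), 2)
  }
  expect_warning(hc <- fd_histogram(rep(3, 10)), "degenerate")
  expect_length(hc$counts, 2)
  expect_equal(max(hc$counts), 10)        # all mass in one bin
  expect_error(fd_histogram(c(1, 2, 3)), "at least 4")
})

test_that("gamma_pdf matches the closed form and normalizes to 1", {
  expect_equal(gamma_pdf(0, 1, 1), 1)
  expect_equal(gamma_pdf(0, 2, 1), 0)
  expect_equal(gamma_pdf(0, 0.5, 1), Inf)
  # quadrature normalization for several shapes
  for (a in c(0.5, 1, 5)) {
    q <- integrate(gamma_pdf, 0, 50, shape = a, scale = 1,
                   rel.tol = 1e-9, subdivisions = 500L)
    expect_equal(q$value, 1, tolerance = 1e-6)
  }
  # closed-form mode at (a-1)*b for a > 1
  grid <- seq(0.001, 10, by = 0.001)
  for (a in c(1.5, 2, 7)) {
    b <- 0.6
    expect_equal(grid[which.max(gamma_pdf(grid, a, b))], (a - 1) * b,
                 tolerance = 0.002)
  }
  # agrees with the standard parameterization everywhere
  x <- seq(0.01, 8, by = 0.07)
  expect_equal(gamma_pdf(x, 2.3, 0.7), dgamma(x, shape = 2.3, scale = 0.7),
               tolerance = 1e-12)
})

test_that("MLE recovers parameters and matches an independent fitter", {
  set.seed(5)
  x <- rgamma(10000, shape = 2, scale = 0.5)
  fit <- fit_gamma_mle(x)
  expect_gte(2, fit$ci_shape[1]); expect_lte(2, fit$ci_shape[2])
  expect_gte(0.5, fit$ci_scale[1]); expect_lte(0.5, fit$ci_scale[2])
  # cross-check point estimates against MASS::fitdistr
  ref <- MASS::fitdistr(x, "gamma")
  expect_equal(fit$shape, unname(ref$estimate["shape"]), tolerance = 1e-4)
  expect_equal(fit$scale, 1 / unname(ref$estimate["rate"]), tolerance = 1e-4)
})

test_that("the fitted point is a local likelihood maximum", {
  set.seed(6)
  x <- rgamma(2000, shape = 3, scale = 2)
  fit <- fit_gamma_mle(x)
  ll <- function(a, b) sum(dgamma(x, shape = a, scale = b, log = TRUE))
  base <- ll(fit$shape, fit$scale)
  for (da in c(-1e-3, 1e-3)) for (db in c(-1e-3, 1e-3))
    expect_gte(base, ll(fit$shape + da, fit$scale + db))
  expect_equal(fit$loglik, base, tolerance = 1e-8)
})

test_that("MLE shape is scale-equivariant and input is validated", {
  set.seed(7)
  x <- rgamma(500, shape = 2.5, scale = 0.2)
  f1 <- fit_gamma_mle(x)
  f2 <- fit_gamma_mle(x * 7.3)
  expect_equal(f2$shape, f1$shape, tolerance = 1e-12)
  expect_equal(f2$scale, f1$scale * 7.3, tolerance = 1e-12)
  expect_error(fit_gamma_mle(c(x, -1)), "positive")
  expect_error(fit_gamma_mle(x[1:5]), "at least 10")
  expect_warning(fit_gamma_mle(x[1:50]), "fewer than 100")
  expect_error(suppressWarnings(fit_gamma_mle(rep(2, 20))), "degenerate")
})

test_that("MLE bias shrinks as the sample grows", {
  biases <- vapply(c(100, 1000, 10000), function(n) {
    set.seed(n)
    mean(vapply(1:40, function(i)
      suppressWarnings(fit_gamma_mle(rgamma(n, 2, scale = 0.5)))$shape,
      numeric(1))) - 2
  }, numeric(1))
  expect_true(all(diff(abs(biases)) < 0))
})

test_that("moments obey the closed forms and the NSR identity", {
  m <- gamma_moments(list(shape = 4, scale = 0.25))
  expect_equal(m$mean, 1.0)
  expect_equal(m$variance, 0.25)
  expect_equal(m$nsr, 0.25)
  expect_equal(m$skewness, 1.0)            # 2/sqrt(4)
  mexp <- gamma_moments(list(shape = 1, scale = 2))
  expect_equal(mexp$skewness, 2.0)
  expect_equal(mexp$kurtosis, 9.0)         # exponential case
})

test_that("log-log fit recovers slope -1 exactly for constant mean", {
  a <- c(0.8, 1.5, 3, 6, 12)
  b <- 0.76 / a
  fit <- loglog_power_fit(a, b)
  expect_equal(fit$slope, -1, tolerance = 1e-12)
  expect_equal(fit$intercept, log(0.76), tolerance = 1e-12)
  fit10 <- loglog_power_fit(a, b, log_base = "base10")
  expect_equal(fit10$intercept, log10(0.76), tolerance = 1e-12)
  expect_equal(fit10$slope, -1, tolerance = 1e-12)
})

test_that("log-log fit degrades gracefully under perturbation, errors on rank deficiency", {
  set.seed(8)
  a <- exp(runif(30, log(0.5), log(8)))
  b <- 0.76 * exp(rnorm(30, 0, 0.05)) / a    # means vary by ~5%
  fit <- loglog_power_fit(a, b)
  expect_gte(fit$slope, -1.05); expect_lte(fit$slope, -0.95)
  expect_error(loglog_power_fit(rep(2, 5), rep(0.3, 5)), "degenerate")
  expect_error(loglog_power_fit(c(1, 2), c(1, 2)), "at least 3")
})

test_that("two-sample KS equals the brute-force ECDF supremum", {
  set.seed(9)
  for (rep in 1:5) {
    x <- rgamma(40 + rep, 2, scale = 1)
    y <- rgamma(60, 2.5, scale = 0.8)
    ks <- ks_two_sample(x, y)
    expect_equal(ks$D, brute_force_ks2(x, y), tolerance = 1e-12)
  }
  x <- rgamma(50, 2, scale = 1)
  same <- ks_two_sample(x, x)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  far <- ks_two_sample(x, x + 10)
  expect_equal(far$D, 1)                   # disjoint supports
})

test_that("one-sample KS against the moment-matched normal uses the ECDF supremum", {
  set.seed(10)
  x <- rgamma(150, 2, scale = 0.1)
  ks <- ks_vs_normal(x)
  expect_equal(ks$D, brute_force_ks1(x, mean(x), sd(x)), tolerance = 1e-12)
  expect_error(ks_vs_normal(rep(1, 30)), "zero-variance")
  expect_error(ks_vs_normal(rnorm(10)), "at least 20")
})

test_that("normality KS rejects skewed Gamma, accepts the Gaussian limit", {
  set.seed(11)
  skewed <- rgamma(500, shape = 2, scale = 0.1)
  expect_lt(ks_vs_normal(skewed)$p, 0.01)
  nearly_normal <- rgamma(500, shape = 1000, scale = 0.001)
  expect_gt(ks_vs_normal(nearly_normal)$p, 0.05)
  # the Monte-Carlo corrected p also rejects for the skewed sample
  mc <- ks_vs_normal(skewed, mc_correct = TRUE, n_mc = 200)
  expect_lt(mc$p_mc, 0.05)
})

test_that("candidate-family comparison prefers the generating family", {
  set.seed(12)
  cmp <- compare_distribution_fits(rgamma(2000, shape = 3, scale = 0.5))
  expect_equal(cmp$family[1], "gamma")
  cmp2 <- compare_distribution_fits(rlnorm(2000, 0, 0.8))
  expect_equal(cmp2$family[1], "lognormal")
})

test_that("condition shift report detects separation and respects the null", {
  set.seed(13)
  # under the null (same Gamma law) the pairwise KS p is rarely small:
  # check in aggregate rather than on a single draw
  null_p <- vapply(1:20, function(i) {
    s <- list(c1 = rgamma(500, 2, scale = 0.1),
              c2 = rgamma(500, 2, scale = 0.1))
    condition_shift_report(s)$pairwise$p[1]
  }, numeric(1))
  expect_gte(mean(null_p > 0.05), 0.8)
  sep <- list(low = rgamma(500, 2, scale = 0.1),
              high = rgamma(500, 4, scale = 0.1))
  rep_sep <- condition_shift_report(sep, sample_label = "AM")
  expect_lt(rep_sep$pairwise$p[1], 0.01)
  expect_length(rep_sep$plane_points, 2)
  # the strongly skewed (shape 2) condition departs from normality
  expect_lt(rep_sep$normality$p[rep_sep$normality$condition == "low"], 0.05)
  expect_true(all(is.finite(rep_sep$normality$p)))
  expect_equal(rep_sep$condition_order, c("low", "high"))
  expect_true(all(c("p", "p_adj") %in% names(rep_sep$pairwise)))
  # NSR identity holds for every fit in the report
  for (cn in names(rep_sep$fits))
    expect_identical(gamma_moments(rep_sep$fits[[cn]])$nsr,
                     rep_sep$fits[[cn]]$scale)
})
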