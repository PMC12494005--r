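test_that("the mixture density integrates to 1 for random valid parameters", {
  set.seed(10)
  for (i in 1:25) {
    p <- mixture_params(w = runif(1), kappa = exp(runif(1, log(0.2), log(50))))
    z <- stats::integrate(mixture_pdf, -1, 1,
      params = p,
      rel.tol = 1e-9, subdivisions = 400
    )$value
    expect_equal(z, 1, tolerance = 1e-6)
  }
})

test_that("pure components behave as labelled", {
  g <- mixture_params(w = 0, kappa = 5)
  x <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(mixture_pdf(x, g), mixture_pdf(-x, g), tolerance = 1e-12)

  gam <- mixture_params(w = 1, kappa = 15)
  mass_high <- stats::integrate(mixture_pdf, 0.8, 1, params = gam)$value
  expect_gt(mass_high, 0.9)
})

test_that("the gamma-component mean score increases with kappa", {
  mean_score <- function(kappa) {
    p <- mixture_params(w = 1, kappa = kappa)
    stats::integrate(function(s) s * mixture_pdf(s, p), -1, 1,
      rel.tol = 1e-9, subdivisions = 400
    )$value
  }
  grid <- c(0.5, 1, 2, 4, 8, 16, 32)
  means <- vapply(grid, mean_score, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("null MSE has its closed forms", {
  uniform <- rep(1 / 21, 21)
  expect_equal(null_mse(uniform), 0)
  point <- c(1, rep(0, 20))
  expect_equal(null_mse(point), ((1 - 1 / 21)^2 + 20 * (1 / 21)^2) / 21)
  set.seed(2)
  h <- score_histogram(runif(100, -1, 1))
  expect_gte(null_mse(h), 0)
})

test_that("fits recover generating parameters and beat the null", {
  set.seed(12)
  s <- r_mixture(20000, mixture_params(0.5, 8))
  f <- fit_mixture(s)
  expect_lt(abs(f$params$w - 0.5), 0.05)
  expect_lt(abs(f$params$kappa / 8 - 1), 0.2)
  expect_lte(f$mse_fit, f$mse_null)
  expect_equal(f$mse_ratio_pct, 100 * f$mse_fit / f$mse_null)

  # pure baseline-like sample pushes w to the boundary
  s0 <- r_mixture(20000, mixture_params(0, 5))
  f0 <- fit_mixture(s0)
  expect_lt(f0$params$w, 0.05)
})

test_that("multistart fitting is stable across RNG states", {
  set.seed(13)
  s <- r_mixture(5000, mixture_params(0.7, 10))
  h <- score_histogram(s)
  f1 <- withr::with_seed(1, fit_mixture(h, n_starts = 25))
  f2 <- withr::with_seed(999, fit_mixture(h, n_starts = 10))
  expect_lt(abs(f1$loss - f2$loss), 1e-8)
})

test_that("degenerate histograms are flagged unreliable", {
  expect_warning(f <- fit_mixture(rep(0, 50)), "unreliable")
  expect_true(f$unreliable)
})

test_that("bootstrap SEs are deterministic, zero for B = 1, and shrink with n", {
  set.seed(14)
  s <- r_mixture(400, mixture_params(0.6, 8))
  one <- withr::with_seed(1, bootstrap_fit(s, B = 1))
  expect_equal(one$se_w, 0)
  expect_equal(one$se_kappa, 0)

  b1 <- withr::with_seed(7, bootstrap_fit(s, B = 50))
  b2 <- withr::with_seed(7, bootstrap_fit(s, B = 50))
  expect_identical(b1$se_w, b2$se_w)

  set.seed(15)
  small <- r_mixture(500, mixture_params(0.6, 8))
  big <- r_mixture(2000, mixture_params(0.6, 8))
  se_small <- withr::with_seed(2, bootstrap_fit(small, B = 300))$se_w
  se_big <- withr::with_seed(3, bootstrap_fit(big, B = 300))$se_w
  expect_lt(abs(se_small / se_big - 2), 0.5)
})

test_that("tidy and glance expose the fit in broom shape", {
  set.seed(16)
  f <- fit_mixture(r_mixture(2000, mixture_params(0.6, 8)))
  td <- tidy(f)
  expect_equal(td$term, c("w", "kappa"))
  expect_true(all(c("mse_fit", "mse_null", "mse_ratio_pct") %in% names(glance(f))))
  expect_s3_class(autoplot(f), "ggplot")
})
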