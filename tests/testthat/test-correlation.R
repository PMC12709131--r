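test_that("cumulative trapezoid handles the standard cases", {
  expect_equal(cumulative_trapezoid(c(0, 2, 5, 10), rep(3, 4)),
               c(0, 6, 15, 30))                       # constant: a*T
  expect_equal(cumulative_trapezoid(0, 7), 0)          # single point
  expect_equal(cumulative_trapezoid(c(0, 1), c(0, 2)), c(0, 1))
  expect_error(cumulative_trapezoid(c(0, 1), c(1, 2, 3)), "length")
  expect_error(cumulative_trapezoid(c(0, 0, 1), c(1, 2, 3)), "increasing")
})

test_that("trapezoid cumulative is exact under grid refinement for linear integrands", {
  f <- function(t) 2 * t + 1
  coarse <- seq(0, 100, by = 25)
  fine <- seq(0, 100, by = 5)
  cc <- cumulative_trapezoid(coarse, f(coarse))
  cf <- cumulative_trapezoid(fine, f(fine))
  expect_equal(cc[length(cc)], cf[length(cf)])
  expect_equal(cf[fine %in% coarse], cc)
})

test_that("fit_linear matches the closed-form oracle and handles edge cases", {
  f <- fit_linear(1:10, 500 * (1:10))
  expect_equal(f$slope, 500)
  expect_equal(f$intercept, 0, tolerance = 1e-10)
  expect_equal(f$r_squared, 1)

  fc <- fit_linear(1:5, rep(2, 5))
  expect_equal(fc$slope, 0)
  expect_equal(fc$r_squared, 0)

  expect_error(fit_linear(rep(1, 5), 1:5), "degenerate")
  expect_error(fit_linear(1, 1), "at least 2")

  set.seed(33)
  for (k in 1:100) {
    n <- sample(5:50, 1)
    x <- stats::rnorm(n)
    y <- stats::rnorm(n)
    got <- fit_linear(x, y)
    ora <- ols_oracle(x, y)
    for (fld in names(ora))  # mixed tolerance: near-zero stats agree to ulps
      expect_lt(abs(got[[fld]] - ora[[fld]]), 1e-12 * (1 + abs(ora[[fld]])))
  }
})

test_that("slope recovery on noisy proportional data is within sampling error", {
  set.seed(5)
  n <- 1e4
  x <- stats::runif(n)
  y <- x + stats::rnorm(n, 0, 0.01)
  f <- fit_linear(x, y)
  expect_lt(abs(f$slope - 1), 3 * f$se_slope)
  expect_lt(abs(f$intercept), 3 * f$se_intercept)
})

make_exact_series <- function(concs, kappa = 500, sigma_bleach = NULL) {
  # zero-noise ensemble; optionally disable bleaching via sigma_bleach = 0
  params <- if (is.null(sigma_bleach)) soed_parameters() else
    soed_parameters(sigma = sigma_bleach)
  B <- make_basis()
  lapply(concs, function(cc) {
    sim <- simulate_series(phantom_spec(cc), irradiation_protocol(),
                           params = params, basis = B,
                           noise = noise_config(sigma = 0),
                           kappa_detect = kappa)
    dose_time_series(unmix_series(sim$spectra, B), sim$trajectory,
                     label = paste0(cc, "mgL"))
  })
}

test_that("exact proportionality gives the detection scale at every time", {
  series <- make_exact_series(c(2, 4, 6), kappa = 500, sigma_bleach = 0)
  fits <- correlate_instantaneous(series, at_times = c(1, 450, 900))
  slopes <- vapply(fits, function(f) f$slope, 0)
  expect_equal(unname(slopes), rep(500, 3), tolerance = 1e-8)
  expect_true(all(abs(vapply(fits, function(f) f$intercept, 0)) < 1e-6))
  cum <- correlate_cumulative(series)
  expect_equal(cum$slope, 500, tolerance = 1e-8)
  expect_gt(cum$r_squared, 1 - 1e-10)
  expect_equal(cum$intercept, 0, tolerance = 1e-6)
})

test_that("cumulative regression on a bleaching zero-noise ensemble is exact", {
  series <- make_exact_series(c(2, 3, 4, 5, 6))
  cum <- correlate_cumulative(series)
  expect_equal(cum$slope, 500, tolerance = 1e-8)
  expect_gt(cum$r_squared, 1 - 1e-10)
})

test_that("instantaneous correlation needs coverage and at least two phantoms", {
  series <- make_exact_series(c(2, 4), sigma_bleach = 0)
  expect_error(correlate_instantaneous(series[1]), "at least 2")
  expect_error(correlate_instantaneous(series, at_times = 2000), "cadence")
  expect_error(correlate_cumulative(series[2]), "at least 2")
  # t = 450 is equidistant from acquisitions at 400 and 500: earlier one wins
  expect_identical(soxdosim:::nearest_acquisition(seq(0, 900, 100), 450, 100), 5L)
})

test_that("photobleaching fits recover the generating line", {
  t <- seq(0, 900, 100)
  expect_equal(photobleach_fit(t, rep(1, 10))$slope, 0)
  f <- photobleach_fit(t, 1 - 1e-4 * t)
  expect_equal(f$slope, -1e-4)
  expect_equal(f$r_squared, 1)

  # end-to-end: noiseless fluorescence pipeline reproduces the least-squares
  # line of the generator's bleaching curve
  fb <- make_fluorescence_basis()
  ps <- spectrum(fb$wavelengths, fb$components[, "ps"])
  bg <- spectrum(fb$wavelengths, fb$components[, "bg"])
  sim <- simulate_fluorescence_series(phantom_spec(6),
                                      irradiation_protocol(duration_s = 300),
                                      basis = fb, noise = noise_config(sigma = 0))
  out <- fluorescence_series(sim$spectra, ps, bg)
  got <- photobleach_fit(out$t_s, out$rel_concentration)
  want <- ols_oracle(sim$truth$t_s, sim$truth$rel_S0)
  expect_equal(got$slope, want$slope, tolerance = 1e-8)
  expect_equal(got$intercept, want$intercept, tolerance = 1e-8)
})
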