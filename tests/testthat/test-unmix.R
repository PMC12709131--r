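test_that("exact mixtures are recovered exactly", {
  B <- toy_basis()
  s <- spectrum(B$wavelengths, drop(B$components %*% c(2, 3, 1)))
  u <- svd_unmix(s, B)
  expect_equal(unname(u$amplitudes), c(2, 3, 1), tolerance = 1e-10)
  expect_lt(u$residual_rms, 1e-10 * sqrt(mean(s$intensities^2)))
  expect_equal(u$fitted, s$intensities, tolerance = 1e-10)
})

test_that("a spectrum orthogonal to the basis yields zero amplitudes", {
  wl <- seq(1200, 1600, length.out = 40)
  B <- basis_matrix(wl, cbind(a = rep(1, 40),
                              b = sin(2 * pi * (wl - 1200) / 400)))
  # orthogonalise a test vector against both columns
  y <- cos(2 * pi * 3 * (wl - 1200) / 400)
  for (j in 1:2) {
    col <- B$components[, j]
    y <- y - sum(y * col) / sum(col^2) * col
  }
  # re-orthogonalise against the first column (columns are not orthogonal)
  y <- y - sum(y * B$components[, 1]) / sum(B$components[, 1]^2) * B$components[, 1]
  u <- svd_unmix(spectrum(wl, y), B)
  expect_equal(unname(u$amplitudes), c(0, 0), tolerance = 1e-8)
  expect_equal(u$residual_rms, sqrt(mean(y^2)), tolerance = 1e-8)
})

test_that("SVD solution matches the normal-equations oracle on random instances", {
  set.seed(101)
  for (k in 1:100) {
    m <- sample(10:60, 1)
    p <- sample(2:4, 1)
    B <- matrix(stats::rnorm(m * p), m, p) + 2 * diag(nrow = m, ncol = p)
    colnames(B) <- paste0("c", 1:p)
    wl <- seq_len(m) + 1000
    bm <- basis_matrix(wl, B)
    y <- stats::rnorm(m)
    a_pkg <- svd_unmix(spectrum(wl, y), bm)$amplitudes
    a_ora <- normal_eq_oracle(B, y)
    expect_lt(max(abs(a_pkg - a_ora)) / max(abs(a_ora)), 1e-8)
  }
})

test_that("unconstrained amplitudes are linear in the input", {
  B <- toy_basis()
  set.seed(7)
  x <- stats::rnorm(length(B$wavelengths))
  y <- stats::rnorm(length(B$wavelengths))
  ax <- svd_unmix(spectrum(B$wavelengths, x), B)$amplitudes
  ay <- svd_unmix(spectrum(B$wavelengths, y), B)$amplitudes
  axy <- svd_unmix(spectrum(B$wavelengths, 2 * x + 3 * y), B)$amplitudes
  expect_equal(axy, 2 * ax + 3 * ay, tolerance = 1e-9)
})

test_that("non-negative refinement clips model mismatch without breaking consistency", {
  B <- toy_basis()
  # consistent non-negative mixture: constraint inactive, same answer
  s <- spectrum(B$wavelengths, drop(B$components %*% c(2, 3, 1)))
  expect_equal(unname(svd_unmix(s, B, nonneg = TRUE)$amplitudes), c(2, 3, 1),
               tolerance = 1e-8)
  # mixture with a negative true coefficient: constrained fit is >= 0 and
  # no worse than dropping the offending component
  s2 <- spectrum(B$wavelengths, drop(B$components %*% c(2, -1, 1)))
  u2 <- svd_unmix(s2, B, nonneg = TRUE)
  expect_true(all(u2$amplitudes >= 0))
  u_free <- svd_unmix(s2, B)
  expect_lt(u_free$amplitudes[["phos"]], 0)   # unconstrained fit reports mismatch
  expect_gte(u2$residual_rms, u_free$residual_rms)
})

test_that("noisy amplitude recovery is unbiased over repeated draws", {
  B <- make_basis(basis_shape_config(grid = wavelength_grid(1200, 1600, 128)))
  truth <- c(o2 = 4, phos = 2, bg = 0.5)
  peak <- max(B$components %*% truth)
  n_rep <- 200
  rec <- matrix(NA_real_, n_rep, 3)
  for (k in seq_len(n_rep)) {
    q <- simulate_quench_pair(B, a_o2 = 4, a_phos = 2, a_bg = 0.5, r = 0,
                              noise = noise_config(sigma = 0.01 * peak, seed = 1000 + k))
    rec[k, ] <- svd_unmix(q$pre, B)$amplitudes
  }
  mu <- colMeans(rec)
  se <- apply(rec, 2, stats::sd) / sqrt(n_rep)
  expect_true(all(abs(mu - truth) < 3 * se))
})

test_that("quench difference requires matching grids and subtracts pointwise", {
  wl <- seq(1200, 1600, length.out = 16)
  a <- spectrum(wl, sin(wl / 40))
  expect_equal(quench_difference(a, a)$intensities, rep(0, 16))
  b <- spectrum(seq(1200, 1600, length.out = 17), rep(1, 17))
  expect_error(quench_difference(a, b), "grid")
})

test_that("unmix_series orders by time and recovers the bleaching dynamics", {
  B <- make_basis()
  # short protocol keeps all components within float range of each other
  pr <- irradiation_protocol(duration_s = 300, cadence_s = 100)
  sim <- simulate_series(phantom_spec(6), pr, basis = B,
                         noise = noise_config(sigma = 0))
  shuffled <- sim$spectra[c(3, 1, 4, 2)]
  out <- unmix_series(shuffled, B)
  expect_equal(out$t_s, c(0, 100, 200, 300))
  expect_equal(out$a_o2, sim$truth$a_o2, tolerance = 1e-8)
  expect_equal(out$a_phos, sim$truth$a_phos, tolerance = 1e-8)
  one <- unmix_series(sim$spectra[2], B)
  expect_equal(nrow(one), 1L)
  expect_error(unmix_series(list(), B), "empty")
})

test_that("smoothing before fitting leaves exact mixtures nearly unchanged", {
  B <- make_basis()
  pr <- irradiation_protocol(duration_s = 200, cadence_s = 100)
  sim <- simulate_series(phantom_spec(6), pr, basis = B,
                         noise = noise_config(sigma = 0))
  sm <- unmix_series(sim$spectra, B, smooth = TRUE)
  expect_equal(sm$a_o2, sim$truth$a_o2, tolerance = 0.05)
})

test_that("fluorescence unmixing recovers amplitudes and relative bleaching", {
  fb <- make_fluorescence_basis()
  ps <- spectrum(fb$wavelengths, fb$components[, "ps"])
  bg <- spectrum(fb$wavelengths, fb$components[, "bg"])
  s <- spectrum(fb$wavelengths, 4 * fb$components[, "ps"])
  u <- fluorescence_unmix(s, ps, bg, n_fourier = 1)
  expect_equal(u$amplitudes[["ps"]], 4, tolerance = 1e-10)
  expect_equal(unname(u$amplitudes[c("cos1", "sin1")]), c(0, 0),
               tolerance = 1e-9)
  u0 <- fluorescence_unmix(s, ps, bg, n_fourier = 0)
  expect_length(u0$amplitudes, 2)
  expect_equal(u0$amplitudes[["ps"]], 4, tolerance = 1e-10)

  sim <- simulate_fluorescence_series(phantom_spec(6),
                                      irradiation_protocol(duration_s = 300),
                                      basis = fb, noise = noise_config(sigma = 0))
  out <- fluorescence_series(sim$spectra, ps, bg)
  expect_equal(out$rel_concentration, sim$truth$rel_S0, tolerance = 1e-8)
})
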