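table2_printed <- function() {
  vals <- rbind(c(1.19, 1.33, 1.48, 1.62, 1.89),
                c(0.88, 1.00, 1.12, 1.23, 1.43),
                c(0.80, 0.87, 0.97, 1.08, 1.25),
                c(0.74, 0.84, 0.91, 1.00, 1.18),
                c(0.74, 0.83, 0.90, 1.02, 1.17))
  dimnames(vals) <- list(c(5, 10, 15, 20, 40), c(0.1, 0.3, 0.5, 0.7, 1.0))
  vals
}

test_that("the packaged correction-factor grid matches the measured table", {
  tb <- cf_table()
  expect_equal(tb$cf, table2_printed())
  expect_equal(as.numeric(cf_lookup(tb, optical_properties(0.3, 10))), 1.00)
  expect_equal(as.numeric(cf_lookup(tb, optical_properties(1.0, 5))), 1.89)
  # every node reproduces exactly
  for (musp in tb$musp_grid)
    for (mua in tb$mua_grid)
      expect_identical(as.numeric(cf_lookup(tb, optical_properties(mua, musp))),
                       table2_printed()[as.character(musp), as.character(mua)])
})

test_that("bilinear interpolation is exact at nodes, bounded between them, and clamps", {
  tb <- cf_table()
  expect_equal(as.numeric(cf_lookup(tb, optical_properties(0.2, 10))),
               (0.88 + 1.00) / 2)                     # midpoint of printed nodes
  set.seed(2)
  for (k in 1:50) {
    mua <- stats::runif(1, 0.1, 1.0)
    musp <- stats::runif(1, 5, 40)
    v <- as.numeric(cf_lookup(tb, optical_properties(mua, musp)))
    i <- findInterval(musp, tb$musp_grid, rightmost.closed = TRUE)
    j <- findInterval(mua, tb$mua_grid, rightmost.closed = TRUE)
    corners <- tb$cf[i:(i + 1), j:(j + 1)]
    expect_gte(v, min(corners) - 1e-12)
    expect_lte(v, max(corners) + 1e-12)
  }
  expect_warning(v <- cf_lookup(tb, optical_properties(2.0, 10)), "clamped")
  expect_equal(as.numeric(v), 1.43)                    # clamped to the mua edge
  expect_true(attr(v, "clamped"))
  expect_error(optical_properties(-0.1, 10), ">= 0")
})

test_that("correction factors are applied multiplicatively", {
  tb <- cf_table()
  expect_equal(apply_cf(100, optical_properties(0.3, 10), tb), 100)
  expect_equal(apply_cf(0, optical_properties(0.7, 15), tb), 0)
  expect_equal(apply_cf(100, optical_properties(1.0, 5), tb), 189)
  expect_error(apply_cf(Inf, optical_properties(0.3, 10), tb), "finite")
})

test_that("signal-ratio correction factors behave as ratios", {
  expect_equal(compute_cf_from_signals(0.5, 0.5), 1)
  expect_equal(compute_cf_from_signals(0.25, 0.5), 2)
  expect_error(compute_cf_from_signals(0, 1), "> 0")
})

test_that("the transport estimator is deterministic and validates input", {
  op <- optical_properties(0.3, 10)
  a <- mc_detected_signal(op, n_photons = 2e3, seed = 9)
  b <- mc_detected_signal(op, n_photons = 2e3, seed = 9)
  expect_identical(a, b)
  expect_error(mc_detected_signal(op, n_photons = 500), "1000")
  expect_error(mc_detected_signal(optical_properties(0, 10), n_photons = 2e3),
               "mua")
})

test_that("overwhelming absorption extinguishes the detected signal", {
  weak <- mc_detected_signal(optical_properties(0.1, 10), n_photons = 1e4,
                             seed = 3, estimator = "next_event")
  strong <- mc_detected_signal(optical_properties(1e3, 10), n_photons = 1e4,
                               seed = 3, estimator = "next_event")
  expect_lt(strong$signal, 1e-3 * weak$signal)
})

test_that("analog and next-event estimators agree on the same physics", {
  for (cl in list(c(0.3, 10), c(1.0, 5))) {
    op <- optical_properties(cl[1], cl[2])
    ra <- mc_detected_signal(op, n_photons = 1e5, seed = 21, estimator = "analog")
    rn <- mc_detected_signal(op, n_photons = 5e4, seed = 22,
                             estimator = "next_event")
    z <- (ra$signal - rn$signal) / sqrt(ra$se^2 + rn$se^2)
    expect_lt(abs(z), 4)
  }
})

test_that("standard error scales as one over the square root of photon count", {
  op <- optical_properties(0.3, 10)
  ns <- c(1e3, 1e4, 1e5)
  ses <- vapply(ns, function(n) {
    mc_detected_signal(op, n_photons = n, seed = 40 + log10(n),
                       estimator = "next_event")$se
  }, 0)
  # 1/sqrt(n): ratio ~sqrt(10) = 3.16 per decade, ~10 over two decades
  r1 <- ses[1] / ses[2]
  r2 <- ses[2] / ses[3]
  expect_gt(r1, 1.8); expect_lt(r1, 5.5)
  expect_gt(r2, 1.8); expect_lt(r2, 5.5)
  expect_gt(ses[1] / ses[3], 5); expect_lt(ses[1] / ses[3], 20)
})

test_that("the MC correction factor is 1 at the reference point by construction", {
  g <- mc_cf_grid(mua_grid = 0.3, musp_grid = 10, n_photons = 2e3, seed = 12)
  expect_equal(as.numeric(g$cf[1, 1]), 1)   # same seed, same cell as reference
})
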