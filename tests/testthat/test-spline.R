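test_that("zero-smoothing spline interpolates the samples exactly", {
  x <- seq(1, 6, 0.5)
  y <- 0.2 + 0.1 * x - 0.03 * x^2 + 0.002 * x^3
  cs <- fit_spline(x, y, smoothing = "none")
  expect_equal(cs$fun(x), y, tolerance = 1e-10)
  cs0 <- fit_spline(x, y, smoothing = 0)
  expect_equal(cs0$fun(x), y, tolerance = 1e-10)
})

test_that("spline fitting enforces its preconditions", {
  expect_error(fit_spline(c(1, 2, 3), c(1, 1, 1)), "at least 4")
  expect_error(fit_spline(c(1, 3, 2, 4), rep(1, 4)), "increasing")
  expect_error(fit_spline(1:4, c(1, NA, 1, 1)), "non-finite")
  expect_error(fit_spline(1:4, rep(1, 4), smoothing = "bogus"), "smoothing")
})

test_that("dense spline evaluation tracks the simulator", {
  sp <- default_spectra()
  # CEST spectrum: broad features, interpolation follows the model closely
  cc <- fit_spline(sp$cest_offsets, sp$cest_z, smoothing = "none")
  dc <- seq(1.25, 6.55, by = 0.01)
  oc <- z_spectrum(sp$sys, dc, cest_schedule()$b1_amplitude,
                   cest_schedule()$sat_duration, 7)
  expect_lt(max(abs(cc$fun(dc) - oc)), 5e-3)
  # WASSR spectrum: the narrow direct-saturation dip limits pointwise
  # fidelity near the center; the shoulders stay accurate and the
  # minimum location (what WASSR is used for) is tested in test-b0
  cs <- fit_spline(sp$wassr_offsets, sp$wassr_z, smoothing = "none")
  dense <- seq(-0.58, 0.58, by = 0.004)
  oracle <- z_spectrum(sp$sys, dense, wassr_schedule()$b1_amplitude,
                       wassr_schedule()$sat_duration, 7)
  shoulders <- abs(dense) > 0.1
  expect_lt(max(abs(cs$fun(dense) - oracle)[shoulders]), 1.5e-2)
})

test_that("sample_mz reads the 1-Hz grid and respects the domain", {
  sp <- default_spectra()
  cs <- fit_spline(sp$cest_offsets, sp$cest_z, smoothing = "none")
  # an acquisition offset is (almost) on the grid: recover the sample
  expect_equal(sample_mz(cs, 3.5), sp$cest_z[which(sp$cest_offsets == 3.5)],
               tolerance = 1e-3)
  # grid spacing is 1 Hz ~ 0.0025 ppm: nearest-point lookup moves < half step
  expect_equal(sample_mz(cs, 2.7501), sample_mz(cs, 2.75), tolerance = 1e-4)
  expect_error(sample_mz(cs, 7.0), "outside")
  expect_error(sample_mz(cs, 1.0), "outside")
})

test_that("B0 correction shifts the evaluation frame", {
  sp <- default_spectra()
  cs <- fit_spline(sp$cest_offsets, sp$cest_z, smoothing = "none")
  # identity at zero shift
  cs0 <- apply_b0_correction(cs, 0)
  expect_equal(sample_mz(cs0, c(2.75, 3.5, 6.0)), sample_mz(cs, c(2.75, 3.5, 6.0)))
  # corrected(w) = original(w + shift)
  cs1 <- apply_b0_correction(cs, 0.1)
  expect_equal(sample_mz(cs1, 3.5), sample_mz(cs, 3.6), tolerance = 1e-12)
  # a huge shift pushes the 6-ppm sample out of the domain
  expect_error(apply_b0_correction(cs, 5.0, required_ppm = c(2.75, 3.5, 6.0)),
               "outside the corrected domain")
})
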