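# single-pool continuous-wave steady state has a closed form; it serves
# as the analytic oracle for the matrix solver
lorentzian_z <- function(offset_ppm, b1, t1, t2, field_mhz = 400.22) {
  r1 <- 1 / t1; r2 <- 1 / t2
  delta <- 2 * pi * field_mhz * offset_ppm
  w1 <- 2 * pi * 42.5764 * b1
  r1 * (delta^2 + r2^2) / (r1 * (delta^2 + r2^2) + w1^2 * r2)
}

test_that("single-pool steady state matches the analytic closed form", {
  sys <- water_only()
  for (off in c(0, 0.2, 1, 3.5, 6.6, -2, 1000)) {
    expect_equal(bm_steady_state(sys, off, 1.5),
                 lorentzian_z(off, 1.5, 2, 0.06), tolerance = 1e-10)
  }
  # on-resonance saturation at 1.5 uT wipes out the water signal
  expect_lt(bm_steady_state(sys, 0, 1.5), 0.001)
})

test_that("no saturation means no signal loss", {
  sys <- default_pool_system()
  expect_equal(bm_steady_state(sys, 3.5, 0), 1)
  expect_equal(bm_evolve(sys, 3.5, 0, t_sat = 4), 1)
})

test_that("spectra are symmetric for symmetric systems", {
  sys <- water_only()
  offs <- seq(0.1, 3, 0.37)
  z_pos <- vapply(offs, function(o) bm_steady_state(sys, o, 1.5), 0)
  z_neg <- vapply(-offs, function(o) bm_steady_state(sys, o, 1.5), 0)
  expect_equal(z_pos, z_neg, tolerance = 1e-9)

  # a solute at +3.5 ppm mirrored to -3.5 ppm mirrors the whole spectrum
  sys_p <- one_solute_system(3.5)
  sys_m <- one_solute_system(-3.5)
  offs <- seq(-5, 5, 0.5)
  zp <- z_spectrum(sys_p, offs, 1.5, 4)
  zm <- z_spectrum(sys_m, rev(-offs), 1.5, 4)
  expect_equal(zp, rev(zm), tolerance = 1e-9)
})

test_that("finite-pulse evolution converges to the steady state", {
  sys <- default_pool_system()
  for (off in c(1.2, 2.75, 3.5, 6.0)) {
    expect_equal(bm_evolve(sys, off, 1.5, t_sat = 20),
                 bm_steady_state(sys, off, 1.5), tolerance = 1e-3)
  }
})

test_that("evolution agrees with an independent stiff ODE integration", {
  skip_if_not_installed("deSolve")
  sys <- default_pool_system()
  # moderate offsets keep the oscillatory integration tractable for lsoda
  cases <- list(list(off = 0.05, b1 = 0.2, t = 0.1),   # WASSR conditions
                list(off = 0.3, b1 = 1.5, t = 0.5))    # CEST power
  for (cs in cases) {
    m <- cestpH:::bm_matrix(sys, cs$off, cs$b1, ph = 7)
    deriv <- function(t, y, parms) list(m$A %*% y + m$b)
    sol <- deSolve::lsoda(m$m0, c(0, cs$t), deriv, NULL,
                          rtol = 1e-10, atol = 1e-12, maxsteps = 1e5)
    z_ode <- unname(sol[2, 4])  # columns: time, then state; water Mz is state 3
    expect_equal(bm_evolve(sys, cs$off, cs$b1, t_sat = cs$t), z_ode,
                 tolerance = 1e-6)
  }
})

test_that("saturation builds up monotonically and z stays physical", {
  sys <- default_pool_system()
  # low-power on-resonance (WASSR regime): longer saturation digs deeper
  expect_lte(bm_evolve(sys, 0, 0.2, t_sat = 4),
             bm_evolve(sys, 0, 0.2, t_sat = 0.1))
  # off-resonance CEST saturation likewise
  expect_lte(bm_evolve(sys, 3.5, 1.5, t_sat = 4),
             bm_evolve(sys, 3.5, 1.5, t_sat = 0.1))
  for (ph in c(6.2, 7.0, 7.6)) {
    z <- z_spectrum(sys, cest_schedule()$offsets_ppm[seq(1, 55, 6)], 1.5, 4, ph)
    expect_true(all(z >= 0 & z <= 1))
  }
})
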