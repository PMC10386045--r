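test_that("the AACID ratio evaluates its defining arithmetic", {
  expect_equal(compute_aacid(mz_amide = 0.7, mz_amine = 0.6, mz_ref = 0.9),
               0.7 * 0.3 / (0.6 * 0.2))
  # equal amide and amine samples cancel to exactly 1
  expect_equal(compute_aacid(0.55, 0.55, 0.9), 1)
  expect_equal(compute_aacid(0.1, 0.1, 0.4), 1)
  # degenerate denominators flag, never NaN
  expect_true(is.na(compute_aacid(0.7, 0, 0.9)))
  expect_true(is.na(compute_aacid(0.9, 0.6, 0.9)))
})

test_that("AACID is invariant under overall signal scaling", {
  set.seed(99)
  for (i in 1:50) {
    mz <- sort(runif(3, 0.1, 1))  # amide < amine < ref ordering not required
    c_scale <- runif(1, 0.1, 10)
    a1 <- compute_aacid(mz[1], mz[2], mz[3])
    a2 <- compute_aacid(c_scale * mz[1], c_scale * mz[2], c_scale * mz[3])
    expect_equal(a1, a2, tolerance = 1e-12)
  }
})

test_that("the pH calibration is the exact affine map", {
  expect_equal(aacid_to_ph(0), 12.8)
  expect_equal(aacid_to_ph(3.2), 0)
  # slope application: an AACID rise of 0.0775 is a 0.31 pH drop
  expect_equal(aacid_to_ph(1.2775) - aacid_to_ph(1.2), -0.31)
  # affinity: differences scale with the slope only
  set.seed(7)
  a <- runif(20, 0.5, 3); b <- runif(20, 0.5, 3)
  expect_equal(aacid_to_ph(a) - aacid_to_ph(b), -4 * (a - b))
  # custom calibration
  cal <- aacid_calibration(slope = -3.5, intercept = 12)
  expect_equal(aacid_to_ph(2, cal), 5)
  expect_error(aacid_calibration(slope = 0), "nonzero")
})

test_that("maps are spatially constant on a uniform noiseless phantom", {
  spec <- phantom_spec(
    nx = 10, ny = 10,
    classes = list(tissue_class("tissue", 7.0, "rect",
                                center = c(0.5, 0.5), radii = c(0.5, 0.5))),
    b0 = 0, noise_sigma = 0, seed = 1)
  ph <- generate_phantom(spec, n_repeats = 1)
  cn <- normalize_by_reference(ph$cest[[1]])
  maps <- make_maps(cn, smoothing = "none")
  vals <- maps$aacid$values[maps$aacid$valid]
  expect_equal(length(vals), 100)
  expect_lt(sd(vals), 1e-6)
  expect_equal(maps$ph$values, -4 * maps$aacid$values + 12.8)
})

test_that("the lower-pH region shows the higher AACID", {
  ph <- noiseless_phantom()  # tumor 6.8, contralateral 7.1
  cn <- normalize_by_reference(ph$cest[[1]])
  maps <- make_maps(cn, smoothing = "none")
  tum <- roi_stats(maps$aacid, ph$truth$masks$masks$tumor)
  con <- roi_stats(maps$aacid, ph$truth$masks$masks$contralateral)
  expect_gt(tum$mean, con$mean)
})

test_that("an all-invalid stack yields empty maps without crashing", {
  d <- array(NA_real_, c(4, 4, 55))
  st <- zspec_stack(d, cest_schedule()$offsets_ppm, numeric(),
                    normalized = TRUE)
  maps <- make_maps(st, smoothing = "none")
  expect_equal(sum(maps$aacid$valid), 0)
  expect_true(all(is.na(maps$aacid$values)))
})

test_that("simulator AACID falls as pH rises", {
  a <- simulated_aacid(c(6.8, 7.0, 7.2))
  expect_true(all(diff(a) < 0))
})
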