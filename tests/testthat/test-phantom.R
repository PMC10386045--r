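test_that("rician noise has the documented properties", {
  x <- matrix(1, 100, 100)
  expect_identical(add_rician_noise(x, 0), x)
  y1 <- add_rician_noise(x, 0.02, seed = 42)
  y2 <- add_rician_noise(x, 0.02, seed = 42)
  expect_identical(y1, y2)
  y3 <- add_rician_noise(x, 0.02, seed = 43)
  expect_false(identical(y1, y3))
  expect_error(add_rician_noise(x, -0.1), "sigma")
})

test_that("rician sample mean matches the quadrature oracle", {
  # E[R] for R = sqrt((v+g1)^2 + g2^2), v = 1, sigma = 0.02, by numerical
  # integration of the Rice density; the exponentially scaled Bessel keeps
  # the integrand finite at v/sigma = 50
  v <- 1; sigma <- 0.02
  rice_density <- function(r)
    (r / sigma^2) * exp(-(r - v)^2 / (2 * sigma^2)) *
      besselI(r * v / sigma^2, 0, expon.scaled = TRUE)
  rice_mean <- integrate(function(r) r * rice_density(r),
                         lower = max(0, v - 12 * sigma),
                         upper = v + 12 * sigma)$value

  n <- 1e4
  y <- add_rician_noise(matrix(v, 100, 100), sigma, seed = 7)
  se <- sd(y) / sqrt(n)
  expect_lt(abs(mean(y) - rice_mean), 3 * se)
})

test_that("phantom generation is deterministic and honors its spec", {
  spec <- two_class_spec(noise_sigma = 0.01, seed = 5)
  p1 <- generate_phantom(spec, n_repeats = 2)
  p2 <- generate_phantom(spec, n_repeats = 2)
  expect_identical(p1$cest[[1]]$data, p2$cest[[1]]$data)
  expect_identical(p1$wassr[[2]]$data, p2$wassr[[2]]$data)
  # repeats differ (independent noise streams)
  expect_false(identical(p1$cest[[1]]$data, p1$cest[[2]]$data))
  # ground truth consistent with the spec
  expect_setequal(names(p1$truth$masks$masks), c("contralateral", "tumor"))
  expect_setequal(unique(na.omit(as.vector(p1$truth$ph_map))), c(7.1, 6.8))
  expect_equal(unique(p1$truth$ph_map[p1$truth$masks$masks$tumor]), 6.8)
})

test_that("noiseless uniform-field phantoms give identical spectra per class", {
  ph <- noiseless_phantom()  # sigma = 0, b0 = 0
  stack <- ph$cest[[1]]
  for (m in ph$truth$masks$masks) {
    idx <- which(m)
    spectra <- apply(stack$data, 3, `[`, idx)
    expect_lt(max(apply(spectra, 2, sd)), 1e-12)
  }
  # reference frames carry the unsaturated-level signal
  ref <- stack$data[, , 56][ph$truth$label > 0]
  expect_true(all(ref > 0.999))
})

test_that("overlapping tissue regions are rejected", {
  spec <- phantom_spec(
    nx = 12, ny = 12,
    classes = list(
      tissue_class("a", 7.0, "ellipse", center = c(0.5, 0.5), radii = c(0.3, 0.3)),
      tissue_class("b", 6.8, "ellipse", center = c(0.55, 0.5), radii = c(0.3, 0.3))),
    noise_sigma = 0, seed = 1)
  expect_error(generate_phantom(spec, n_repeats = 1), "overlapping")
})

test_that("phantom B0 truth is applied to the spectra", {
  # constant +0.09 ppm shift moves the WASSR minimum to +0.09
  spec <- two_class_spec(noise_sigma = 0, b0 = 0.09)
  ph <- generate_phantom(spec, n_repeats = 1)
  wn <- normalize_by_reference(ph$wassr[[1]],
                               reference = reference_image(ph$cest[[1]]))
  idx <- which(ph$truth$masks$masks$tumor)[1]
  xy <- arrayInd(idx, dim(ph$truth$label))
  est <- estimate_b0(wn$offsets_ppm, wn$data[xy[1], xy[2], ],
                     field_mhz = wn$field_mhz, smoothing = "none")
  expect_true(est$valid)
  expect_equal(est$shift, 0.09, tolerance = 0.003)
})
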