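mini_stack <- function(data, offsets, refs = numeric()) {
  zspec_stack(data, offsets, refs, voxel_dims = c(0.4, 0.4, 2),
              field_mhz = 400.22)
}

test_that("reference normalization divides by the mean reference frame", {
  # one voxel: references 100 and 102, one saturated frame at 51
  d <- array(c(51, 100, 102), c(1, 1, 3))
  st <- mini_stack(d, offsets = 2.0, refs = c(-1000, 1000))
  nz <- normalize_by_reference(st)
  expect_equal(as.vector(nz$data), 51 / 101, tolerance = 1e-12)
  expect_equal(nz$data[1, 1, 1], 0.50495, tolerance = 1e-4)
  expect_length(nz$reference_offsets_ppm, 0)
  expect_true(nz$normalized)

  # spectrum equal to its reference -> constant 1
  d2 <- array(5, c(2, 2, 4))
  nz2 <- normalize_by_reference(mini_stack(d2, offsets = c(1, 2, 3), refs = 1000))
  expect_true(all(nz2$data == 1))
})

test_that("zero reference flags the voxel invalid without failing the stack", {
  d <- array(1, c(2, 1, 3))
  d[1, 1, 3] <- 0  # reference frame of voxel (1,1)
  st <- mini_stack(d, offsets = c(2, 3), refs = 1000)
  nz <- expect_silent(normalize_by_reference(st))
  expect_false(nz$valid[1, 1])
  expect_true(nz$valid[2, 1])
  expect_true(is.na(nz$data[1, 1, 1]))
})

test_that("normalization is idempotent against unit references", {
  z <- array(runif(2 * 2 * 3, 0.2, 1), c(2, 2, 3))
  st <- mini_stack(z, offsets = c(1, 2, 3))
  nz <- normalize_by_reference(st, reference = matrix(1, 2, 2))
  expect_equal(nz$data, z)
})

test_that("external reference is required when no reference frames exist", {
  st <- mini_stack(array(1, c(2, 2, 3)), offsets = c(1, 2, 3))
  expect_error(normalize_by_reference(st), "no reference frames")
  expect_error(normalize_by_reference(st, reference = matrix(1, 3, 3)),
               "2x2")
})

test_that("repeat averaging is an arithmetic mean with validity propagation", {
  a <- array(runif(4 * 4 * 5), c(4, 4, 5))
  sa <- mini_stack(a, offsets = 1:5)
  s2a <- mini_stack(2 * a, offsets = 1:5)
  avg <- average_repeats(list(sa, sa, sa))
  expect_equal(avg$data, a)
  avg2 <- average_repeats(list(sa, s2a))
  expect_equal(avg2$data, 1.5 * a)

  bad <- a; bad[1, 1, ] <- NA
  sb <- mini_stack(bad, offsets = 1:5)
  avg3 <- average_repeats(list(sa, sb))
  expect_false(avg3$valid[1, 1])
  expect_true(avg3$valid[2, 2])
})

test_that("averaging rejects mismatched repeats", {
  sa <- mini_stack(array(1, c(4, 4, 3)), offsets = 1:3)
  sb <- mini_stack(array(1, c(4, 5, 3)), offsets = 1:3)
  sc <- mini_stack(array(1, c(4, 4, 3)), offsets = 2:4)
  expect_error(average_repeats(list(sa, sb)), "geometry")
  expect_error(average_repeats(list(sa, sc)), "offset")
})

test_that("averaging repeats improves SNR by about sqrt(n)", {
  # 3 averaged Rician repeats of a constant image vs a single repeat
  v <- 0.8; sigma <- 0.02
  base <- matrix(v, 60, 60)
  reps <- lapply(1:3, function(r) add_rician_noise(base, sigma, seed = 100 + r))
  avg <- Reduce(`+`, reps) / 3
  ratio <- sd(reps[[1]]) / sd(avg)
  expect_equal(ratio, sqrt(3), tolerance = 0.1)
})
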