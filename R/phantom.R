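#' Tissue classes for digital phantoms
#'
#' A tissue class is a named region with its own intracellular pH and,
#' optionally, its own pool system. Regions are defined by shape
#' primitives in fractional grid coordinates (`(0, 0)` top-left,
#' `(1, 1)` bottom-right).
#'
#' @param name Region name (e.g. "tumor", "peritumoral", "contralateral").
#' @param ph Intracellular pH of the region, in `[5.5, 8.5]`.
#' @param shape `"ellipse"`, `"annulus"` or `"rect"`.
#' @param center Fractional `(x, y)` center.
#' @param radii Fractional `(rx, ry)` outer radii (half-widths for
#'   `"rect"`).
#' @param inner_radii Fractional inner radii, for `"annulus"` only.
#' @param pools Optional [pool_system()] override for this region.
#' @return An object of class `tissue_class`.
#' @export
tissue_class <- function(name, ph, shape = c("ellipse", "annulus", "rect"),
                         center = c(0.5, 0.5), radii = c(0.2, 0.2),
                         inner_radii = NULL, pools = NULL) {
  shape <- match.arg(shape)
  if (!is_number(ph) || ph < 5.5 || ph > 8.5)
    stopf("tissue pH must lie in [5.5, 8.5] (got %s)", format(ph))
  if (shape == "annulus" && is.null(inner_radii))
    stopf("annulus requires inner_radii")
  if (!is.null(pools)) stopifnot(inherits(pools, "pool_system"))
  structure(list(name = name, ph = ph, shape = shape, center = center,
                 radii = radii, inner_radii = inner_radii, pools = pools),
            class = "tissue_class")
}

# Rasterize one tissue class on an nx x ny grid.
class_mask <- function(cls, nx, ny) {
  u <- (matrix(seq_len(nx), nx, ny) - 0.5) / nx
  v <- (matrix(seq_len(ny), nx, ny, byrow = TRUE) - 0.5) / ny
  du <- u - cls$center[1]; dv <- v - cls$center[2]
  inside <- switch(cls$shape,
    ellipse = (du / cls$radii[1])^2 + (dv / cls$radii[2])^2 <= 1,
    rect    = abs(du) <= cls$radii[1] & abs(dv) <= cls$radii[2],
    annulus = {
      outer_in <- (du / cls$radii[1])^2 + (dv / cls$radii[2])^2 <= 1
      inner_in <- (du / cls$inner_radii[1])^2 + (dv / cls$inner_radii[2])^2 <= 1
      outer_in & !inner_in
    })
  inside
}

#' Smooth polynomial B0 field model
#'
#' Evaluates `c0 + c1 u + c2 v + c3 u v + c4 u^2 + c5 v^2` on fractional
#' coordinates `u, v` rescaled to `[-1, 1]`, then clamps to +/- `cap` ppm
#' so a WASSR window of +/- 0.6 ppm always brackets the water minimum.
#'
#' @param coef Numeric vector of up to 6 polynomial coefficients (ppm).
#' @param cap Absolute clamp in ppm.
#' @return A function `(nx, ny) -> nx x ny` matrix of B0 offsets (ppm).
#' @export
b0_polynomial <- function(coef = c(0, 0.05, -0.04, 0.02, 0.03, -0.02),
                          cap = 0.3) {
  coef <- c(coef, numeric(6))[1:6]
  function(nx, ny) {
    u <- 2 * ((matrix(seq_len(nx), nx, ny) - 0.5) / nx) - 1
    v <- 2 * ((matrix(seq_len(ny), nx, ny, byrow = TRUE) - 0.5) / ny) - 1
    b0 <- coef[1] + coef[2] * u + coef[3] * v + coef[4] * u * v +
      coef[5] * u^2 + coef[6] * v^2
    pmin(pmax(b0, -cap), cap)
  }
}

#' Digital phantom specification
#'
#' Describes the 2-D slice geometry, the tissue classes with their
#' intracellular pH, the B0 inhomogeneity model, an optional B1 scale
#' field, the Rician noise level (relative to the unsaturated signal) and
#' the master seed driving every random draw.
#'
#' @param nx,ny Grid size in voxels.
#' @param voxel_dims Voxel dimensions `c(dx, dy, dz)` in mm.
#' @param classes List of [tissue_class()]es; regions must be disjoint.
#' @param b0 Either a function `(nx, ny) -> matrix` of per-voxel B0 offsets
#'   (ppm), a single number, or an `nx x ny` matrix.
#' @param b1_scale Per-voxel B1 multiplier: a single number or an
#'   `nx x ny` matrix (default 1, i.e. no B1 perturbation).
#' @param noise_sigma Rician noise scale relative to the unsaturated
#'   signal (>= 0).
#' @param seed Master RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(nx = 96, ny = 96, voxel_dims = c(0.4, 0.4, 2),
                         classes, b0 = b0_polynomial(), b1_scale = 1,
                         noise_sigma = 0.02, seed = 1L) {
  if (!is_number(nx) || !is_number(ny) || nx < 2 || ny < 2 ||
      nx != round(nx) || ny != round(ny))
    stopf("invalid grid: nx and ny must be integers >= 2")
  if (!is.list(classes) || length(classes) < 1L ||
      !all(vapply(classes, inherits, TRUE, "tissue_class")))
    stopf("classes must be a non-empty list of tissue_class objects")
  if (anyDuplicated(vapply(classes, `[[`, "", "name")))
    stopf("tissue class names must be unique")
  if (!is_number(noise_sigma) || noise_sigma < 0)
    stopf("noise_sigma must be >= 0")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 voxel_dims = as.numeric(voxel_dims), classes = classes,
                 b0 = b0, b1_scale = b1_scale,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default three-class tumor phantom
#'
#' A contralateral patch at pH 7.0, a tumor at pH 7.2 (alkaline
#' intracellular shift typical of gliomas) and a peritumoral rim at
#' pH 7.05, on the CEST acquisition grid (96 x 96, 0.4 mm in-plane,
#' 2 mm slice).
#'
#' @inheritParams phantom_spec
#' @param ph Named numeric vector of class pH values to override the
#'   defaults, e.g. `c(tumor = 6.9)`.
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(nx = 96, ny = 96, noise_sigma = 0.02,
                                 seed = 1L, ph = numeric()) {
  phs <- c(contralateral = 7.0, peritumoral = 7.05, tumor = 7.2)
  phs[names(ph)] <- ph
  classes <- list(
    tissue_class("contralateral", phs[["contralateral"]], "ellipse",
                 center = c(0.30, 0.50), radii = c(0.16, 0.28)),
    tissue_class("peritumoral", phs[["peritumoral"]], "annulus",
                 center = c(0.70, 0.45), radii = c(0.145, 0.17),
                 inner_radii = c(0.10, 0.12)),
    tissue_class("tumor", phs[["tumor"]], "ellipse",
                 center = c(0.70, 0.45), radii = c(0.10, 0.12)))
  phantom_spec(nx = nx, ny = ny, classes = classes,
               noise_sigma = noise_sigma, seed = seed)
}

#' Add Rician noise to magnitude data
#'
#' Each value `v` is replaced by `sqrt((v + g1)^2 + g2^2)` with
#' `g1, g2 ~ Normal(0, sigma)`, the noise model of magnitude MRI images.
#' `sigma = 0` returns the input unchanged.
#'
#' @param x Numeric array or matrix (or a [zspec_stack()], whose data are
#'   perturbed in place).
#' @param sigma Gaussian channel noise SD (>= 0), in the units of `x`.
#' @param seed Optional seed; the same seed reproduces the same noise.
#' @return Object of the same shape/class as `x`.
#' @export
add_rician_noise <- function(x, sigma, seed = NULL) {
  if (!is_number(sigma) || sigma < 0) stopf("sigma must be >= 0")
  if (inherits(x, "zspec_stack")) {
    x$data <- add_rician_noise(x$data, sigma, seed)
    return(x)
  }
  if (sigma == 0) return(x)
  with_seed(seed, {
    g1 <- rnorm(length(x), 0, sigma)
    g2 <- rnorm(length(x), 0, sigma)
    out <- sqrt((x + g1)^2 + g2^2)
    attributes(out) <- attributes(x)
    out
  })
}

# Dense master Z-spectrum of one tissue class over the offsets the voxels
# can reach after B0 shifting; voxel spectra are spline-interpolated from
# it. 0.005-ppm spacing keeps the interpolation error far below the noise
# floor while avoiding a per-voxel Bloch-McConnell solve.
master_spectrum <- function(system, ph, schedule, b0_range, b1_scale = 1,
                            step = 0.005) {
  # voxel spectra are evaluated at (offset - b0), so the grid must extend
  # downward by the largest positive b0 and upward by the largest negative
  lo <- min(schedule$offsets_ppm) - max(0, b0_range[2]) - 2 * step
  hi <- max(schedule$offsets_ppm) - min(0, b0_range[1]) + 2 * step
  grid <- seq(lo, hi, by = step)
  z <- z_spectrum(system, grid, schedule$b1_amplitude * b1_scale,
                  schedule$sat_duration, ph)
  zref <- vapply(schedule$reference_offsets_ppm, function(o)
    bm_evolve(system, o, schedule$b1_amplitude * b1_scale,
              schedule$sat_duration, ph), 0)
  list(fun = splinefun(grid, z, method = "natural"), ref = zref)
}

#' Generate a CEST/WASSR phantom acquisition
#'
#' Simulates the full acquisition of one imaging session: `n_repeats`
#' raw CEST stacks and WASSR stacks with per-voxel B0-shifted,
#' B1-scaled, pH-resolved Bloch-McConnell spectra, plus the ground truth
#' (pH map, B0 map, tissue masks). Reference frames carry the
#' unsaturated-equivalent signal; Rician noise is drawn independently per
#' repeat from streams derived from the master seed, so the same spec
#' reproduces bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @param cest_sched,wassr_sched [saturation_schedule()]s for the two
#'   acquisitions.
#' @param n_repeats Number of repeated acquisitions (>= 1).
#' @param pools Default [pool_system()] for classes without an override.
#' @return A list with elements `cest` (list of raw [zspec_stack()]s),
#'   `wassr` (likewise), and `truth` (list with `ph_map`, `b0_map`,
#'   `masks` ([roi_set()]), `label`).
#' @export
generate_phantom <- function(spec, cest_sched = cest_schedule(),
                             wassr_sched = wassr_schedule(),
                             n_repeats = 3L, pools = default_pool_system()) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is_number(n_repeats) || n_repeats < 1) stopf("n_repeats must be >= 1")
  nx <- spec$nx; ny <- spec$ny
  masks <- lapply(spec$classes, class_mask, nx = nx, ny = ny)
  names(masks) <- vapply(spec$classes, `[[`, "", "name")
  overlap <- Reduce(`+`, masks)
  if (any(overlap > 1)) stopf("overlapping tissue regions in phantom spec")

  b0 <- spec$b0
  if (is.function(b0)) b0 <- b0(nx, ny)
  if (is_number(b0)) b0 <- matrix(b0, nx, ny)
  if (!is.matrix(b0) || !all(dim(b0) == c(nx, ny)))
    stopf("b0 field must evaluate to an %dx%d matrix", nx, ny)
  b1s <- spec$b1_scale
  if (is_number(b1s)) b1s <- matrix(b1s, nx, ny)
  b1q <- round(b1s, 3)  # quantize so master spectra can be shared

  ph_map <- matrix(NA_real_, nx, ny)
  for (i in seq_along(masks)) ph_map[masks[[i]]] <- spec$classes[[i]]$ph

  n_cest <- n_frames(cest_sched)
  n_wassr <- n_frames(wassr_sched)
  cest0 <- array(0, c(nx, ny, n_cest))
  wassr0 <- array(0, c(nx, ny, n_wassr))
  b0_rng <- range(b0)

  for (i in seq_along(masks)) {
    cls <- spec$classes[[i]]
    sys_i <- if (is.null(cls$pools)) pools else cls$pools
    in_cls <- which(masks[[i]])
    for (b1v in unique(b1q[in_cls])) {
      vox <- in_cls[b1q[in_cls] == b1v]
      ms_c <- master_spectrum(sys_i, cls$ph, cest_sched, b0_rng, b1v)
      ms_w <- master_spectrum(sys_i, cls$ph, wassr_sched, b0_rng, b1v)
      for (v in vox) {
        # apparent spectrum of a voxel whose water resonates at +b0 ppm
        sh <- b0[v]
        xy <- arrayInd(v, c(nx, ny))
        cest0[xy[1], xy[2], ] <- c(ms_c$fun(cest_sched$offsets_ppm - sh), ms_c$ref)
        wassr0[xy[1], xy[2], ] <- c(ms_w$fun(wassr_sched$offsets_ppm - sh), ms_w$ref)
      }
    }
  }

  seeds <- derive_seeds(spec$seed, 2L * n_repeats)
  mk_stack <- function(arr, sched, seed_i) {
    noisy <- add_rician_noise(arr, spec$noise_sigma, seeds[seed_i])
    zspec_stack(noisy, sched$offsets_ppm, sched$reference_offsets_ppm,
                voxel_dims = spec$voxel_dims, field_mhz = pools$field_mhz,
                normalized = FALSE, b1_amplitude = sched$b1_amplitude,
                sat_duration = sched$sat_duration)
  }
  cest <- lapply(seq_len(n_repeats), function(r) mk_stack(cest0, cest_sched, 2L * r - 1L))
  wassr <- lapply(seq_len(n_repeats), function(r) mk_stack(wassr0, wassr_sched, 2L * r))

  label <- matrix(0L, nx, ny)
  for (i in seq_along(masks)) label[masks[[i]]] <- i
  truth <- list(ph_map = ph_map, b0_map = b0,
                masks = roi_set(masks, spec$voxel_dims), label = label)
  list(cest = cest, wassr = wassr, truth = truth)
}
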