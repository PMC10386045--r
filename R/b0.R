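#' Estimate the per-voxel water-center shift from a WASSR spectrum
#'
#' The water saturation shift referencing (WASSR) spectrum is a low-power,
#' short-saturation Z-spectrum whose minimum sits at the voxel's apparent
#' water frequency. The sampled spectrum is spline-fitted, evaluated on
#' the 1-Hz grid across the sampled domain, and the grid argmin is
#' returned as the B0 shift. Among minima whose value is within `1e-4` of
#' the global minimum, the one closest to 0 ppm wins. A minimum attained
#' at a domain boundary means the shift is not bracketed: the voxel is
#' flagged invalid instead of returning a shift.
#'
#' @param offsets_ppm Sampled WASSR offsets (ppm), strictly increasing.
#' @param z Normalized z values at those offsets.
#' @param field_mhz Water resonance frequency (MHz).
#' @param smoothing Spline smoothing control (see [fit_spline()]).
#' @return A list with `shift` (ppm, `NA` when invalid) and `valid`.
#' @export
estimate_b0 <- function(offsets_ppm, z, field_mhz = 400.22, smoothing = "gcv") {
  cs <- fit_spline(offsets_ppm, z, field_mhz = field_mhz, smoothing = smoothing)
  hz <- spectrum_hz_grid(cs)
  ppm_grid <- hz / field_mhz
  zz <- cs$fun(ppm_grid)
  i_min <- which.min(zz)
  near <- which(zz <= zz[i_min] + 1e-4)
  i_best <- near[which.min(abs(ppm_grid[near]))]
  if (i_best == 1L || i_best == length(ppm_grid) ||
      i_min == 1L || i_min == length(ppm_grid)) {
    return(list(shift = NA_real_, valid = FALSE))
  }
  list(shift = ppm_grid[i_best], valid = TRUE)
}

#' Per-voxel B0 map from a normalized WASSR stack
#'
#' Runs [estimate_b0()] at every valid voxel of the stack.
#'
#' @param stack A normalized WASSR [zspec_stack()] (references removed).
#' @param smoothing Spline smoothing control (see [fit_spline()]).
#' @return An object of class `b0_map`: `shift` (matrix, ppm; `NA` where
#'   invalid), `valid` (logical matrix), `voxel_dims`, `field_mhz`.
#' @export
estimate_b0_map <- function(stack, smoothing = "gcv") {
  stopifnot(inherits(stack, "zspec_stack"))
  if (!stack$normalized) stopf("WASSR stack must be normalized first")
  d <- dim(stack$data)
  shift <- matrix(NA_real_, d[1], d[2])
  valid <- matrix(FALSE, d[1], d[2])
  for (ix in seq_len(d[1])) {
    for (iy in seq_len(d[2])) {
      if (!stack$valid[ix, iy]) next
      est <- tryCatch(
        estimate_b0(stack$offsets_ppm, stack$data[ix, iy, ],
                    field_mhz = stack$field_mhz, smoothing = smoothing),
        error = function(e) list(shift = NA_real_, valid = FALSE))
      shift[ix, iy] <- est$shift
      valid[ix, iy] <- est$valid
    }
  }
  structure(list(shift = shift, valid = valid,
                 voxel_dims = stack$voxel_dims, field_mhz = stack$field_mhz),
            class = "b0_map")
}

#' @export
print.b0_map <- function(x, ...) {
  cat(sprintf("<b0_map> %dx%d, %d/%d voxels valid, shift range [%g, %g] ppm\n",
              nrow(x$shift), ncol(x$shift), sum(x$valid), length(x$valid),
              suppressWarnings(min(x$shift, na.rm = TRUE)),
              suppressWarnings(max(x$shift, na.rm = TRUE))))
  invisible(x)
}
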