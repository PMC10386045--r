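#' AACID calibration parameters
#'
#' The linear mouse-brain calibration mapping AACID to intracellular pH:
#' `pHi = slope * AACID + intercept`, with defaults `slope = -4` pH per
#' AACID unit and `intercept = 12.8` pH units.
#'
#' @param slope pH change per AACID unit (nonzero).
#' @param intercept pH at AACID = 0.
#' @return An object of class `aacid_calibration`.
#' @export
aacid_calibration <- function(slope = -4, intercept = 12.8) {
  if (!is_number(slope) || slope == 0) stopf("slope must be a nonzero number")
  if (!is_number(intercept)) stopf("intercept must be a single finite number")
  structure(list(slope = slope, intercept = intercept),
            class = "aacid_calibration")
}

#' Compute the AACID ratio from three Mz samples
#'
#' Amine/amide concentration-independent detection combines the
#' B0-corrected Z-spectrum values at the amide (+3.5 ppm) and amine
#' (+2.75 ppm) resonances with the +6.0 ppm reference point:
#' \deqn{AACID = \frac{M_z(3.5)\,(M_z(6.0) - M_z(2.75))}
#'                    {M_z(2.75)\,(M_z(6.0) - M_z(3.5))}}
#' Being a ratio of CEST effects, it is independent of an overall signal
#' scale. Degenerate inputs (`mz_amine = 0` or `mz_ref = mz_amide`) yield
#' `NA` so callers can flag the voxel invalid; the parametric maps never
#' carry NaN.
#'
#' @param mz_amide z value at +3.5 ppm.
#' @param mz_amine z value at +2.75 ppm.
#' @param mz_ref z value at +6.0 ppm.
#' @return AACID value(s); `NA` where undefined. Vectorized.
#' @export
compute_aacid <- function(mz_amide, mz_amine, mz_ref) {
  num <- mz_amide * (mz_ref - mz_amine)
  den <- mz_amine * (mz_ref - mz_amide)
  out <- ifelse(mz_amine == 0 | mz_ref == mz_amide | !is.finite(den) |
                  !is.finite(num), NA_real_, num / den)
  as.numeric(out)
}

#' Convert AACID to calibrated intracellular pH
#'
#' Applies the affine calibration `pHi = slope * AACID + intercept`.
#'
#' @param aacid AACID value(s).
#' @param cal An [aacid_calibration()].
#' @return pH value(s).
#' @examples
#' aacid_to_ph(0)      # 12.8
#' aacid_to_ph(3.2)    # 0
#' @export
aacid_to_ph <- function(aacid, cal = aacid_calibration()) {
  stopifnot(inherits(cal, "aacid_calibration"))
  cal$slope * aacid + cal$intercept
}

# Scalar parametric map with validity mask.
param_map <- function(values, valid, voxel_dims) {
  stopifnot(is.matrix(values), is.logical(valid),
            all(dim(values) == dim(valid)))
  values[!valid] <- NA_real_
  structure(list(values = values, valid = valid,
                 voxel_dims = as.numeric(voxel_dims)),
            class = "param_map")
}

#' @export
print.param_map <- function(x, ...) {
  cat(sprintf("<param_map> %dx%d, %d/%d valid, range [%g, %g]\n",
              nrow(x$values), ncol(x$values), sum(x$valid), length(x$valid),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Pixel-wise AACID and pH parametric maps
#'
#' For every valid voxel of a normalized (and repeat-averaged) CEST stack:
#' fit the smoothing spline, apply the voxel's WASSR B0 shift, read the
#' 1-Hz-resolution spectrum at 2.75, 3.5 and 6.0 ppm, and convert to AACID
#' and calibrated pH. Validity masks of the stack and the B0 map are
#' intersected; voxels where the corrected domain no longer covers the
#' sampling points, or where AACID is undefined, are flagged invalid
#' rather than propagating NaN.
#'
#' @param stack A normalized CEST [zspec_stack()].
#' @param b0map Optional [estimate_b0_map()] result; `NULL` skips B0
#'   correction.
#' @param cal An [aacid_calibration()].
#' @param smoothing Spline smoothing control (see [fit_spline()]).
#' @param sample_ppm Named offsets at which Mz is read
#'   (`amine`, `amide`, `reference`).
#' @return A list of class `aacid_maps` with `aacid` and `ph`
#'   ([param_map()]s).
#' @export
make_maps <- function(stack, b0map = NULL, cal = aacid_calibration(),
                      smoothing = "gcv",
                      sample_ppm = c(amine = 2.75, amide = 3.5, reference = 6.0)) {
  stopifnot(inherits(stack, "zspec_stack"))
  if (!stack$normalized) stopf("CEST stack must be normalized first")
  if (!is.null(b0map)) {
    stopifnot(inherits(b0map, "b0_map"))
    if (!all(dim(b0map$shift) == dim(stack$valid)))
      stopf("B0 map geometry does not match the stack")
  }
  d <- dim(stack$data)
  aacid <- matrix(NA_real_, d[1], d[2])
  valid <- matrix(FALSE, d[1], d[2])
  req <- unname(sample_ppm[c("amide", "amine", "reference")])
  for (ix in seq_len(d[1])) {
    for (iy in seq_len(d[2])) {
      if (!stack$valid[ix, iy]) next
      sh <- 0
      if (!is.null(b0map)) {
        if (!b0map$valid[ix, iy]) next
        sh <- b0map$shift[ix, iy]
      }
      a <- tryCatch({
        cs <- fit_spline(stack$offsets_ppm, stack$data[ix, iy, ],
                         field_mhz = stack$field_mhz, smoothing = smoothing)
        cs <- apply_b0_correction(cs, sh, required_ppm = req)
        mz <- sample_mz(cs, req)
        compute_aacid(mz_amide = mz[1], mz_amine = mz[2], mz_ref = mz[3])
      }, error = function(e) NA_real_)
      if (is.finite(a)) {
        aacid[ix, iy] <- a
        valid[ix, iy] <- TRUE
      }
    }
  }
  ph <- aacid_to_ph(aacid, cal)
  structure(list(aacid = param_map(aacid, valid, stack$voxel_dims),
                 ph = param_map(ph, valid, stack$voxel_dims)),
            class = "aacid_maps")
}

#' Spectrum-level AACID of the simulator at given pH values
#'
#' Runs the forward model end to end for a single idealized voxel (no
#' B0 shift, no noise): simulate the Z-spectrum on the CEST schedule,
#' fit the continuous spectrum, read Mz at 2.75/3.5/6.0 ppm and form the
#' AACID ratio. This is the simulator's own AACID-pH response curve,
#' used to express scripted pH changes as expected AACID changes.
#'
#' @param ph Numeric vector of pH values.
#' @param system A [pool_system()].
#' @param schedule A [saturation_schedule()].
#' @param smoothing Spline smoothing control (exact interpolation by
#'   default: the input is noiseless).
#' @return Numeric vector of AACID values, one per pH.
#' @export
simulated_aacid <- function(ph, system = default_pool_system(),
                            schedule = cest_schedule(), smoothing = "none") {
  vapply(ph, function(p) {
    z <- z_spectrum(system, schedule$offsets_ppm, schedule$b1_amplitude,
                    schedule$sat_duration, p)
    cs <- fit_spline(schedule$offsets_ppm, z, field_mhz = system$field_mhz,
                     smoothing = smoothing)
    mz <- sample_mz(cs, c(3.5, 2.75, 6.0))
    compute_aacid(mz_amide = mz[1], mz_amine = mz[2], mz_ref = mz[3])
  }, 0)
}
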