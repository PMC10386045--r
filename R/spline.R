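#' Fit a continuous Z-spectrum to sampled offsets
#'
#' Fits a smoothing spline (or an exact interpolating cubic spline) through
#' one voxel's sampled Z-spectrum and exposes it at 1-Hz resolution: every
#' evaluation is snapped to the nearest point of a grid with 1-Hz spacing
#' (`1/field_mhz` ppm), whose endpoints lie inside the sampled domain.
#'
#' Smoothing choices: `"gcv"` (default) selects the smoothing parameter by
#' generalized cross-validation — appropriate for noisy data; `"none"` (or
#' the number 0) interpolates the samples exactly; a positive number is
#' passed to [stats::smooth.spline()] as `spar`.
#'
#' @param offsets_ppm Strictly increasing numeric vector of at least 4
#'   sampled offsets (ppm).
#' @param z Numeric vector of sampled z values, same length.
#' @param field_mhz Water resonance frequency (MHz), fixes the 1-Hz grid.
#' @param smoothing `"gcv"`, `"none"`, or a number (0 = exact
#'   interpolation, > 0 = `spar`).
#' @return An object of class `continuous_spectrum` with elements `fun`
#'   (the fitted spline), `domain` (sampled ppm range), `field_mhz` and
#'   `shift` (accumulated B0 correction, ppm).
#' @export
fit_spline <- function(offsets_ppm, z, field_mhz = 400.22, smoothing = "gcv") {
  if (length(offsets_ppm) != length(z))
    stopf("offsets_ppm and z must have equal length")
  if (length(unique(offsets_ppm)) < 4L)
    stopf("need at least 4 distinct offsets to fit a spline (got %d)",
          length(unique(offsets_ppm)))
  if (any(diff(offsets_ppm) <= 0))
    stopf("offsets_ppm must be strictly increasing")
  if (any(!is.finite(z))) stopf("z contains non-finite values")

  exact <- identical(smoothing, "none") ||
    (is.numeric(smoothing) && length(smoothing) == 1L && smoothing == 0)
  gcv <- identical(smoothing, "gcv")
  spar <- is.numeric(smoothing) && length(smoothing) == 1L &&
    is.finite(smoothing) && smoothing > 0
  if (!exact && !gcv && !spar)
    stopf("smoothing must be \"gcv\", \"none\" or a single non-negative number")
  if (exact || sd(z) == 0) {
    fun <- splinefun(offsets_ppm, z, method = "natural")
  } else if (gcv) {
    fit <- smooth.spline(offsets_ppm, z, cv = FALSE, keep.data = FALSE)
    fun <- function(x) predict(fit, x)$y
  } else {
    fit <- smooth.spline(offsets_ppm, z, spar = smoothing, keep.data = FALSE)
    fun <- function(x) predict(fit, x)$y
  }
  structure(list(fun = fun, domain = range(offsets_ppm),
                 field_mhz = field_mhz, shift = 0),
            class = "continuous_spectrum")
}

# Integer-Hz grid covering the native domain (endpoints snapped inside).
spectrum_hz_grid <- function(cs) {
  f <- cs$field_mhz
  eps <- 1e-9
  seq(ceiling(cs$domain[1] * f - eps), floor(cs$domain[2] * f + eps))
}

#' Evaluate the 1-Hz-resolution spectrum at a given offset
#'
#' Returns the spline value at the 1-Hz grid point nearest `ppm`,
#' accounting for any B0 shift applied with [apply_b0_correction()]
#' (a spectrum corrected by shift `s` is read out at `ppm + s` in native
#' coordinates).
#'
#' @param cs A `continuous_spectrum` from [fit_spline()].
#' @param ppm Offset(s) at which to sample (ppm, corrected frame).
#' @return Numeric z value(s).
#' @export
sample_mz <- function(cs, ppm) {
  stopifnot(inherits(cs, "continuous_spectrum"))
  w <- ppm + cs$shift
  eps <- 1e-9
  if (any(w < cs$domain[1] - eps | w > cs$domain[2] + eps))
    stopf("offset %s ppm outside spectrum domain [%g, %g] (after shift %g)",
          paste(format(ppm[w < cs$domain[1] - eps | w > cs$domain[2] + eps]),
                collapse = ", "),
          cs$domain[1] - cs$shift, cs$domain[2] - cs$shift, cs$shift)
  hz <- spectrum_hz_grid(cs)
  target_hz <- pmin(pmax(round(w * cs$field_mhz), hz[1]), hz[length(hz)])
  cs$fun(target_hz / cs$field_mhz)
}

#' Apply a B0 frequency shift to a continuous spectrum
#'
#' A voxel whose water center appears at `+shift` ppm (as estimated by
#' WASSR) has its corrected spectrum defined by
#' `corrected(w) = original(w + shift)`; the evaluable domain contracts
#' accordingly. If `required_ppm` offsets are supplied, the correction
#' fails immediately when any of them leaves the corrected domain (the
#' caller flags the voxel invalid).
#'
#' @param cs A `continuous_spectrum`.
#' @param shift Water-center shift in ppm.
#' @param required_ppm Offsets (corrected frame) that must remain
#'   evaluable, e.g. `c(2.75, 3.5, 6.0)`.
#' @return The shifted `continuous_spectrum`.
#' @export
apply_b0_correction <- function(cs, shift, required_ppm = NULL) {
  stopifnot(inherits(cs, "continuous_spectrum"))
  if (!is_number(shift)) stopf("shift must be a single finite number (ppm)")
  cs$shift <- cs$shift + shift
  if (!is.null(required_ppm)) {
    w <- required_ppm + cs$shift
    bad <- w < cs$domain[1] | w > cs$domain[2]
    if (any(bad))
      stopf("required sampling point(s) %s ppm outside the corrected domain [%g, %g]",
            paste(required_ppm[bad], collapse = ", "),
            cs$domain[1] - cs$shift, cs$domain[2] - cs$shift)
  }
  cs
}

#' @export
print.continuous_spectrum <- function(x, ...) {
  cat(sprintf("<continuous_spectrum> domain [%g, %g] ppm at %.2f MHz (1 Hz ~ %.4f ppm), shift %+g ppm\n",
              x$domain[1], x$domain[2], x$field_mhz, 1 / x$field_mhz, x$shift))
  invisible(x)
}
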