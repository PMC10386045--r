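#' Z-spectrum image stacks
#'
#' A `zspec_stack` holds one 2-D slice acquired at a series of saturation
#' offsets: an `nx x ny x K` array where the first `length(offsets_ppm)`
#' frames are the sampled offsets and any remaining frames are the
#' far-off-resonance reference acquisitions, in the order given by
#' `reference_offsets_ppm`.
#'
#' @param data Numeric array `nx x ny x K` with
#'   `K = length(offsets_ppm) + length(reference_offsets_ppm)`.
#' @param offsets_ppm Ordered sampled saturation offsets (ppm).
#' @param reference_offsets_ppm Reference offsets (ppm) whose frames close
#'   the stack; may be empty.
#' @param voxel_dims Voxel dimensions `c(dx, dy, dz)` in mm.
#' @param field_mhz Water resonance frequency (MHz).
#' @param normalized Has the stack been divided by its reference signal?
#' @param valid Optional logical `nx x ny` validity mask; defaults to all
#'   voxels with finite data.
#'
#' @return An object of class `zspec_stack`.
#' @export
zspec_stack <- function(data, offsets_ppm, reference_offsets_ppm = numeric(),
                        voxel_dims = c(0.4, 0.4, 2), field_mhz = 400.22,
                        normalized = FALSE, valid = NULL,
                        b1_amplitude = NA_real_, sat_duration = NA_real_) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("data must be an nx x ny x K array")
  k_expect <- length(offsets_ppm) + length(reference_offsets_ppm)
  if (dim(data)[3] != k_expect)
    stopf("stack has %d frames but %d offsets are declared", dim(data)[3], k_expect)
  if (length(voxel_dims) != 3L || any(voxel_dims <= 0))
    stopf("voxel_dims must be three positive lengths (mm)")
  if (is.null(valid)) {
    valid <- apply(is.finite(data), c(1, 2), all)
  }
  stopifnot(is.logical(valid), all(dim(valid) == dim(data)[1:2]))
  structure(
    list(data = data, offsets_ppm = as.numeric(offsets_ppm),
         reference_offsets_ppm = as.numeric(reference_offsets_ppm),
         voxel_dims = as.numeric(voxel_dims), field_mhz = field_mhz,
         normalized = isTRUE(normalized), valid = valid,
         b1_amplitude = b1_amplitude, sat_duration = sat_duration),
    class = "zspec_stack")
}

#' @export
print.zspec_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<zspec_stack> %dx%d voxels, %d offsets + %d reference frame(s), %s, %d/%d voxels valid\n",
              d[1], d[2], length(x$offsets_ppm), length(x$reference_offsets_ppm),
              if (x$normalized) "normalized" else "raw",
              sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Reference image of a raw stack
#'
#' Voxel-wise mean of the far-off-resonance reference frames, i.e. the
#' unsaturated signal intensity.
#'
#' @param stack A raw [zspec_stack()] with at least one reference frame.
#' @return Numeric matrix `nx x ny`.
#' @export
reference_image <- function(stack) {
  stopifnot(inherits(stack, "zspec_stack"))
  n_ref <- length(stack$reference_offsets_ppm)
  if (n_ref < 1L) stopf("stack has no reference frames")
  ref_idx <- length(stack$offsets_ppm) + seq_len(n_ref)
  apply(stack$data[, , ref_idx, drop = FALSE], c(1, 2), mean)
}

#' Normalize a stack by its reference signal
#'
#' Divides every voxel's spectrum by the mean of that voxel's reference
#' frames (the far-off-resonance acquisitions) and drops the reference
#' frames from the offsets axis. A stack without its own reference frames
#' (e.g. a 41-point WASSR acquisition) is normalized against an external
#' `reference` image, typically [reference_image()] of the companion CEST
#' stack. Voxels whose reference signal is zero, negative, non-finite or
#' below `min_reference` are flagged invalid rather than raising an
#' error; `min_reference` guards against pure-noise (air) voxels whose
#' magnitude signal is positive by construction.
#'
#' @param stack A raw [zspec_stack()].
#' @param reference Optional external reference matrix (`nx x ny`), used
#'   when the stack has no reference frames of its own.
#' @param min_reference Minimum reference signal for a voxel to count as
#'   valid (same units as the raw data; default 0 = only zero/negative
#'   excluded).
#' @return A normalized [zspec_stack()] without reference frames.
#' @export
normalize_by_reference <- function(stack, reference = NULL, min_reference = 0) {
  stopifnot(inherits(stack, "zspec_stack"))
  n_ref <- length(stack$reference_offsets_ppm)
  n_off <- length(stack$offsets_ppm)
  if (n_ref >= 1L && is.null(reference)) {
    ref_mean <- reference_image(stack)
  } else if (!is.null(reference)) {
    if (!is.matrix(reference) || !all(dim(reference) == dim(stack$valid)))
      stopf("external reference must be an %dx%d matrix",
            dim(stack$valid)[1], dim(stack$valid)[2])
    ref_mean <- reference
  } else {
    stopf("stack has no reference frames and no external reference was given")
  }
  ok <- is.finite(ref_mean) & ref_mean > 0 & ref_mean >= min_reference
  sat <- stack$data[, , seq_len(n_off), drop = FALSE]
  denom <- ifelse(ok, ref_mean, NA_real_)
  z <- sweep(sat, c(1, 2), denom, "/")
  zspec_stack(z, stack$offsets_ppm, numeric(),
              voxel_dims = stack$voxel_dims, field_mhz = stack$field_mhz,
              normalized = TRUE, valid = stack$valid & ok,
              b1_amplitude = stack$b1_amplitude, sat_duration = stack$sat_duration)
}

#' Average repeated acquisitions voxel-wise
#'
#' @param stacks List of [zspec_stack()]s with identical geometry, offsets
#'   and normalization state.
#' @return A [zspec_stack()] holding the arithmetic mean; a voxel is valid
#'   only where it is valid in every repeat.
#' @export
average_repeats <- function(stacks) {
  if (!is.list(stacks) || length(stacks) < 1L ||
      !all(vapply(stacks, inherits, TRUE, "zspec_stack")))
    stopf("stacks must be a non-empty list of zspec_stack objects")
  ref <- stacks[[1]]
  for (s in stacks[-1]) {
    if (!identical(dim(s$data), dim(ref$data)))
      stopf("repeat geometry mismatch: %s vs %s",
            paste(dim(s$data), collapse = "x"), paste(dim(ref$data), collapse = "x"))
    if (!isTRUE(all.equal(s$offsets_ppm, ref$offsets_ppm)) ||
        !isTRUE(all.equal(s$reference_offsets_ppm, ref$reference_offsets_ppm)))
      stopf("repeat offset lists differ")
    if (!identical(s$normalized, ref$normalized))
      stopf("cannot average normalized with raw stacks")
  }
  mean_data <- Reduce(`+`, lapply(stacks, `[[`, "data")) / length(stacks)
  valid <- Reduce(`&`, lapply(stacks, `[[`, "valid"))
  zspec_stack(mean_data, ref$offsets_ppm, ref$reference_offsets_ppm,
              voxel_dims = ref$voxel_dims, field_mhz = ref$field_mhz,
              normalized = ref$normalized, valid = valid,
              b1_amplitude = ref$b1_amplitude, sat_duration = ref$sat_duration)
}
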