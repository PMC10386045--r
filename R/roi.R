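#' Named ROI masks on a stated grid
#'
#' @param masks Named list of logical matrices of identical dimensions.
#' @param voxel_dims Voxel dimensions `c(dx, dy, dz)` in mm.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(masks, voxel_dims) {
  if (!is.list(masks) || length(masks) < 1L || is.null(names(masks)) ||
      any(names(masks) == ""))
    stopf("masks must be a named list of logical matrices")
  dims <- dim(masks[[1]])
  for (m in masks) {
    if (!is.logical(m) || !is.matrix(m) || !all(dim(m) == dims))
      stopf("all masks must be logical matrices of identical dimensions")
  }
  if (length(voxel_dims) != 3L || any(voxel_dims <= 0))
    stopf("voxel_dims must be three positive lengths (mm)")
  structure(list(masks = masks, voxel_dims = as.numeric(voxel_dims)),
            class = "roi_set")
}

#' ROI summary statistics over the valid voxels of a map
#'
#' @param map A [param_map()]-style object (`values`, `valid`).
#' @param mask Logical matrix selecting the ROI.
#' @return A data frame with `mean`, `sd`, `sem` (`sd/sqrt(n)`) and
#'   `n_valid`.
#' @export
roi_stats <- function(map, mask) {
  stopifnot(inherits(map, "param_map"), is.logical(mask),
            all(dim(mask) == dim(map$values)))
  sel <- mask & map$valid
  n <- sum(sel)
  if (n == 0L) stopf("ROI contains no valid voxels")
  v <- map$values[sel]
  s <- if (n > 1L) sd(v) else 0
  data.frame(mean = mean(v), sd = s, sem = s / sqrt(n), n_valid = n)
}

#' Percent change of a summary value relative to baseline
#'
#' @param pre_mean Baseline value (nonzero).
#' @param post_mean Follow-up value.
#' @return `100 * (post - pre) / pre`.
#' @export
percent_change <- function(pre_mean, post_mean) {
  if (any(pre_mean == 0)) stopf("baseline value is zero; percent change undefined")
  100 * (post_mean - pre_mean) / pre_mean
}

#' Convert an AACID change to a pH change
#'
#' With the default calibration slope of -4 pH per AACID unit,
#' `delta_ph = -4 * (aacid_post - aacid_pre)`: an AACID increase means a
#' pH drop.
#'
#' @param aacid_pre,aacid_post AACID values before/after.
#' @param cal An [aacid_calibration()].
#' @return pH change (post minus pre).
#' @export
delta_ph <- function(aacid_pre, aacid_post, cal = aacid_calibration()) {
  stopifnot(inherits(cal, "aacid_calibration"))
  cal$slope * (aacid_post - aacid_pre)
}

#' Volume of a binary mask
#'
#' @param mask Logical matrix (or array) of voxels.
#' @param voxel_dims Voxel dimensions `c(dx, dy, dz)` in mm (required).
#' @return Volume in mm^3.
#' @examples
#' tumor_volume(matrix(TRUE, 10, 10), c(0.2, 0.2, 1))  # 4 mm^3
#' @export
tumor_volume <- function(mask, voxel_dims) {
  if (missing(voxel_dims) || length(voxel_dims) != 3L || any(voxel_dims <= 0))
    stopf("voxel_dims (three positive lengths in mm) are required")
  stopifnot(is.logical(mask))
  sum(mask) * prod(voxel_dims)
}

#' ROI time course across a series of parametric maps
#'
#' Summarizes one ROI over maps acquired at successive timepoints and
#' attaches the percent change of the ROI mean relative to the first
#' timepoint and, for AACID maps, the implied pH change via the
#' calibration slope.
#'
#' @param maps List of [param_map()]s, one per timepoint.
#' @param mask Logical ROI matrix.
#' @param timepoints Strictly increasing numeric vector (e.g. minutes),
#'   same length as `maps`; at least 2.
#' @param cal An [aacid_calibration()] used for the `delta_ph` column.
#' @return A data frame with one row per timepoint: `time`, `mean`, `sd`,
#'   `sem`, `n_valid`, `pct_change`, `delta_ph`.
#' @export
build_timecourse <- function(maps, mask, timepoints, cal = aacid_calibration()) {
  if (length(maps) < 2L) stopf("need at least 2 timepoints")
  if (length(timepoints) != length(maps))
    stopf("timepoints and maps must have equal length")
  if (anyDuplicated(timepoints)) stopf("duplicate timepoints")
  if (any(diff(timepoints) <= 0)) stopf("timepoints must be strictly increasing")
  rows <- do.call(rbind, lapply(maps, roi_stats, mask = mask))
  out <- cbind(data.frame(time = timepoints), rows)
  out$pct_change <- percent_change(out$mean[1], out$mean)
  out$delta_ph <- delta_ph(out$mean[1], out$mean, cal)
  out
}
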