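# NIfTI + JSON-sidecar input/output. The saturation-offset schedule cannot
# be carried portably in a NIfTI header, so every stack file <name>.nii(.gz)
# travels with a sidecar <name>.json listing offsets, references, pulse
# parameters and field strength.

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

as_nifti_image <- function(arr, voxel_dims) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(voxel_dims, rep(1, max(0, nd - 3)))[seq_len(nd)]
  img
}

#' Write a Z-spectrum stack as NIfTI + JSON sidecar
#'
#' The image is a 4-D volume (x, y, slice = 1, frame); invalid voxels are
#' stored as NaN across frames. The sidecar records `offsets_ppm`,
#' `reference_offsets_ppm`, `b1_amplitude`, `sat_duration`, `field_mhz`,
#' `voxel_dims` and the normalization flag.
#'
#' @param stack A [zspec_stack()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "zspec_stack"))
  d <- dim(stack$data)
  data <- stack$data
  data[array(!stack$valid, d)] <- NA_real_
  arr <- array(data, c(d[1], d[2], 1L, d[3]))
  RNifti::writeNifti(as_nifti_image(arr, stack$voxel_dims), path)
  meta <- list(offsets_ppm = stack$offsets_ppm,
               reference_offsets_ppm = stack$reference_offsets_ppm,
               b1_amplitude = stack$b1_amplitude,
               sat_duration = stack$sat_duration,
               field_mhz = stack$field_mhz,
               voxel_dims = stack$voxel_dims,
               normalized = stack$normalized)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a Z-spectrum stack written by [write_stack()]
#'
#' @param path Path to the `.nii`/`.nii.gz` file; the JSON sidecar must
#'   sit next to it.
#' @return A [zspec_stack()].
#' @export
read_stack <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stopf("missing sidecar %s", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(meta$field_mhz) || !is.finite(as.numeric(meta$field_mhz)))
    stopf("sidecar %s is missing required field 'field_mhz'", sp)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  n_frames <- d[length(d)]
  declared <- length(meta$offsets_ppm) + length(meta$reference_offsets_ppm)
  if (declared != n_frames)
    stopf("sidecar lists %d offsets but the volume has %d frames",
          declared, n_frames)
  data <- array(arr, c(d[1], d[2], n_frames))
  data[is.nan(data)] <- NA_real_
  b1 <- if (is.null(meta$b1_amplitude)) NA_real_ else as.numeric(meta$b1_amplitude)
  ts <- if (is.null(meta$sat_duration)) NA_real_ else as.numeric(meta$sat_duration)
  zspec_stack(data, meta$offsets_ppm,
              if (is.null(meta$reference_offsets_ppm)) numeric() else meta$reference_offsets_ppm,
              voxel_dims = as.numeric(meta$voxel_dims),
              field_mhz = as.numeric(meta$field_mhz),
              normalized = isTRUE(meta$normalized),
              b1_amplitude = b1, sat_duration = ts)
}

#' Write a parametric map (values + validity-mask companion)
#'
#' Writes `<path>` with NaN at invalid voxels and a companion
#' `<stem>_valid.nii(.gz)` binary mask.
#'
#' @param map A [param_map()]-style object or a `b0_map` (its `shift`
#'   matrix is written).
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  values <- if (inherits(map, "b0_map")) map$shift else map$values
  valid <- map$valid
  vd <- map$voxel_dims
  v <- values
  v[!valid] <- NA_real_
  RNifti::writeNifti(as_nifti_image(v, vd), path)
  mask_path <- sub("(\\.nii(\\.gz)?)$", "_valid\\1", path)
  RNifti::writeNifti(as_nifti_image(array(as.numeric(valid), dim(valid)), vd),
                     mask_path)
  invisible(path)
}

#' Read a parametric map written by [write_map()]
#'
#' @param path Path to the values image.
#' @param voxel_dims Voxel dimensions to attach (mm); read from the NIfTI
#'   header when omitted.
#' @return A [param_map()].
#' @export
read_map <- function(path, voxel_dims = NULL) {
  img <- RNifti::readNifti(path)
  values <- matrix(as.array(img), dim(img)[1], dim(img)[2])
  if (is.null(voxel_dims)) voxel_dims <- RNifti::pixdim(img)[1:3]
  mask_path <- sub("(\\.nii(\\.gz)?)$", "_valid\\1", path)
  if (file.exists(mask_path)) {
    valid <- matrix(as.array(RNifti::readNifti(mask_path)) > 0,
                    dim(values)[1], dim(values)[2])
  } else {
    valid <- is.finite(values)
  }
  values[is.nan(values)] <- NA_real_
  param_map(values, valid, voxel_dims)
}

#' Write an ROI set as a label image + JSON legend
#'
#' @param rois An [roi_set()].
#' @param path Output path ending in `.nii` or `.nii.gz`; a JSON sidecar
#'   maps label integers to ROI names.
#' @return `path`, invisibly.
#' @export
write_roi_set <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  label <- matrix(0L, nrow(rois$masks[[1]]), ncol(rois$masks[[1]]))
  for (i in seq_along(rois$masks)) label[rois$masks[[i]]] <- i
  RNifti::writeNifti(as_nifti_image(label, rois$voxel_dims), path)
  jsonlite::write_json(list(labels = as.list(setNames(seq_along(rois$masks),
                                                      names(rois$masks))),
                            voxel_dims = rois$voxel_dims),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ROI set written by [write_roi_set()]
#' @param path Path to the label image.
#' @return An [roi_set()].
#' @export
read_roi_set <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stopf("missing sidecar %s", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  img <- RNifti::readNifti(path)
  label <- matrix(round(as.array(img)), dim(img)[1], dim(img)[2])
  masks <- lapply(meta$labels, function(l) label == l)
  roi_set(masks, as.numeric(meta$voxel_dims))
}

#' Per-voxel CSV export of AACID/pH maps
#'
#' @param maps An `aacid_maps` object from [make_maps()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_voxels <- function(maps, path) {
  stopifnot(inherits(maps, "aacid_maps"))
  d <- dim(maps$aacid$values)
  df <- data.frame(x = rep(seq_len(d[1]), d[2]),
                   y = rep(seq_len(d[2]), each = d[1]),
                   aacid = as.vector(maps$aacid$values),
                   ph = as.vector(maps$ph$values),
                   valid = as.vector(maps$aacid$valid))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
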