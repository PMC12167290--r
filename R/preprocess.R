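#' Load a 3D volume from NIfTI or a DICOM series directory
#'
#' NIfTI files (`.nii`, `.nii.gz`) are read with RNifti; a directory is
#' interpreted as one DICOM series (uncompressed little-endian) read slice by
#' slice. Series whose slice thickness or slice gap varies are rejected, so
#' only constant-slice-thickness volumes enter the pipeline.
#'
#' @param path a NIfTI file or a directory containing one DICOM series.
#' @return A [volume_image] with spacing taken from the header.
#' @export
load_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path)) stop("cannot read volume: no such file ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) return(read_nifti_volume(path))
  stop("unsupported volume format: ", path, " (expected .nii/.nii.gz or a DICOM directory)")
}

#' Resample a volume to a target voxel spacing
#'
#' Voxel centres are placed at `index * spacing` mm; the output grid spans the
#' same physical extent to within one voxel per axis. Images use trilinear
#' interpolation, masks nearest-neighbour.
#'
#' @param vol a [volume_image] or [binary_mask].
#' @param target_spacing_mm target voxel spacing, default `(0.6, 0.6, 4.5)` mm.
#' @param interpolation `"trilinear"` or `"nearest"`; masks always use nearest.
#' @return The resampled object, same class as `vol`.
#' @export
resample <- function(vol, target_spacing_mm = c(0.6, 0.6, 4.5),
                     interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  target_spacing_mm <- check_spacing(target_spacing_mm)
  is_mask <- inherits(vol, "binary_mask")
  if (is_mask) interpolation <- "nearest"
  d <- dim(vol$data)
  if (max(abs(vol$spacing_mm - target_spacing_mm)) < 1e-9) return(vol)
  od <- pmax(1L, as.integer(round(d * vol$spacing_mm / target_spacing_mm)))
  out <- .cpp_resample3(as.numeric(vol$data), d, vol$spacing_mm, od, target_spacing_mm,
                        interpolation == "nearest")
  out <- array(out, od)
  if (is_mask) binary_mask(out != 0, target_spacing_mm) else volume_image(out, target_spacing_mm)
}

#' Center-crop then zero-pad a volume to a fixed shape
#'
#' Cropping removes symmetric margins (the extra voxel of an odd margin is
#' removed from the trailing side); padding adds zeros symmetrically with the
#' odd remainder going to the trailing side. Idempotent at the target shape.
#'
#' @param vol a [volume_image] or [binary_mask].
#' @param target_shape integer voxel counts, default `(256, 256, 32)`.
#' @return Same class as `vol`, with shape exactly `target_shape`.
#' @export
center_crop_pad <- function(vol, target_shape = c(256, 256, 32)) {
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape <= 0))
    stop("`target_shape` must be three positive integers")
  x <- vol$data
  d <- dim(x)
  idx <- vector("list", 3L)
  for (a in 1:3) {
    if (d[a] >= target_shape[a]) {
      start <- (d[a] - target_shape[a]) %/% 2L + 1L
      idx[[a]] <- seq.int(start, length.out = target_shape[a])
    } else idx[[a]] <- seq_len(d[a])
  }
  x <- x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  d <- dim(x)
  if (any(d < target_shape)) {
    out <- array(if (is.logical(x)) FALSE else 0, target_shape)
    lead <- (target_shape - d) %/% 2L
    out[lead[1] + seq_len(d[1]), lead[2] + seq_len(d[2]), lead[3] + seq_len(d[3])] <- x
    x <- out
  }
  if (inherits(vol, "binary_mask")) binary_mask(x, vol$spacing_mm) else volume_image(x, vol$spacing_mm)
}

#' Percentile-clip and rescale intensities to [0, 1]
#'
#' Values are clipped to the `p_low`/`p_high` percentiles of the whole volume
#' and mapped linearly onto `[0, 1]`.
#'
#' @param vol a [volume_image].
#' @param p_low,p_high clipping percentiles (0-100), defaults 1 and 99.
#' @return A [volume_image] with values in `[0, 1]`.
#' @export
normalize_intensity <- function(vol, p_low = 1, p_high = 99) {
  if (!is.numeric(p_low) || !is.numeric(p_high) || p_low >= p_high)
    stop("`p_low` must be smaller than `p_high`")
  q <- quantile(vol$data, probs = c(p_low, p_high) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    warning("constant-intensity volume: returning all 0.5")
    return(volume_image(array(0.5, dim(vol$data)), vol$spacing_mm))
  }
  x <- pmin(pmax(vol$data, q[1]), q[2])
  volume_image(array((x - q[1]) / (q[2] - q[1]), dim(x)), vol$spacing_mm)
}

#' Full preprocessing pipeline
#'
#' Resample to the target spacing, center-crop/pad to the target shape, then
#' percentile-clip and normalize to `[0, 1]`.
#'
#' @inheritParams resample
#' @inheritParams center_crop_pad
#' @param clip clipping percentiles passed to [normalize_intensity()].
#' @return A preprocessed [volume_image].
#' @export
preprocess_volume <- function(vol, target_spacing_mm = c(0.6, 0.6, 4.5),
                              target_shape = c(256, 256, 32), clip = c(1, 99)) {
  vol <- resample(vol, target_spacing_mm)
  vol <- center_crop_pad(vol, target_shape)
  normalize_intensity(vol, clip[1], clip[2])
}
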