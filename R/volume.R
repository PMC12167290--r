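#' 3D scalar volume with voxel spacing
#'
#' A `volume_image` is the package's container for a single-channel 3D image:
#' a numeric array indexed `(x, y, z)` plus the voxel spacing in millimetres.
#' The axis convention is `x` = left-right, `y` = posterior-anterior (anterior
#' is increasing `y`), `z` = inferior-superior (the slice axis of an axial
#' acquisition). Physical coordinates place the centre of voxel `(1,1,1)` at
#' 0 mm, so voxel `(i,j,k)` sits at `((i-1)*sx, (j-1)*sy, (k-1)*sz)` mm.
#'
#' @param data numeric 3D array.
#' @param spacing_mm numeric length-3 voxel spacing `(x, y, z)` in mm.
#' @return An object of class `volume_image`.
#' @examples
#' v <- volume_image(array(0, c(8, 8, 4)), spacing_mm = c(0.6, 0.6, 4.5))
#' dim(v$data)
#' @export
volume_image <- function(data, spacing_mm = c(0.6, 0.6, 4.5)) {
  data <- as_array3(data, "data")
  spacing_mm <- check_spacing(spacing_mm)
  structure(list(data = data, spacing_mm = spacing_mm), class = "volume_image")
}

#' Binary mask aligned to a volume
#'
#' @param data logical (or 0/1 numeric) 3D array.
#' @param spacing_mm voxel spacing in mm, shared with the paired volume.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing_mm = c(0.6, 0.6, 4.5)) {
  data <- as_array3(data, "data")
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1))) stop("mask values must be 0/1 or logical")
    data <- array(data != 0, dim = dim(data))
  }
  storage.mode(data) <- "logical"
  spacing_mm <- check_spacing(spacing_mm)
  structure(list(data = data, spacing_mm = spacing_mm), class = "binary_mask")
}

as_array3 <- function(x, what) {
  if (inherits(x, c("volume_image", "binary_mask"))) x <- x$data
  if (is.null(dim(x)) || length(dim(x)) != 3L)
    stop(sprintf("`%s` must be a 3D array", what))
  x
}

check_spacing <- function(spacing_mm) {
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be three strictly positive numbers")
  spacing_mm
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s voxels, spacing (%.3g, %.3g, %.3g) mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, spacing (%.3g, %.3g, %.3g) mm, %d foreground\n",
              paste(dim(x$data), collapse = "x"),
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3], sum(x$data)))
  invisible(x)
}

stopifnot_same_geometry <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("volumes/masks have mismatched shapes: ",
         paste(dim(a$data), collapse = "x"), " vs ", paste(dim(b$data), collapse = "x"))
  if (max(abs(a$spacing_mm - b$spacing_mm)) > 1e-6)
    stop("volumes/masks have mismatched voxel spacing")
  invisible(TRUE)
}

#' Write a volume or mask as NIfTI
#'
#' Volumes are stored as float32, masks as uint8; voxel spacing goes into the
#' NIfTI `pixdim` header fields.
#'
#' @param x a [volume_image] or [binary_mask].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  dat <- x$data
  if (inherits(x, "binary_mask")) storage.mode(dat) <- "integer"
  attr(dat, "pixdim") <- x$spacing_mm
  img <- RNifti::asNifti(dat,
                         datatype = if (inherits(x, "binary_mask")) "uint8" else "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) { img <- img[, , , 1L]; d <- dim(img) }
  if (length(d) != 3L) stop("expected a 3D NIfTI volume, got ", length(d), " dimensions")
  volume_image(array(as.numeric(img), dim = d), spacing_mm = RNifti::pixdim(img)[1:3])
}
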