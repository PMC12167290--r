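#' Otsu intensity threshold
#'
#' Threshold maximising the between-class variance of a fixed 256-bin
#' histogram over `[0, 1]` (values are clamped into that range; the volume is
#' expected to be normalized). Ties are broken towards the lowest boundary.
#'
#' @param vol a [volume_image] (or numeric array) with at least two distinct values.
#' @param bins number of histogram bins, default 256.
#' @return The threshold intensity (upper edge of the chosen bin).
#' @export
otsu_threshold <- function(vol, bins = 256L) {
  x <- if (inherits(vol, "volume_image")) vol$data else vol
  if (length(unique(as.numeric(x))) < 2L)
    stop("Otsu threshold undefined for constant input")
  x <- pmin(pmax(as.numeric(x), 0), 1)
  edges <- seq(0, 1, length.out = bins + 1L)
  centers <- (edges[-1] + edges[-(bins + 1L)]) / 2
  h <- tabulate(pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), bins), nbins = bins)
  p <- h / sum(h)
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[bins]
  # between-class variance at boundary after bin t (t = 1..bins-1)
  w0b <- w0[-bins]; mub <- mu[-bins]
  valid <- w0b > 0 & w0b < 1
  sigma_b <- rep(-Inf, bins - 1L)
  sigma_b[valid] <- (mu_t * w0b[valid] - mub[valid])^2 / (w0b[valid] * (1 - w0b[valid]))
  if (!any(is.finite(sigma_b))) stop("Otsu threshold undefined: all mass in one bin")
  # empty bins between modes tie exactly; take the middle of the optimal plateau
  top <- which(sigma_b >= max(sigma_b) - 1e-12)
  edges[as.integer(round(mean(top))) + 1L]
}

#' Segment the image background
#'
#' Otsu thresholding followed by morphological opening and closing (spherical
#' elements in mm) and extraction of the largest connected foreground
#' component; everything else is background. Zeroing the background of the
#' input yields the clean target volume for training.
#'
#' @param vol a normalized [volume_image].
#' @param opening_radius_mm,closing_radius_mm structuring-element radii in mm.
#' @return A [binary_mask] marking background voxels.
#' @export
segment_background <- function(vol, opening_radius_mm = 1.8, closing_radius_mm = 2.4) {
  thr <- otsu_threshold(vol)
  fg <- binary_mask(vol$data > thr, vol$spacing_mm)
  if (!any(fg$data) || all(fg$data))
    stop("degenerate segmentation: thresholding produced all-foreground or all-background")
  fg <- open_mm(fg, opening_radius_mm)
  fg <- close_mm(fg, closing_radius_mm)
  fg <- largest_component(fg)
  if (!any(fg$data)) stop("degenerate segmentation: no foreground component survived morphology")
  binary_mask(!fg$data, vol$spacing_mm)
}

#' Zero out background voxels
#'
#' @param vol a [volume_image].
#' @param background a [binary_mask] of background voxels.
#' @return A [volume_image] with background set to 0.
#' @export
remove_background <- function(vol, background) {
  stopifnot_same_geometry(vol, background)
  volume_image(vol$data * !background$data, vol$spacing_mm)
}

# --- pluggable bone segmentation backends -------------------------------------

bone_backends <- new.env(parent = emptyenv())

#' Register a bone segmentation backend
#'
#' A backend is a function `function(vol, ...)` returning a [binary_mask] of
#' all bone in the volume. The built-in `"threshold"` backend (Otsu within the
#' foreground plus opening) suits phantoms and bright-bone contrasts; `"file"`
#' reads an externally produced segmentation (e.g. from a dedicated bone
#' segmentation model) verbatim from a NIfTI path.
#'
#' @param name backend identifier.
#' @param fun function `(vol, ...) -> binary_mask`.
#' @export
register_bone_backend <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = bone_backends)
  invisible(name)
}

#' Segment bone with a pluggable backend
#'
#' @param vol a normalized [volume_image].
#' @param backend backend identifier; see [register_bone_backend()].
#' @param ... passed to the backend (`"file"` expects `path = `; `"threshold"`
#'   accepts `background` to restrict the search to the foreground).
#' @return A [binary_mask] of bone voxels.
#' @export
segment_bone <- function(vol, backend = "threshold", ...) {
  if (!exists(backend, envir = bone_backends, inherits = FALSE))
    stop("unknown bone backend '", backend, "'; registered backends: ",
         paste(sort(ls(bone_backends)), collapse = ", "))
  fun <- get(backend, envir = bone_backends, inherits = FALSE)
  out <- fun(vol, ...)
  if (!inherits(out, "binary_mask")) stop("bone backend '", backend, "' did not return a binary_mask")
  stopifnot_same_geometry(vol, out)
  out
}

bone_backend_threshold <- function(vol, background = NULL, opening_radius_mm = 1.2, ...) {
  fgdata <- if (is.null(background)) !segment_background(vol)$data else !background$data
  vals <- vol$data[fgdata]
  thr <- otsu_threshold(vals)
  bone <- binary_mask(vol$data > thr & fgdata, vol$spacing_mm)
  open_mm(bone, opening_radius_mm)
}

bone_backend_file <- function(vol, path, ...) {
  m <- read_nifti_volume(path)
  binary_mask(m$data != 0, vol$spacing_mm)
}

register_bone_backend("threshold", bone_backend_threshold)
register_bone_backend("file", bone_backend_file)

# ------------------------------------------------------------------------------

#' Localize the patella in a bone segmentation
#'
#' The patella is taken as the largest 26-connected bone component whose
#' centroid lies in the anterior region of the volume (the anterior
#' `anterior_fraction` of the y extent). If no component qualifies, a
#' condition of class `pseudoknee_patella_not_found` is signalled so callers
#' can fall back to an ellipsoid mask.
#'
#' @param bone_mask a [binary_mask] of all bone.
#' @param anterior_fraction fraction of the y extent counted as anterior,
#'   default 0.4.
#' @return A [binary_mask] containing only the patella component.
#' @export
localize_patella <- function(bone_mask, anterior_fraction = 0.4) {
  if (!any(bone_mask$data))
    patella_not_found("empty bone mask: nothing to localize")
  lab <- label_components(bone_mask)
  ny <- dim(bone_mask$data)[2]
  cutoff <- (1 - anterior_fraction) * ny
  sizes <- tabulate(lab)
  best <- 0L; best_size <- 0L
  for (comp in seq_along(sizes)) {
    if (sizes[comp] == 0L) next
    idx <- which(lab == comp, arr.ind = TRUE)
    if (mean(idx[, 2]) > cutoff && sizes[comp] > best_size) {
      best <- comp; best_size <- sizes[comp]
    }
  }
  if (best == 0L)
    patella_not_found("no bone component with an anterior centroid; use the ellipsoid fallback")
  binary_mask(lab == best, bone_mask$spacing_mm)
}

patella_not_found <- function(msg) {
  cond <- structure(class = c("pseudoknee_patella_not_found", "error", "condition"),
                    list(message = msg, call = sys.call(-1)))
  stop(cond)
}

#' Bowl-shaped inpainting mask around the patella
#'
#' All voxels whose physical Euclidean distance to the patella is at most
#' `offset_mm`, excluding the patella itself: the patella is the conditioning
#' anatomy and must survive masking. Anisotropic voxel spacing is respected
#' (the offset is isotropic in mm, not in voxels).
#'
#' @param patella a non-empty [binary_mask].
#' @param offset_mm offset radius in mm, default 30.
#' @return A [binary_mask].
#' @export
make_bowl_mask <- function(patella, offset_mm = 30) {
  if (!any(patella$data)) stop("cannot build a bowl mask around an empty patella mask")
  d2 <- distance_transform_sq(patella)
  binary_mask(d2 <= offset_mm^2 + 1e-9 & !patella$data, patella$spacing_mm)
}

#' Analytic ellipsoid mask in physical coordinates
#'
#' Fallback inpainting mask for volumes where the patella cannot be localized.
#'
#' @param shape voxel counts `(X, Y, Z)`.
#' @param spacing_mm voxel spacing in mm.
#' @param center_mm ellipsoid centre in mm (must lie inside the volume).
#' @param radii_mm ellipsoid semi-axes in mm (positive).
#' @return A [binary_mask].
#' @export
ellipsoid_fallback_mask <- function(shape, spacing_mm, center_mm, radii_mm) {
  shape <- as.integer(shape); spacing_mm <- check_spacing(spacing_mm)
  if (any(radii_mm <= 0)) stop("ellipsoid radii must be positive")
  ext <- (shape - 1) * spacing_mm
  if (any(center_mm < 0) || any(center_mm > ext))
    stop("ellipsoid centre lies outside the volume (extent ",
         paste(round(ext, 1), collapse = " x "), " mm)")
  xs <- (seq_len(shape[1]) - 1) * spacing_mm[1]
  ys <- (seq_len(shape[2]) - 1) * spacing_mm[2]
  zs <- (seq_len(shape[3]) - 1) * spacing_mm[3]
  dx2 <- ((xs - center_mm[1]) / radii_mm[1])^2
  dy2 <- ((ys - center_mm[2]) / radii_mm[2])^2
  dz2 <- ((zs - center_mm[3]) / radii_mm[3])^2
  m <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1 + 1e-12
  binary_mask(array(m, shape), spacing_mm)
}

#' Build the conditioning pair (masked image, mask)
#'
#' @param vol a [volume_image].
#' @param m2 the inpainting [binary_mask].
#' @return A list of class `conditioning_pair` with `m1` (volume with the mask
#'   region voided) and `m2`.
#' @export
build_conditioning <- function(vol, m2) {
  stopifnot_same_geometry(vol, m2)
  m1 <- volume_image(vol$data * !m2$data, vol$spacing_mm)
  structure(list(m1 = m1, m2 = m2), class = "conditioning_pair")
}

#' Full masking pipeline: background removal to inpainting mask
#'
#' Runs background segmentation, bone segmentation, patella localization and
#' bowl-mask construction; falls back to an analytic ellipsoid when no patella
#' is found and fallback parameters are supplied. The inpainting mask is
#' clipped to the foreground (the background is already zeroed, so masking air
#' would waste model capacity).
#'
#' @param vol a normalized [volume_image].
#' @param offset_mm bowl offset around the patella in mm.
#' @param anterior_fraction passed to [localize_patella()].
#' @param bone_backend passed to [segment_bone()].
#' @param fallback optional list `(center_mm, radii_mm)` for the ellipsoid fallback.
#' @param ... extra arguments for the bone backend.
#' @return A list with `y0` (background-zeroed volume), `m2`, `pair`
#'   (a `conditioning_pair`), plus the intermediate `background`, `bone` and
#'   `patella` masks (`patella` is `NULL` when the fallback was used).
#' @export
mask_pathology <- function(vol, offset_mm = 30, anterior_fraction = 0.4,
                           bone_backend = "threshold", fallback = NULL, ...) {
  background <- segment_background(vol)
  y0 <- remove_background(vol, background)
  bone <- segment_bone(y0, backend = bone_backend, background = background, ...)
  patella <- tryCatch(localize_patella(bone, anterior_fraction),
                      pseudoknee_patella_not_found = function(e) NULL)
  if (!is.null(patella)) {
    m2 <- make_bowl_mask(patella, offset_mm)
  } else if (!is.null(fallback)) {
    m2 <- ellipsoid_fallback_mask(dim(vol$data), vol$spacing_mm,
                                  fallback$center_mm, fallback$radii_mm)
  } else {
    stop("patella not found and no ellipsoid fallback configured; ",
         "supply `fallback = list(center_mm=, radii_mm=)`")
  }
  m2 <- binary_mask(m2$data & !background$data, vol$spacing_mm)
  list(y0 = y0, m2 = m2, pair = build_conditioning(y0, m2),
       background = background, bone = bone, patella = patella)
}
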