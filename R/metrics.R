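#' Masked image-quality metrics
#'
#' Scores computed over the masked region only, as used for inpainting
#' evaluation. `masked_mse` is the mean squared difference across mask voxels;
#' `masked_psnr` is `10 log10(data_range^2 / mse)` (infinite for identical
#' inputs); `masked_ssim` zeroes both volumes outside the mask, computes the
#' dense per-voxel SSIM map over the whole volume (Gaussian window), and
#' averages the map at mask voxels. With an all-ones mask each metric reduces
#' to its standard whole-volume counterpart.
#'
#' @param ref,pred reference and predicted volumes ([volume_image] or array).
#' @param mask a [binary_mask] (or logical array); must be non-empty.
#' @return A scalar.
#' @export
masked_mse <- function(ref, pred, mask) {
  r <- as_array3(ref, "ref"); p <- as_array3(pred, "pred"); m <- as_array3(mask, "mask")
  if (!identical(dim(r), dim(p)) || !identical(dim(r), dim(m)))
    stop("ref/pred/mask shapes differ")
  m <- m != 0
  if (!any(m)) stop("mask is empty")
  mean((r[m] - p[m])^2)
}

#' @rdname masked_mse
#' @param data_range intensity range of the data, default 1.
#' @export
masked_psnr <- function(ref, pred, mask, data_range = 1.0) {
  mse <- masked_mse(ref, pred, mask)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' @rdname masked_mse
#' @param window odd Gaussian window width in voxels, default 7.
#' @param sigma Gaussian window standard deviation in voxels, default 1.5.
#' @export
masked_ssim <- function(ref, pred, mask, data_range = 1.0, window = 7L, sigma = 1.5) {
  r <- as_array3(ref, "ref"); p <- as_array3(pred, "pred"); m <- as_array3(mask, "mask")
  if (!identical(dim(r), dim(p)) || !identical(dim(r), dim(m)))
    stop("ref/pred/mask shapes differ")
  m <- m != 0
  if (!any(m)) stop("mask is empty")
  if (sum(m) < window^3)
    stop("mask (", sum(m), " voxels) is smaller than the SSIM window (", window^3, " voxels)")
  r <- r * m; p <- p * m
  map <- ssim_map(r, p, data_range = data_range, window = window, sigma = sigma)
  mean(map[m])
}

#' Dense structural-similarity map of two volumes
#'
#' Per-voxel SSIM with a Gaussian-weighted local window (symmetric boundary
#' padding) and the usual stabilizers `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`.
#'
#' @inheritParams masked_ssim
#' @return A 3D array of per-voxel SSIM values.
#' @export
ssim_map <- function(ref, pred, data_range = 1.0, window = 7L, sigma = 1.5) {
  a <- as_array3(ref, "ref"); b <- as_array3(pred, "pred")
  if (!identical(dim(a), dim(b))) stop("shapes differ")
  if (window %% 2L == 0L) stop("`window` must be odd")
  kern <- gauss_kernel(sigma, radius = window %/% 2L)
  smooth <- function(x) {
    for (ax in 1:3) x <- filter_axis(x, kern, ax)
    x
  }
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  mu1 <- smooth(a); mu2 <- smooth(b)
  s11 <- smooth(a * a) - mu1 * mu1
  s22 <- smooth(b * b) - mu2 * mu2
  s12 <- smooth(a * b) - mu1 * mu2
  ((2 * mu1 * mu2 + c1) * (2 * s12 + c2)) /
    ((mu1^2 + mu2^2 + c1) * (s11 + s22 + c2))
}

#' Trochlear landmark triple on one axial slice
#'
#' In-plane (x, y) positions in mm of the medial condyle apex, the lateral
#' condyle apex and the sulcus nadir. "Medial" is the smaller-x apex by
#' convention.
#'
#' @param medial,lateral,sulcus numeric `(x, y)` pairs in mm.
#' @return An object of class `landmark_triple`.
#' @export
landmark_triple <- function(medial, lateral, sulcus) {
  pts <- list(medial = as.numeric(medial), lateral = as.numeric(lateral),
              sulcus = as.numeric(sulcus))
  for (nm in names(pts)) if (length(pts[[nm]]) != 2L || any(!is.finite(pts[[nm]])))
    stop("`", nm, "` must be a finite (x, y) pair")
  if (all(pts$medial == pts$lateral)) stop("condyle points must be distinct")
  structure(pts, class = "landmark_triple")
}

#' Sulcus angle from a landmark triple
#'
#' The angle at the sulcus nadir between the rays to the two condyle apices,
#' in degrees; 180 for a flat (collinear) trochlea. Larger angles indicate a
#' shallower, more dysplastic groove.
#'
#' @param lm a [landmark_triple()].
#' @return Angle in degrees, in `(0, 180]`.
#' @export
sulcus_angle <- function(lm) {
  v1 <- lm$medial - lm$sulcus
  v2 <- lm$lateral - lm$sulcus
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0)
    stop("sulcus point coincides with a condyle apex; angle undefined")
  acos(pmin(pmax(sum(v1 * v2) / (n1 * n2), -1), 1)) * 180 / pi
}

#' Trochlear groove depth from a landmark triple
#'
#' Anterior-direction (y) distance from the condylar apex level to the sulcus
#' nadir. The apex level is the mean of the two condyle apex heights by
#' default (`method = "max"` uses the higher one).
#'
#' @param lm a [landmark_triple()].
#' @param method `"mean"` (default) or `"max"` aggregation of the two apices.
#' @return Depth in mm (0 for a flat trochlea).
#' @export
trochlear_groove_depth <- function(lm, method = c("mean", "max")) {
  method <- match.arg(method)
  apex <- if (method == "mean") mean(c(lm$medial[2], lm$lateral[2])) else
    max(lm$medial[2], lm$lateral[2])
  apex - lm$sulcus[2]
}

#' Detect trochlear landmarks on an axial slice
#'
#' Builds the anterior bone-surface profile `y(x)` of the femur on the given
#' slice (the most anterior bone voxel per x column), finds its local maxima
#' (plateau-aware), takes the two highest as the condyle apices and the
#' minimum between them as the sulcus nadir. A single flat plateau (fully
#' filled groove) degenerates to apices at the plateau ends and the nadir at
#' its centre (depth 0, angle 180).
#'
#' @param vol the [volume_image] (carries the voxel spacing).
#' @param bone_mask [binary_mask] of the femur; if the patella is part of the
#'   mask pass `patella_mask` so it can be excluded from the profile.
#' @param slice axial slice index.
#' @param patella_mask optional [binary_mask] removed from `bone_mask`.
#' @return A [landmark_triple()] with attribute `"slice"`.
#' @export
detect_trochlea_landmarks <- function(vol, bone_mask, slice, patella_mask = NULL) {
  stopifnot_same_geometry(vol, bone_mask)
  d <- dim(bone_mask$data)
  if (slice < 1L || slice > d[3]) stop("slice index out of range")
  m <- bone_mask$data[, , slice]
  if (!is.null(patella_mask)) m <- m & !patella_mask$data[, , slice]
  sx <- vol$spacing_mm[1]; sy <- vol$spacing_mm[2]
  prof <- apply(m, 1L, function(col) { w <- which(col); if (length(w)) max(w) else NA_integer_ })
  valid <- which(!is.na(prof))
  if (length(valid) < 3L) stop("no usable bone surface on slice ", slice)
  xs <- (valid - 1) * sx
  ys <- (prof[valid] - 1) * sy

  # plateau-aware local maxima over the run-length-encoded profile
  r <- rle(ys)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nruns <- length(r$values)
  is_max <- vapply(seq_len(nruns), function(i) {
    left_ok <- i == 1L || r$values[i] > r$values[i - 1L]
    right_ok <- i == nruns || r$values[i] > r$values[i + 1L]
    left_ok && right_ok
  }, logical(1))
  peaks <- which(is_max)
  run_center <- function(i) mean(xs[starts[i]:ends[i]])

  if (length(peaks) == 1L && r$lengths[peaks] >= 3L &&
      abs(r$values[peaks] - max(ys)) < 1e-9) {
    # flat plateau: degenerate (filled) trochlea
    i <- peaks
    med <- c(xs[starts[i]], r$values[i])
    lat <- c(xs[ends[i]], r$values[i])
    sul <- c(run_center(i), r$values[i])
    lm <- landmark_triple(med, lat, sul)
    attr(lm, "slice") <- slice
    return(lm)
  }
  if (length(peaks) < 2L)
    stop("fewer than two surface maxima on slice ", slice, ": not a trochlea-bearing slice")
  hts <- r$values[peaks]
  top <- max(hts)
  cand <- peaks[abs(hts - top) < 1e-9]
  if (length(cand) >= 2L) {
    p1 <- cand[1]; p2 <- cand[length(cand)]
  } else {
    ord <- peaks[order(r$values[peaks], decreasing = TRUE)][1:2]
    p1 <- min(ord); p2 <- max(ord)
  }
  med <- c(run_center(p1), r$values[p1])
  lat <- c(run_center(p2), r$values[p2])
  between <- (ends[p1] + 1L):(starts[p2] - 1L)
  if (!length(between)) stop("no profile between the condyle apices on slice ", slice)
  ymin <- min(ys[between])
  sel <- between[abs(ys[between] - ymin) < 1e-9]
  sul <- c(mean(xs[sel]), ymin)
  lm <- landmark_triple(med, lat, sul)
  attr(lm, "slice") <- slice
  lm
}

#' Landmarks from a phantom's ground-truth table
#'
#' @param ph a `phantom_truth`.
#' @param slice slice index; defaults to the phantom's central slice.
#' @return A [landmark_triple()].
#' @export
phantom_landmarks <- function(ph, slice = ph$central_slice) {
  row <- ph$landmarks[ph$landmarks$slice == slice, ]
  if (nrow(row) != 1L) stop("no landmarks for slice ", slice)
  landmark_triple(c(row$medial_x, row$medial_y),
                  c(row$lateral_x, row$lateral_y),
                  c(row$sulcus_x, row$sulcus_y))
}
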