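#' Wavelet subband names
#'
#' Subband letter order: the first letter is the filter applied along the
#' first array axis (x), then y, then z; `l` = low-pass, `h` = high-pass.
#' @export
WAVELET_BANDS <- c("lll", "llh", "lhl", "lhh", "hll", "hlh", "hhl", "hhh")

# the four subbands carrying an x/y high-pass pair, L1-regularized in training
HF_REG_BANDS <- c("lhh", "hlh", "hhl", "hhh")

#' 8-subband wavelet coefficient tensor
#'
#' A `wavelet_tensor` is a numeric 4D array `(X/2, Y/2, Z/2, 8)` whose fourth
#' axis enumerates the subbands in the order [WAVELET_BANDS].
#'
#' @param coeffs numeric 4D array with 8 subbands on the fourth axis.
#' @param spacing_mm voxel spacing of the *source* volume (carried along so
#'   [idwt3()] can restore it); may be `NULL`.
#' @return An object of class `wavelet_tensor`.
#' @export
wavelet_tensor <- function(coeffs, spacing_mm = NULL) {
  d <- dim(coeffs)
  if (length(d) != 4L || d[4] != 8L)
    stop("`coeffs` must be a 4D array with 8 subbands on the fourth axis")
  dimnames(coeffs) <- c(rep(list(NULL), 3), list(WAVELET_BANDS))
  structure(coeffs, class = "wavelet_tensor", spacing_mm = spacing_mm)
}

#' @export
Ops.wavelet_tensor <- function(e1, e2) {
  sp <- if (inherits(e1, "wavelet_tensor")) attr(e1, "spacing_mm") else attr(e2, "spacing_mm")
  a1 <- if (inherits(e1, "wavelet_tensor")) unclass_wt(e1) else e1
  if (!missing(e2)) {
    a2 <- if (inherits(e2, "wavelet_tensor")) unclass_wt(e2) else e2
    out <- get(.Generic)(a1, a2)
  } else out <- get(.Generic)(a1)
  if (is.logical(out)) out else wavelet_tensor(out, sp)
}

unclass_wt <- function(x) { attributes(x) <- list(dim = dim(x)); x }

#' Extract one subband
#'
#' @param wt a [wavelet_tensor].
#' @param band subband name, one of [WAVELET_BANDS].
#' @return A 3D numeric array.
#' @export
subband <- function(wt, band) {
  band <- match.arg(band, WAVELET_BANDS)
  x <- unclass_wt(wt)[, , , match(band, WAVELET_BANDS), drop = FALSE]
  dim(x) <- dim(x)[1:3]
  x
}

haar_split <- function(x, axis) {
  n <- dim(x)[axis]
  i1 <- seq(1L, n, 2L); i2 <- seq(2L, n, 2L)
  s <- sqrt(2)
  switch(axis,
         list(lo = (x[i1, , , drop = FALSE] + x[i2, , , drop = FALSE]) / s,
              hi = (x[i1, , , drop = FALSE] - x[i2, , , drop = FALSE]) / s),
         list(lo = (x[, i1, , drop = FALSE] + x[, i2, , drop = FALSE]) / s,
              hi = (x[, i1, , drop = FALSE] - x[, i2, , drop = FALSE]) / s),
         list(lo = (x[, , i1, drop = FALSE] + x[, , i2, drop = FALSE]) / s,
              hi = (x[, , i1, drop = FALSE] - x[, , i2, drop = FALSE]) / s))
}

haar_merge <- function(lo, hi, axis) {
  d <- dim(lo); d[axis] <- 2L * d[axis]
  out <- array(0, d)
  n <- d[axis]
  i1 <- seq(1L, n, 2L); i2 <- seq(2L, n, 2L)
  s <- sqrt(2)
  if (axis == 1L) { out[i1, , ] <- (lo + hi) / s; out[i2, , ] <- (lo - hi) / s }
  else if (axis == 2L) { out[, i1, ] <- (lo + hi) / s; out[, i2, ] <- (lo - hi) / s }
  else { out[, , i1] <- (lo + hi) / s; out[, , i2] <- (lo - hi) / s }
  out
}

#' Single-level 3D Haar wavelet analysis
#'
#' Orthonormal Haar filters `(1, 1)/sqrt(2)` and `(1, -1)/sqrt(2)` applied
#' along each axis, producing 8 half-resolution subbands. Orthonormality makes
#' the transform energy-preserving (Parseval), so unit-variance white noise in
#' image space stays unit-variance white in wavelet space — the property the
#' diffusion process relies on. A constant volume of value `c` maps to an
#' `lll` subband constant at `2*sqrt(2)*c` with all other subbands zero.
#'
#' @param vol a [volume_image] or 3D numeric array with even extents.
#' @return A [wavelet_tensor].
#' @export
dwt3 <- function(vol) {
  sp <- if (inherits(vol, "volume_image")) vol$spacing_mm else
    if (inherits(vol, "binary_mask")) vol$spacing_mm else NULL
  x <- as_array3(vol, "vol")
  storage.mode(x) <- "double"
  d <- dim(x)
  odd <- which(d %% 2L != 0L)
  if (length(odd))
    stop("dwt3 requires even extents; axis ", paste(c("x", "y", "z")[odd], collapse = ", "),
         " has odd length")
  s1 <- haar_split(x, 1L)
  out <- array(0, c(d %/% 2L, 8L))
  k <- 0L
  for (b1 in c("lo", "hi")) {
    s2 <- haar_split(s1[[b1]], 2L)
    for (b2 in c("lo", "hi")) {
      s3 <- haar_split(s2[[b2]], 3L)
      for (b3 in c("lo", "hi")) {
        k <- k + 1L
        out[, , , k] <- s3[[b3]]
      }
    }
  }
  wavelet_tensor(out, sp)
}

#' Single-level 3D Haar wavelet synthesis
#'
#' Exact inverse of [dwt3()].
#'
#' @param wt a [wavelet_tensor].
#' @param as_volume return a [volume_image] (default) or a bare array.
#' @return The reconstructed volume.
#' @export
idwt3 <- function(wt, as_volume = TRUE) {
  if (!inherits(wt, "wavelet_tensor")) stop("`wt` must be a wavelet_tensor")
  x <- unclass_wt(wt)
  get_band <- function(k) { b <- x[, , , k, drop = FALSE]; dim(b) <- dim(x)[1:3]; b }
  # merge z within each (axis1, axis2) branch, then y, then x
  ll <- haar_merge(get_band(1L), get_band(2L), 3L)
  lh <- haar_merge(get_band(3L), get_band(4L), 3L)
  hl <- haar_merge(get_band(5L), get_band(6L), 3L)
  hh <- haar_merge(get_band(7L), get_band(8L), 3L)
  lo <- haar_merge(ll, lh, 2L)
  hi <- haar_merge(hl, hh, 2L)
  vol <- haar_merge(lo, hi, 1L)
  sp <- attr(wt, "spacing_mm")
  if (as_volume && !is.null(sp)) volume_image(vol, sp) else vol
}
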