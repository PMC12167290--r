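#' Specification of a synthetic knee phantom
#'
#' The phantom is a stylised axial knee: a femur-like slab whose anterior
#' surface carries two condylar ridges separated by a V-shaped trochlear
#' groove, an ellipsoidal patella anterior to the groove, a smooth
#' soft-tissue envelope and a dark background with additive Gaussian noise.
#' Groove geometry is analytic, so the sulcus angle (SA) and trochlear groove
#' depth (TGD) of the generated anatomy are known exactly.
#'
#' The V-profile couples angle, depth and condyle separation: the condyle
#' apices sit `d = TGD * tan(SA/2)` mm either side of the sulcus nadir. Flat
#' grooves (`groove_depth_mm = 0`) have an SA of 180 degrees by construction
#' and use a default condyle separation. The anterior apex line is snapped to
#' the voxel-centre grid so that voxelised surfaces realise the requested
#' geometry without sub-voxel bias.
#'
#' @param shape integer voxel counts `(X, Y, Z)`.
#' @param spacing_mm voxel spacing in mm; the default matches axial
#'   proton-density fat-saturated knee protocols (0.6 x 0.6 x 4.5 mm).
#' @param sulcus_angle_deg sulcus angle in degrees, in `(90, 180]`.
#' @param groove_depth_mm trochlear groove depth in mm, `>= 0`.
#' @param patella_radii_mm ellipsoid semi-axes of the patella (mm).
#' @param patella_center_mm patella centre (mm); `NULL` places it anterior to
#'   the groove, centred in x and z.
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param bone_intensity,soft_tissue_intensity,background_intensity tissue
#'   class intensities in `[0, 1]`.
#' @param seed integer RNG seed; equal specs give bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(112, 112, 16),
                         spacing_mm = c(0.6, 0.6, 4.5),
                         sulcus_angle_deg = 150,
                         groove_depth_mm = 5,
                         patella_radii_mm = c(9, 4.5, 9),
                         patella_center_mm = NULL,
                         noise_sd = 0.02,
                         bone_intensity = 0.9,
                         soft_tissue_intensity = 0.4,
                         background_intensity = 0.05,
                         seed = 1L) {
  spec <- list(shape = as.integer(shape), spacing_mm = as.numeric(spacing_mm),
               sulcus_angle_deg = sulcus_angle_deg, groove_depth_mm = groove_depth_mm,
               patella_radii_mm = as.numeric(patella_radii_mm),
               patella_center_mm = if (is.null(patella_center_mm)) NULL else as.numeric(patella_center_mm),
               noise_sd = noise_sd, bone_intensity = bone_intensity,
               soft_tissue_intensity = soft_tissue_intensity,
               background_intensity = background_intensity, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  fail <- function(field, msg) stop(sprintf("invalid phantom spec: `%s` %s", field, msg), call. = FALSE)
  if (length(spec$shape) != 3L || any(spec$shape <= 0)) fail("shape", "must be three positive integers")
  if (length(spec$spacing_mm) != 3L || any(spec$spacing_mm <= 0)) fail("spacing_mm", "must be three positive numbers")
  if (!is.finite(spec$sulcus_angle_deg) || spec$sulcus_angle_deg <= 90 || spec$sulcus_angle_deg > 180)
    fail("sulcus_angle_deg", "must lie in (90, 180]")
  if (!is.finite(spec$groove_depth_mm) || spec$groove_depth_mm < 0) fail("groove_depth_mm", "must be >= 0")
  if (length(spec$patella_radii_mm) != 3L || any(spec$patella_radii_mm <= 0))
    fail("patella_radii_mm", "must be three positive radii")
  if (!is.finite(spec$noise_sd) || spec$noise_sd < 0) fail("noise_sd", "must be >= 0")
  for (f in c("bone_intensity", "soft_tissue_intensity", "background_intensity"))
    if (!is.finite(spec[[f]]) || spec[[f]] < 0 || spec[[f]] > 1) fail(f, "must lie in [0, 1]")
  geom <- phantom_geometry(spec)
  if (geom$d > geom$envelope_a - 4)
    stop(sprintf(paste("invalid phantom spec: `sulcus_angle_deg`/`groove_depth_mm` imply a condyle",
                       "separation of %.1f mm that exceeds the soft-tissue envelope (%.1f mm);",
                       "reduce the angle, the depth, or enlarge `shape`"),
                 geom$d, geom$envelope_a - 4), call. = FALSE)
  invisible(spec)
}

# derived deterministic geometry (all mm); apex line snapped to the y grid
phantom_geometry <- function(spec) {
  sx <- spec$spacing_mm[1]; sy <- spec$spacing_mm[2]; sz <- spec$spacing_mm[3]
  ext <- (spec$shape - 1) * spec$spacing_mm
  cx <- ext[1] / 2
  envelope_a <- ext[1] / 2 - 8 * sx        # in-plane semi-axes of soft tissue
  envelope_b <- 0.38 * ext[2]
  envelope_cy <- ext[2] / 2 - 4 * sy
  y_apex <- round((envelope_cy + 0.12 * ext[2]) / sy) * sy   # grid-aligned condyle apex line
  g <- spec$groove_depth_mm
  half <- spec$sulcus_angle_deg / 2 * pi / 180
  d <- if (g > 0 && spec$sulcus_angle_deg < 180) g * tan(half) else 12
  list(cx = cx, ext = ext, envelope_a = envelope_a, envelope_b = envelope_b,
       envelope_cy = envelope_cy, y_apex = y_apex, d = d,
       w_half = min(d + 6, envelope_a - 3),
       y_post = max(y_apex - max(g + 4, min(16, 0.55 * envelope_b)),
                    envelope_cy - envelope_b + 2 * sy, 0),
       rounding = 0.08)                     # parabolic condyle falloff (1/mm)
}

run_with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic knee phantom with known ground truth
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_truth`: a list with `volume`
#'   ([volume_image]), `bone_mask` (femur plus patella), `patella_mask`,
#'   `background_mask` ([binary_mask]s), `landmarks` (per-slice condyle apices
#'   and sulcus nadir in mm), `central_slice` and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(64, 64, 8), noise_sd = 0))
#' ph$volume
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  # an SA of exactly 180 degrees is a flat trochlea: no groove is realisable
  g <- if (spec$sulcus_angle_deg >= 180) 0 else spec$groove_depth_mm
  build_phantom(spec, groove_depth_eff = g)
}

#' Generate a phantom with a dysplastic (partially filled) trochlear groove
#'
#' Emulates trochlear dysplasia by filling the groove of the healthy phantom:
#' the sulcus nadir rises towards the condylar apex line while the condyles
#' stay fixed, so the measured sulcus angle increases monotonically with
#' `dysplasia_fill` and the groove depth shrinks to zero at full fill.
#'
#' @param spec a [phantom_spec()] describing the underlying healthy knee.
#' @param dysplasia_fill fraction of the groove depth that is filled, in `[0, 1]`.
#' @return A `phantom_truth`, as [generate_phantom()].
#' @export
generate_pathological_phantom <- function(spec, dysplasia_fill) {
  validate_phantom_spec(spec)
  if (!is.numeric(dysplasia_fill) || length(dysplasia_fill) != 1L ||
      !is.finite(dysplasia_fill) || dysplasia_fill < 0 || dysplasia_fill > 1)
    stop("`dysplasia_fill` must be a single number in [0, 1]")
  build_phantom(spec, groove_depth_eff = spec$groove_depth_mm * (1 - dysplasia_fill))
}

build_phantom <- function(spec, groove_depth_eff) {
  geom <- phantom_geometry(spec)
  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  sx <- spec$spacing_mm[1]; sy <- spec$spacing_mm[2]; sz <- spec$spacing_mm[3]
  xm <- (seq_len(nx) - 1) * sx
  ym <- (seq_len(ny) - 1) * sy
  zm <- (seq_len(nz) - 1) * sz
  u <- xm - geom$cx
  g <- groove_depth_eff
  d <- geom$d

  # anterior femoral surface y(x): V-groove between the apices, rounded outside
  vdepth <- if (d > 0) g * (1 - abs(u) / d) else rep(0, length(u))
  y_surf <- ifelse(abs(u) <= d,
                   geom$y_apex - vdepth,
                   geom$y_apex - geom$rounding * (abs(u) - d)^2)
  if (g > 0) {
    # realise the apex and nadir landmarks on the voxel grid: one-voxel-wide
    # flats at the condyle apices and the sulcus nadir
    y_surf[abs(abs(u) - d) <= sx / 2 + 1e-9] <- geom$y_apex
    y_surf[abs(u) <= sx / 2 + 1e-9] <- geom$y_apex - g
  }

  femur2d <- outer(seq_len(nx), seq_len(ny), function(i, j)
    abs(u[i]) <= geom$w_half & ym[j] >= geom$y_post & ym[j] <= y_surf[i])
  envelope2d <- outer(seq_len(nx), seq_len(ny), function(i, j)
    (u[i] / geom$envelope_a)^2 + ((ym[j] - geom$envelope_cy) / geom$envelope_b)^2 <= 1)

  pc <- spec$patella_center_mm
  if (is.null(pc)) pc <- c(geom$cx, geom$y_apex + 4 + spec$patella_radii_mm[2], geom$ext[3] / 2)
  pr <- spec$patella_radii_mm

  femur <- array(FALSE, spec$shape)
  envelope <- array(FALSE, spec$shape)
  for (k in seq_len(nz)) { femur[, , k] <- femur2d; envelope[, , k] <- envelope2d }
  patella <- array(FALSE, spec$shape)
  iz <- which(abs(zm - pc[3]) <= pr[3])
  if (length(iz)) {
    pat2d <- outer(seq_len(nx), seq_len(ny), function(i, j)
      ((xm[i] - pc[1]) / pr[1])^2 + ((ym[j] - pc[2]) / pr[2])^2)
    for (k in iz) {
      rem <- 1 - ((zm[k] - pc[3]) / pr[3])^2
      patella[, , k] <- pat2d <= rem
    }
  }
  patella <- patella & envelope & !femur   # patella embedded in soft tissue, never femur

  vol <- array(spec$background_intensity, spec$shape)
  vol[envelope] <- spec$soft_tissue_intensity
  vol[femur | patella] <- spec$bone_intensity

  # smooth tissue boundaries in-plane, then add noise
  sigma_vox <- 1.2
  kern <- gauss_kernel(sigma_vox)
  vol <- filter_axis(vol, kern, 1L)
  vol <- filter_axis(vol, kern, 2L)
  if (spec$noise_sd > 0)
    vol <- vol + run_with_seed(spec$seed, array(rnorm(length(vol), sd = spec$noise_sd), dim(vol)))
  vol <- pmin(pmax(vol, 0), 1)
  vol <- array(vol, spec$shape)

  landmarks <- data.frame(slice = seq_len(nz),
                          medial_x = geom$cx - d, medial_y = geom$y_apex,
                          lateral_x = geom$cx + d, lateral_y = geom$y_apex,
                          sulcus_x = geom$cx, sulcus_y = geom$y_apex - g)
  structure(list(volume = volume_image(vol, spec$spacing_mm),
                 bone_mask = binary_mask(femur | patella, spec$spacing_mm),
                 patella_mask = binary_mask(patella, spec$spacing_mm),
                 background_mask = binary_mask(!envelope, spec$spacing_mm),
                 landmarks = landmarks,
                 central_slice = as.integer(round(nz / 2)),
                 groove_depth_eff_mm = g, condyle_half_separation_mm = d,
                 spec = spec),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %s voxels; SA truth %.1f deg, TGD truth %.1f mm (central slice %d)\n",
              paste(x$spec$shape, collapse = "x"),
              if (x$groove_depth_eff_mm > 0) 2 * atan2(x$condyle_half_separation_mm, x$groove_depth_eff_mm) * 180 / pi else 180,
              x$groove_depth_eff_mm, x$central_slice))
  invisible(x)
}

#' Write a phantom to disk
#'
#' Writes the volume (float32 NIfTI), the three truth masks (uint8 NIfTI) and
#' the landmark table (CSV, mm coordinates per slice).
#'
#' @param ph a `phantom_truth`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(ph, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_volume(ph$volume, file.path(dir, "volume.nii.gz"))
  write_volume(ph$bone_mask, file.path(dir, "bone_mask.nii.gz"))
  write_volume(ph$patella_mask, file.path(dir, "patella_mask.nii.gz"))
  write_volume(ph$background_mask, file.path(dir, "background_mask.nii.gz"))
  write.csv(ph$landmarks, file.path(dir, "landmarks.csv"), row.names = FALSE)
  invisible(dir)
}

gauss_kernel <- function(sigma_vox, radius = max(1L, ceiling(3 * sigma_vox))) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

filter_axis <- function(arr, kernel, axis) {
  array(.cpp_filter_axis(as.numeric(arr), dim(arr), kernel, axis - 1L), dim(arr))
}
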