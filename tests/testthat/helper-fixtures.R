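# shared fixtures: desk-scale phantoms and the tiny training setup

desk_phantom <- function(sulcus = 130, g = 3, fill = NULL, seed = 1, noise = 0.02) {
  spec <- phantom_spec(shape = c(64, 64, 8), spacing_mm = c(0.6, 0.6, 4.5),
                       sulcus_angle_deg = sulcus, groove_depth_mm = g,
                       patella_radii_mm = c(5, 2.5, 7), noise_sd = noise, seed = seed)
  if (is.null(fill)) generate_phantom(spec) else generate_pathological_phantom(spec, fill)
}

# 16x16x8 training item: downsampled phantom volume plus a groove-covering
# bowl mask around the patella (8 mm offset reaches the sulcus nadir; the
# patella itself is excluded, as in the full-scale bowl mask)
desk_item <- function(ph = desk_phantom()) {
  v <- center_crop_pad(resample(ph$volume, c(2.4, 2.4, 4.5)), c(16, 16, 8))
  pm <- center_crop_pad(resample(ph$patella_mask, c(2.4, 2.4, 4.5)), c(16, 16, 8))
  m2 <- dilate_mm(pm, 8)
  m2 <- binary_mask(m2$data & !pm$data, m2$spacing_mm)
  list(vol = v, m2 = m2, pm = pm, ph = ph)
}

# sulcus angle / groove depth measured directly on a desk-scale volume
desk_morphometry <- function(vol, pm, slice = 4L) {
  bone <- binary_mask(vol$data > 0.65, vol$spacing_mm)
  det <- detect_trochlea_landmarks(vol, bone, slice, pm)
  c(sa = sulcus_angle(det), tgd = trochlear_groove_depth(det))
}

dice_coef <- function(a, b) {
  a <- if (inherits(a, "binary_mask")) a$data else a
  b <- if (inherits(b, "binary_mask")) b$data else b
  2 * sum(a & b) / (sum(a) + sum(b))
}

jaccard_coef <- function(a, b) {
  a <- if (inherits(a, "binary_mask")) a$data else a
  b <- if (inherits(b, "binary_mask")) b$data else b
  sum(a & b) / sum(a | b)
}
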