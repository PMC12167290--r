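test_that("Otsu matches the brute-force between-class-variance maximizer", {
  set.seed(1)
  cases <- list(
    c(rep(0.1, 500), rep(0.9, 500)),
    runif(2000),
    c(rnorm(5000, 0.2, 0.05), rnorm(5000, 0.8, 0.05)),
    rbeta(3000, 2, 5),
    c(rep(0.02, 900), runif(100, 0.5, 1))
  )
  for (x in cases) {
    x <- pmin(pmax(x, 0), 1)
    expect_equal(otsu_threshold(x), otsu_bruteforce(x))
  }
  bimodal <- c(rep(0.1, 500), rep(0.9, 500))
  thr <- otsu_threshold(bimodal)
  expect_gt(thr, 0.1); expect_lt(thr, 0.9)
  set.seed(7)
  gm <- c(rnorm(5000, 0.2, 0.05), rnorm(5000, 0.8, 0.05))
  expect_gt(otsu_threshold(gm), 0.4); expect_lt(otsu_threshold(gm), 0.6)
  expect_error(otsu_threshold(rep(0.5, 100)), "constant")
})

test_that("background segmentation recovers the phantom background", {
  ph <- desk_phantom()
  bg <- segment_background(ph$volume)
  expect_gte(dice_coef(bg, ph$background_mask), 0.95)
  # noise-free phantom: same accuracy (the blurred tissue boundary dominates)
  ph0 <- desk_phantom(noise = 0)
  bg0 <- segment_background(ph0$volume)
  expect_gte(dice_coef(bg0, ph0$background_mask), 0.95)
  expect_error(segment_background(volume_image(array(0.5, c(8, 8, 4)), c(1, 1, 1))))
})

test_that("morphology removes speckles and closing fills holes", {
  ph <- desk_phantom(noise = 0)
  v <- ph$volume$data
  set.seed(4)
  # salt speckles in the background and a small hole inside the tissue
  bgidx <- which(ph$background_mask$data)
  v[sample(bgidx, 40)] <- 0.9
  hole <- which(!ph$background_mask$data & !ph$bone_mask$data)
  v[hole[100]] <- 0
  bg <- segment_background(volume_image(v, ph$volume$spacing_mm))
  expect_gte(dice_coef(bg, ph$background_mask), 0.95)
  expect_false(bg$data[arrayInd(hole[100], dim(v))])  # hole closed
})

test_that("bone backends segment the phantom and unknown backends fail loudly", {
  ph <- desk_phantom()
  bone <- segment_bone(ph$volume)
  expect_gte(dice_coef(bone, ph$bone_mask), 0.9)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ph$bone_mask, f)
  verb <- segment_bone(ph$volume, backend = "file", path = f)
  expect_identical(verb$data, ph$bone_mask$data)
  expect_error(segment_bone(ph$volume, backend = "nope"), "registered backends")
})

test_that("patella localization picks the largest anterior component", {
  ph <- desk_phantom()
  pat <- localize_patella(ph$bone_mask)
  expect_identical(pat$data, ph$patella_mask$data)  # exact on the clean mask
  # two anterior blobs: the larger wins
  m <- array(FALSE, c(40, 40, 4))
  m[10:17, 30:37, 2] <- TRUE                        # 64 voxels, anterior
  m[25:27, 30:32, 2] <- TRUE                        # 9 voxels, anterior
  pat2 <- localize_patella(binary_mask(m, c(1, 1, 1)))
  expect_equal(sum(pat2$data), 64L)
  # femur-only phantom: distinct fallback condition
  femur <- binary_mask(ph$bone_mask$data & !ph$patella_mask$data, ph$volume$spacing_mm)
  expect_error(localize_patella(femur), class = "pseudoknee_patella_not_found")
  empty <- binary_mask(array(FALSE, dim(m)), c(1, 1, 1))
  expect_error(localize_patella(empty), class = "pseudoknee_patella_not_found")
})

test_that("bowl masks respect physical distance under anisotropic spacing", {
  m <- array(FALSE, c(111, 111, 15)); m[56, 56, 8] <- TRUE
  pat <- binary_mask(m, c(0.6, 0.6, 4.5))
  bowl <- make_bowl_mask(pat, 30)
  idx <- which(bowl$data, arr.ind = TRUE)
  expect_equal(max(abs(idx[, 1] - 56)), 50)    # floor(30 / 0.6)
  expect_equal(max(abs(idx[, 3] - 8)), 6)      # floor(30 / 4.5)
  expect_false(bowl$data[56, 56, 8])           # patella voxel excluded
  d2 <- distance_transform_sq(pat)
  expect_true(all(d2[bowl$data] > 0 & d2[bowl$data] <= 30^2 + 1e-6))
  # monotone in the offset
  small <- make_bowl_mask(pat, 12)
  expect_true(all(!small$data | bowl$data))
  expect_error(make_bowl_mask(binary_mask(array(FALSE, c(4, 4, 2)), c(1, 1, 1))), "empty")
})

test_that("the ellipsoid fallback matches its analytic volume and symmetry", {
  sp <- c(0.6, 0.6, 4.5)
  m <- ellipsoid_fallback_mask(c(121, 121, 21), sp, center_mm = c(36, 36, 45),
                               radii_mm = c(30, 30, 30))
  vol_analytic <- 4 / 3 * pi * 30^3 / prod(sp)
  expect_lt(abs(sum(m$data) - vol_analytic) / vol_analytic, 0.02)
  # sub-voxel radii leave only the centre voxel
  tiny <- ellipsoid_fallback_mask(c(21, 21, 5), sp, c(6, 6, 9), c(0.3, 0.3, 2.25))
  expect_equal(sum(tiny$data), 1L)
  expect_true(tiny$data[11, 11, 3])
  # reflection symmetry through the centre
  idx <- which(m$data, arr.ind = TRUE)
  refl <- cbind(2 * 61 - idx[, 1], 2 * 61 - idx[, 2], 2 * 11 - idx[, 3])
  expect_true(all(m$data[refl]))
  expect_error(ellipsoid_fallback_mask(c(10, 10, 4), sp, c(99, 0, 0), c(5, 5, 5)),
               "outside")
})

test_that("conditioning pairs partition the volume algebraically", {
  set.seed(8)
  v <- volume_image(array(runif(16 * 16 * 8), c(16, 16, 8)), c(1, 1, 1))
  m <- binary_mask(array(runif(16 * 16 * 8) > 0.6, c(16, 16, 8)), c(1, 1, 1))
  pair <- build_conditioning(v, m)
  expect_true(all(pair$m1$data[m$data] == 0))
  expect_identical(pair$m1$data[!m$data], v$data[!m$data])
  expect_equal(pair$m1$data + v$data * m$data, v$data)  # exact reconstruction
  none <- binary_mask(array(FALSE, c(16, 16, 8)), c(1, 1, 1))
  expect_identical(build_conditioning(v, none)$m1$data, v$data)
  all_m <- binary_mask(array(TRUE, c(16, 16, 8)), c(1, 1, 1))
  expect_true(all(build_conditioning(v, all_m)$m1$data == 0))
  expect_error(build_conditioning(v, binary_mask(array(FALSE, c(4, 4, 2)), c(1, 1, 1))),
               "mismatch")
})

test_that("the end-to-end masking pipeline covers the groove and spares the patella", {
  ph <- desk_phantom()
  mp <- mask_pathology(ph$volume)
  expect_false(any(mp$m2$data & mp$patella$data))
  sp <- ph$volume$spacing_mm
  lmrow <- ph$landmarks[ph$landmarks$slice == ph$central_slice, ]
  expect_true(mp$m2$data[round(lmrow$sulcus_x / sp[1]) + 1,
                         round(lmrow$sulcus_y / sp[2]) + 1, ph$central_slice])
  expect_true(mp$m2$data[round(lmrow$medial_x / sp[1]) + 1,
                         round(lmrow$medial_y / sp[2]) + 1, ph$central_slice])
  # pipeline falls back to the ellipsoid when no patella exists
  femur_vol <- ph$volume
  femur_vol$data[ph$patella_mask$data] <- 0.4
  mp2 <- mask_pathology(femur_vol,
                        fallback = list(center_mm = c(19, 25, 16), radii_mm = c(8, 8, 8)))
  expect_gt(sum(mp2$m2$data), 0)
  expect_error(mask_pathology(femur_vol), "fallback")
})
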