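test_that("masked MSE/PSNR agree with direct computation and behave monotonically", {
  set.seed(31)
  d <- c(12, 12, 6)
  ref <- array(runif(prod(d)), d)
  pred <- array(runif(prod(d)), d)
  m <- array(runif(prod(d)) > 0.5, d)
  direct <- {
    acc <- 0; n <- 0
    for (i in which(m)) { acc <- acc + (ref[i] - pred[i])^2; n <- n + 1 }
    acc / n
  }
  expect_equal(masked_mse(ref, pred, m), direct)
  expect_equal(masked_mse(ref, ref, m), 0)
  expect_equal(masked_mse(ref, ref + 0.1 * m, m), 0.01, tolerance = 1e-12)
  expect_equal(masked_psnr(ref, ref + 0.1 * m, m), 20, tolerance = 1e-9)
  expect_equal(masked_psnr(ref, ref + 1 * m, m), 0, tolerance = 1e-9)
  expect_identical(masked_psnr(ref, ref, m), Inf)
  # lower MSE => higher PSNR
  expect_gt(masked_psnr(ref, ref + 0.05 * m, m), masked_psnr(ref, ref + 0.2 * m, m))
  expect_error(masked_mse(ref, pred, array(FALSE, d)), "empty")
})

test_that("the SSIM map matches a direct windowed computation", {
  set.seed(32)
  d <- c(8, 8, 4)
  a <- array(runif(prod(d)), d)
  b <- a + array(rnorm(prod(d), sd = 0.1), d)
  expect_equal(ssim_map(a, b), ssim_loop(a, b), tolerance = 1e-10)
})

test_that("masked SSIM is 1 on identity, near 0 on noise, and reduces to plain SSIM", {
  set.seed(33)
  d <- c(56, 56, 32)
  ref <- array(0, d)
  ref[12:45, 12:45, 8:25] <- 0.8       # structured content
  ref <- ref + array(runif(prod(d), 0, 0.1), d)
  # mask thick relative to the 7^3 window, as a bowl mask is in-plane
  m <- array(FALSE, d); m[9:48, 9:48, 4:29] <- TRUE
  expect_equal(masked_ssim(ref, ref, m), 1, tolerance = 1e-9)
  # two independent noise fields share no structure: similarity near zero
  # (windows straddling the mask boundary share its silhouette, so the score
  # is small but not exactly zero)
  noise <- array(runif(prod(d)), d)
  ref_n <- array(runif(prod(d)), d)
  expect_lt(abs(masked_ssim(ref_n, noise, m)), 0.2)
  allm <- array(TRUE, d)
  expect_equal(masked_ssim(ref, noise, allm), mean(ssim_map(ref, noise)),
               tolerance = 1e-12)
  small <- array(FALSE, d); small[1:2, 1:2, 1] <- TRUE
  expect_error(masked_ssim(ref, ref, small), "window")
})

test_that("sulcus angle matches closed-form geometry and is rigid-motion invariant", {
  flat <- landmark_triple(c(-10, 20), c(10, 20), c(0, 20))
  expect_equal(sulcus_angle(flat), 180)
  v <- landmark_triple(c(-10, 20), c(10, 20), c(0, 15))
  expect_equal(sulcus_angle(v), 2 * atan(10 / 5) * 180 / pi, tolerance = 1e-9)
  # rotate + translate all three points: angle unchanged
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  mv <- function(p) drop(R %*% p) + c(3, -4)
  v2 <- landmark_triple(mv(c(-10, 20)), mv(c(10, 20)), mv(c(0, 15)))
  expect_equal(sulcus_angle(v2), sulcus_angle(v), tolerance = 1e-9)
  expect_error(sulcus_angle(landmark_triple(c(0, 15), c(10, 20), c(0, 15))),
               "coincides")
})

test_that("groove depth is the anterior drop from the condylar apex level", {
  lm <- landmark_triple(c(-10, 20), c(10, 20), c(0, 16))
  expect_equal(trochlear_groove_depth(lm), 4)
  expect_equal(trochlear_groove_depth(landmark_triple(c(-10, 20), c(10, 20), c(0, 20))), 0)
  asym <- landmark_triple(c(-10, 22), c(10, 18), c(0, 16))
  expect_equal(trochlear_groove_depth(asym), 4)            # mean of 22 and 18
  expect_equal(trochlear_groove_depth(asym, method = "max"), 6)
  ph <- generate_phantom(phantom_spec(groove_depth_mm = 5, noise_sd = 0))
  expect_equal(trochlear_groove_depth(phantom_landmarks(ph)), 5, tolerance = 0.2 / 5)
})

test_that("landmark detection recovers the phantom geometry and orders x correctly", {
  ph <- generate_phantom(phantom_spec(sulcus_angle_deg = 140, groove_depth_mm = 4.2,
                                      noise_sd = 0))
  det <- detect_trochlea_landmarks(ph$volume, ph$bone_mask, ph$central_slice,
                                   ph$patella_mask)
  truth <- phantom_landmarks(ph)
  expect_lt(abs(det$medial[1] - truth$medial[1]), 0.7)
  expect_lt(abs(det$lateral[2] - truth$lateral[2]), 0.7)
  expect_true(det$medial[1] < det$sulcus[1])
  expect_true(det$sulcus[1] < det$lateral[1])
  # fully filled groove: flat profile degenerates to zero depth
  ph1 <- generate_pathological_phantom(phantom_spec(sulcus_angle_deg = 140,
                                                    groove_depth_mm = 4.2,
                                                    noise_sd = 0), 1)
  det1 <- detect_trochlea_landmarks(ph1$volume, ph1$bone_mask, ph1$central_slice,
                                    ph1$patella_mask)
  expect_lt(trochlear_groove_depth(det1), 0.2)
})

test_that("healthy and dysplastic phantoms order SA and TGD as expected", {
  spec <- phantom_spec(sulcus_angle_deg = 145, groove_depth_mm = 5, noise_sd = 0)
  healthy <- generate_phantom(spec)
  filled <- generate_pathological_phantom(spec, 0.7)
  dh <- detect_trochlea_landmarks(healthy$volume, healthy$bone_mask,
                                  healthy$central_slice, healthy$patella_mask)
  df <- detect_trochlea_landmarks(filled$volume, filled$bone_mask,
                                  filled$central_slice, filled$patella_mask)
  expect_lt(sulcus_angle(dh), sulcus_angle(df))
  expect_gt(trochlear_groove_depth(dh), trochlear_groove_depth(df))
})
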