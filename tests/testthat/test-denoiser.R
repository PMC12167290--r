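test_that("parameter counts match an independent layer-by-layer summation", {
  tiny <- denoiser_config(base_channels = 8L, channel_mult = c(1, 2), res_blocks = 1L)
  expect_equal(count_denoiser_params(tiny),
               count_params_by_hand(8, c(1, 2), 1, ted = 8, attn = TRUE))
  mid <- denoiser_config(base_channels = 16L, channel_mult = c(1, 2, 2), res_blocks = 2L,
                         bottleneck_attention = FALSE)
  expect_equal(count_denoiser_params(mid),
               count_params_by_hand(16, c(1, 2, 2), 2, ted = 16, attn = FALSE))
  net <- build_denoiser(tiny, seed = 1)
  expect_equal(n_parameters(net), count_denoiser_params(tiny))
})

test_that("parameter count grows monotonically with base channels", {
  counts <- vapply(c(4L, 8L, 16L, 32L), function(b)
    count_denoiser_params(denoiser_config(base_channels = b, channel_mult = c(1, 2),
                                          res_blocks = 1L)), numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("the full-scale configuration is buildable and its count is stable", {
  cfg <- denoiser_config()   # base 64, (1,2,2,4,4), 2 res blocks, 24 -> 8
  expect_equal(count_denoiser_params(cfg), 57954120)
})

test_that("forward passes have the contracted shape and are deterministic", {
  net <- build_denoiser(tiny_denoiser_config(), seed = 2)
  x <- array(rnorm(16 * 16 * 8 * 24), c(16, 16, 8, 24))
  a <- pseudoknee:::denoiser_forward(net, x, 5)$out
  expect_equal(dim(a), c(16L, 16L, 8L, 8L))
  b <- pseudoknee:::denoiser_forward(net, x, 5)$out
  expect_identical(a, b)
  expect_error(pseudoknee:::denoiser_forward(net, array(0, c(16, 16, 8, 9)), 1),
               "24")
  expect_error(pseudoknee:::denoiser_forward(net, array(0, c(7, 8, 8, 24)), 1),
               "divisible")
  # identically rebuilt networks agree
  net2 <- build_denoiser(tiny_denoiser_config(), seed = 2)
  expect_identical(net$params, net2$params)
})

test_that("predict_x0 wires the conditioning channels through the network", {
  net <- build_denoiser(tiny_denoiser_config(), seed = 3)
  sp <- c(1, 1, 1)
  x_t <- dwt3(volume_image(array(rnorm(16 * 16 * 8), c(16, 16, 8)), sp))
  cond <- list(m1 = dwt3(volume_image(array(runif(16 * 16 * 8), c(16, 16, 8)), sp)),
               m2 = dwt3(array(0 + (runif(16 * 16 * 8) > 0.5), c(16, 16, 8))))
  out <- predict_x0(net, x_t, cond, 3)
  expect_s3_class(out, "wavelet_tensor")
  expect_equal(dim(out), c(8L, 8L, 4L, 8L))
  # changing the condition changes the output (the channels are not ignored)
  cond2 <- cond
  cond2$m1 <- wavelet_tensor(unclass(cond$m1) + 1)
  # an untrained network has zero output convolution; nudge one weight
  net$params[["out.conv.w"]][1, 1] <- 0.5
  o1 <- predict_x0(net, x_t, cond, 3)
  o2 <- predict_x0(net, x_t, cond2, 3)
  expect_gt(max(abs(o1 - o2)), 0)
})

test_that("analytic gradients match finite differences through the whole net", {
  set.seed(21)
  cfg <- denoiser_config(base_channels = 4L, channel_mult = c(1, 2), res_blocks = 1L,
                         bottleneck_attention = TRUE)
  net <- build_denoiser(cfg, seed = 3)
  # randomize the zero-initialized tensors so every path carries gradient
  for (nm in names(net$params)) {
    d <- dim(net$params[[nm]])
    p <- net$params[[nm]] + rnorm(length(net$params[[nm]]), sd = 0.05)
    if (!is.null(d)) dim(p) <- d
    net$params[[nm]] <- p
  }
  x <- array(rnorm(8 * 8 * 4 * 24), c(8, 8, 4, 24))
  fw <- pseudoknee:::denoiser_forward(net, x, 7)
  gout <- array(rnorm(length(fw$out)), dim(fw$out))
  grads <- pseudoknee:::tape_backward(fw$tape, fw$out_id, gout)
  expect_setequal(names(grads), names(net$params))
  lossf <- function(n) sum(pseudoknee:::denoiser_forward(n, x, 7)$out * gout)
  h <- 1e-5
  # spot-check one weight in every kind of layer, including attention
  picks <- c("in.conv.w", "time.l1.w", "enc.l1.b1.gn1.g", "enc.l1.down.conv1.w",
             "mid.attn.qkv.w", "mid.attn.proj.w", "dec.l2.b1.emb.w",
             "dec.l2.up.conv2.w", "enc.l2.b1.skip.w", "out.conv.w", "out.norm.b")
  for (nm in picks) {
    i <- sample(length(net$params[[nm]]), 1)
    n2 <- net; n2$params[[nm]][i] <- n2$params[[nm]][i] + h
    n3 <- net; n3$params[[nm]][i] <- n3$params[[nm]][i] - h
    num <- (lossf(n2) - lossf(n3)) / (2 * h)
    expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                 label = paste("gradient of", nm))
  }
})
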