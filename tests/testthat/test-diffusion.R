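test_that("linear schedules expose consistent derived arrays", {
  s <- make_linear_schedule(1000)
  expect_lt(s$alpha_bar[1000], 1e-3)                       # near-Gaussian terminal
  expect_true(all(diff(s$alpha_bar) < 0))                  # strictly decreasing
  expect_equal(s$alpha_bar, cumprod(1 - s$beta))
  expect_equal(s$alpha_bar, s$alpha_bar_prev * s$alpha, tolerance = 1e-14)
  s2 <- make_linear_schedule(2, 0.1, 0.2)
  expect_equal(s2$alpha_bar, c(0.9, 0.72))
  expect_error(make_linear_schedule(10, 0.2, 0.1), "beta")
  expect_error(make_linear_schedule(10, 0, 0.1), "beta")
})

test_that("q_sample follows the closed-form marginal", {
  s <- make_linear_schedule(100)
  x0 <- wavelet_tensor(array(rnorm(2 * 2 * 2 * 8), c(2, 2, 2, 8)))
  z <- wavelet_tensor(array(0, c(2, 2, 2, 8)))
  expect_equal(unclass(q_sample(x0, 50, z, s)),
               sqrt(s$alpha_bar[50]) * unclass(x0), tolerance = 1e-12,
               ignore_attr = TRUE)
  tiny <- make_linear_schedule(100, 1e-8, 1e-8)
  expect_equal(unclass(q_sample(x0, 1, z, tiny)), unclass(x0), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(q_sample(x0, 0, z, s), "t")
  expect_error(q_sample(x0, 101, z, s), "t")
})

test_that("q_sample moments match the stated marginal by Monte Carlo", {
  s <- make_linear_schedule(1000)
  t <- 400; n <- 1e4
  set.seed(1)
  draws <- q_sample(0, t, rnorm(n), s)   # x0 = 0, 1e4 independent draws
  target_var <- 1 - s$alpha_bar[t]
  se_mean <- sqrt(target_var / n)
  se_var <- target_var * sqrt(2 / (n - 1))
  expect_lt(abs(mean(draws) - 0), 3 * se_mean)
  expect_lt(abs(var(draws) - target_var), 3 * se_var)
})

test_that("the training loss and its hand-computed value agree", {
  x0 <- wavelet_tensor(array(0, c(8, 8, 8, 8)))
  pred <- x0
  expect_equal(training_loss(pred, x0, 1), 0)
  # hhh constant at 0.5: MSE share 0.25/8, L1 share 0.5/4
  p2 <- unclass(x0); p2[, , , 8] <- 0.5
  expect_equal(training_loss(wavelet_tensor(p2), x0, 1), 0.25 / 8 + 0.5 / 4)
  expect_equal(training_loss(wavelet_tensor(p2), x0, 0), 0.25 / 8)
  # perturbing llh changes only the MSE term
  p3 <- unclass(x0); p3[, , , 2] <- 0.5
  expect_equal(training_loss(wavelet_tensor(p3), x0, 1), 0.25 / 8)
  expect_error(training_loss(wavelet_tensor(array(0, c(2, 2, 2, 8))), x0), "mismatch")
})

test_that("the loss gradient matches finite differences", {
  set.seed(3)
  x0 <- wavelet_tensor(array(rnorm(64), c(2, 2, 2, 8)))
  p <- wavelet_tensor(array(rnorm(64), c(2, 2, 2, 8)))
  g <- pseudoknee:::training_loss_grad(p, x0, 0.7)
  h <- 1e-6
  for (i in c(1, 9, 30, 60)) {
    p2 <- unclass(p); p2[i] <- p2[i] + h
    p3 <- unclass(p); p3[i] <- p3[i] - h
    num <- (training_loss(wavelet_tensor(p2), x0, 0.7) -
            training_loss(wavelet_tensor(p3), x0, 0.7)) / (2 * h)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("posterior mean and variance satisfy the DDPM identities", {
  s <- make_linear_schedule(2, 0.1, 0.2)
  x0 <- wavelet_tensor(array(rnorm(64), c(2, 2, 2, 8)))
  xt <- wavelet_tensor(array(rnorm(64), c(2, 2, 2, 8)))
  # t = 1: coefficient identity beta_1 / (1 - alpha_bar_1) = 1
  expect_equal(unclass(posterior_mean(xt, x0, 1, s)), unclass(x0), tolerance = 1e-12)
  expect_equal(posterior_variance(1, s), 0)
  # hand-evaluated T = 2 coefficients
  c0 <- sqrt(0.9) * 0.2 / (1 - 0.72)
  ct <- sqrt(0.8) * (1 - 0.9) / (1 - 0.72)
  expect_equal(unclass(posterior_mean(xt, x0, 2, s)),
               c0 * unclass(x0) + ct * unclass(xt), tolerance = 1e-12)
  expect_equal(c0, 0.67764, tolerance = 2e-5)
  expect_equal(ct, 0.31944, tolerance = 2e-5)
  expect_equal(posterior_variance(2, s), 0.1 / 0.28 * 0.2, tolerance = 1e-12)
  # noise-free self-consistency: x_t on the mean path contracts to sqrt(ab_prev) x0
  s3 <- make_linear_schedule(10)
  for (t in c(2, 5, 10)) {
    xt2 <- sqrt(s3$alpha_bar[t]) * x0
    mu <- posterior_mean(xt2, x0, t, s3)
    expect_equal(unclass(mu), sqrt(s3$alpha_bar_prev[t]) * unclass(x0), tolerance = 1e-10)
  }
  # variance bounded by beta
  expect_true(all(s3$posterior_var <= s3$beta + 1e-15))
})

test_that("p_sample is deterministic at t = 1 and has the right variance", {
  s <- make_linear_schedule(50)
  x0 <- wavelet_tensor(array(0, c(2, 2, 2, 8)))
  xt <- wavelet_tensor(array(1, c(2, 2, 2, 8)))
  expect_equal(p_sample(xt, x0, 1, s), posterior_mean(xt, x0, 1, s))
  set.seed(5)
  t <- 30
  mu <- posterior_mean(xt, x0, t, s)
  devs <- replicate(200, as.numeric(p_sample(xt, x0, t, s) - mu))
  v_emp <- var(as.numeric(devs))
  v_true <- posterior_variance(t, s)
  expect_lt(abs(v_emp - v_true), 3 * v_true * sqrt(2 / (length(devs) - 1)))
})

test_that("the reverse chain with an x0 oracle contracts to x0", {
  set.seed(6)
  x0 <- wavelet_tensor(array(rnorm(4 * 4 * 2 * 8), c(4, 4, 2, 8)))
  s <- make_linear_schedule(100)
  x_t <- wavelet_tensor(array(rnorm(length(x0)) * 5, dim(x0)))
  for (t in seq(100, 1)) x_t <- p_sample(x_t, x0, t, s)
  expect_lt(max(abs(x_t - x0)), 1e-3)
})

test_that("inpaint_sample composites with the original outside the mask", {
  set.seed(7)
  v <- volume_image(array(runif(8 * 8 * 4), c(8, 8, 4)), c(1, 1, 1))
  m <- array(FALSE, c(8, 8, 4)); m[3:6, 3:6, 2:3] <- TRUE
  pair <- build_conditioning(v, binary_mask(m, c(1, 1, 1)))
  target <- dwt3(volume_image(array(0.25, c(8, 8, 4)), c(1, 1, 1)))
  oracle <- function(x_t, cond, t) target
  s <- make_linear_schedule(100)
  out <- inpaint_sample(oracle, pair, s, seed = 2)
  expect_identical(out$data[!m], pair$m1$data[!m])
  expect_lt(max(abs(out$data[m] - 0.25)), 1e-3)
  out2 <- inpaint_sample(oracle, pair, s, seed = 2)
  expect_identical(out$data, out2$data)
})
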