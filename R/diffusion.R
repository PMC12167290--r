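#' Linear DDPM noise schedule
#'
#' Forward-process variances `beta_t` linearly interpolated between
#' `beta_start` and `beta_end` over `t = 1..T`, with the derived quantities
#' `alpha_t = 1 - beta_t`, `alpha_bar_t = prod_{s<=t} alpha_s` and the
#' reverse-process posterior variance
#' `posterior_var_t = (1 - alpha_bar_{t-1}) / (1 - alpha_bar_t) * beta_t`
#' (with `alpha_bar_0 := 1`, so the variance at `t = 1` is exactly 0).
#'
#' @param timesteps number of diffusion steps `T`, default 1000.
#' @param beta_start,beta_end schedule endpoints, defaults `1e-4` and `0.02`.
#' @return An object of class `noise_schedule`.
#' @examples
#' s <- make_linear_schedule(timesteps = 2, beta_start = 0.1, beta_end = 0.2)
#' s$alpha_bar   # 0.9, 0.72
#' @export
make_linear_schedule <- function(timesteps = 1000L, beta_start = 1e-4, beta_end = 0.02) {
  timesteps <- as.integer(timesteps)
  if (timesteps < 1L) stop("`timesteps` must be >= 1")
  if (!(beta_start > 0 && beta_start <= beta_end && beta_end < 1))
    stop("need 0 < beta_start <= beta_end < 1")
  beta <- seq(beta_start, beta_end, length.out = timesteps)
  alpha <- 1 - beta
  alpha_bar <- cumprod(alpha)
  alpha_bar_prev <- c(1, alpha_bar[-timesteps])
  posterior_var <- (1 - alpha_bar_prev) / (1 - alpha_bar) * beta
  structure(list(timesteps = timesteps, beta = beta, alpha = alpha,
                 alpha_bar = alpha_bar, alpha_bar_prev = alpha_bar_prev,
                 posterior_var = posterior_var,
                 beta_start = beta_start, beta_end = beta_end),
            class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("<noise_schedule> linear, T = %d, beta in [%g, %g], alpha_bar_T = %.3g\n",
              x$timesteps, x$beta_start, x$beta_end, x$alpha_bar[x$timesteps]))
  invisible(x)
}

check_t <- function(t, sched) {
  if (!inherits(sched, "noise_schedule")) stop("`sched` must be a noise_schedule")
  if (length(t) != 1L || t < 1L || t > sched$timesteps || t != round(t))
    stop("`t` must be an integer in [1, ", sched$timesteps, "]")
  as.integer(t)
}

#' Closed-form forward noising
#'
#' Draws the marginal `x_t = sqrt(alpha_bar_t) x_0 + sqrt(1 - alpha_bar_t) eps`.
#'
#' @param x0 clean wavelet coefficients ([wavelet_tensor] or array).
#' @param t time step in `[1, T]`.
#' @param eps noise shaped like `x0`; standard normal in training.
#' @param sched a [make_linear_schedule()] schedule.
#' @return Noised coefficients, same type as `x0`.
#' @export
q_sample <- function(x0, t, eps, sched) {
  t <- check_t(t, sched)
  sqrt(sched$alpha_bar[t]) * x0 + sqrt(1 - sched$alpha_bar[t]) * eps
}

#' Training loss: MSE plus L1 sparsity on diagonal high-frequency subbands
#'
#' Mean squared error between the predicted and true clean coefficients over
#' all 8 subbands, plus `lambda_reg` times the mean absolute value of the
#' *predicted* `hhh`, `hhl`, `hlh` and `lhh` subbands (the bands combining x/y
#' high-pass filters). Only the prediction enters the L1 term — the ground
#' truth is constant with respect to the model. `llh`, `lhl` and `hll` are not
#' regularized.
#'
#' @param x0_pred,x0 [wavelet_tensor]s of equal shape.
#' @param lambda_reg weight of the L1 term, default 1.
#' @return Scalar loss.
#' @export
training_loss <- function(x0_pred, x0, lambda_reg = 1) {
  if (!identical(dim(x0_pred), dim(x0))) stop("prediction/target shape mismatch")
  mse <- mean((unclass_wt(x0_pred) - unclass_wt(x0))^2)
  hf <- match(HF_REG_BANDS, WAVELET_BANDS)
  l1 <- mean(abs(unclass_wt(x0_pred)[, , , hf]))
  mse + lambda_reg * l1
}

# gradient of training_loss w.r.t. x0_pred (used by the training loop)
training_loss_grad <- function(x0_pred, x0, lambda_reg = 1) {
  p <- unclass_wt(x0_pred); x <- unclass_wt(x0)
  g <- 2 * (p - x) / length(p)
  hf <- match(HF_REG_BANDS, WAVELET_BANDS)
  n_hf <- length(p) / 2   # 4 of 8 subbands
  g[, , , hf] <- g[, , , hf] + lambda_reg * sign(p[, , , hf]) / n_hf
  g
}

#' Reverse-process posterior mean
#'
#' `mu_t(x_t, x0) = sqrt(alpha_bar_{t-1}) beta_t / (1 - alpha_bar_t) * x0_pred
#'  + sqrt(alpha_t) (1 - alpha_bar_{t-1}) / (1 - alpha_bar_t) * x_t`,
#' with `alpha_bar_0 := 1`. At `t = 1` the coefficient on `x0_pred` is exactly
#' 1 and the one on `x_t` is 0, so the chain terminates at the prediction.
#'
#' @param x_t current noisy coefficients.
#' @param x0_pred predicted clean coefficients.
#' @inheritParams q_sample
#' @return The posterior mean, shaped like `x_t`.
#' @export
posterior_mean <- function(x_t, x0_pred, t, sched) {
  t <- check_t(t, sched)
  c0 <- sqrt(sched$alpha_bar_prev[t]) * sched$beta[t] / (1 - sched$alpha_bar[t])
  ct <- sqrt(sched$alpha[t]) * (1 - sched$alpha_bar_prev[t]) / (1 - sched$alpha_bar[t])
  c0 * x0_pred + ct * x_t
}

#' Reverse-process posterior variance
#'
#' @inheritParams q_sample
#' @return Scalar `posterior_var_t`; 0 at `t = 1`.
#' @export
posterior_variance <- function(t, sched) {
  t <- check_t(t, sched)
  sched$posterior_var[t]
}

#' One reverse sampling step
#'
#' Draws `x_{t-1} ~ N(mu_t(x_t, x0_pred), posterior_var_t I)`; deterministic at
#' `t = 1` where the variance is 0. Uses R's RNG stream — seed the caller for
#' reproducibility.
#'
#' @inheritParams posterior_mean
#' @return `x_{t-1}`, shaped like `x_t`.
#' @export
p_sample <- function(x_t, x0_pred, t, sched) {
  t <- check_t(t, sched)
  mu <- posterior_mean(x_t, x0_pred, t, sched)
  v <- sched$posterior_var[t]
  if (v <= 0) return(mu)
  mu + sqrt(v) * array(rnorm(length(mu)), dim(mu))
}

#' Predict clean wavelet coefficients from a noisy state
#'
#' Generic over denoiser representations: trained networks and plain R
#' functions (useful as analytic oracles in tests).
#'
#' @param model a denoiser (a `denoiser_network` or a function
#'   `(x_t, condition, t) -> wavelet coefficients`).
#' @param x_t noisy coefficients ([wavelet_tensor]).
#' @param condition list with wavelet transforms `m1` and `m2` of the masked
#'   image and the mask.
#' @param t time step.
#' @return Predicted clean coefficients.
#' @export
predict_x0 <- function(model, x_t, condition, t) UseMethod("predict_x0")

#' @export
predict_x0.function <- function(model, x_t, condition, t) model(x_t, condition, t)

#' Conditional inpainting by reverse diffusion
#'
#' Starts from pure noise in wavelet space and runs the full reverse chain,
#' conditioning every step on the wavelet transforms of the masked image `m1`
#' and mask `m2`. The final prediction is brought back to image space by the
#' inverse wavelet transform, composited with the input outside the mask
#' (`out = m2 * inpainted + (1 - m2) * original`) and clamped to `[0, 1]`.
#'
#' @param model denoiser; see [predict_x0()].
#' @param pair a `conditioning_pair` from [build_conditioning()].
#' @param sched noise schedule; its `timesteps` must match the model's
#'   training schedule when the model carries one.
#' @param seed optional integer seed controlling the noise trajectory.
#' @return The inpainted [volume_image].
#' @export
inpaint_sample <- function(model, pair, sched, seed = NULL) {
  if (!inherits(pair, "conditioning_pair")) stop("`pair` must be a conditioning_pair")
  if (inherits(model, "denoiser_network") && !is.null(model$timesteps) &&
      model$timesteps != sched$timesteps)
    stop("model was trained with T = ", model$timesteps,
         " but the schedule has T = ", sched$timesteps)
  cond <- list(m1 = dwt3(pair$m1),
               m2 = dwt3(array(as.numeric(pair$m2$data), dim(pair$m2$data))))
  run_chain <- function() {
    x_t <- wavelet_tensor(array(rnorm(length(cond$m1)), dim(cond$m1)),
                          attr(cond$m1, "spacing_mm"))
    for (t in seq(sched$timesteps, 1L)) {
      x0p <- predict_x0(model, x_t, cond, t)
      x_t <- p_sample(x_t, x0p, t, sched)
    }
    x_t
  }
  x_final <- if (is.null(seed)) run_chain() else run_with_seed(seed, run_chain())
  y <- idwt3(wavelet_tensor(unclass_wt(x_final), pair$m1$spacing_mm), as_volume = FALSE)
  m2 <- pair$m2$data
  out <- ifelse(m2, pmin(pmax(y, 0), 1), pair$m1$data)
  volume_image(array(out, dim(y)), pair$m1$spacing_mm)
}
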