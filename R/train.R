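#' Training configuration
#'
#' The `"full"` profile mirrors full-scale practice for this model family
#' (learning rate 1e-5, batch size 10, 1e6 iterations, T = 1000 linear
#' schedule); the `"desk"` profile is a CPU-scale setting for overfitting tiny
#' phantoms (16x16x8 volumes, tiny model, T = 100, 2000 iterations), used
#' throughout the test-suite.
#'
#' @param profile `"full"` (full-scale practice) or `"desk"` (CPU-scale).
#' @param ... overrides for any field: `learning_rate`, `batch_size`,
#'   `iterations`, `lambda_reg`, `timesteps`, `beta_start`, `beta_end`,
#'   `seed`, `log_every`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(profile = c("full", "desk"), ...) {
  profile <- match.arg(profile)
  cfg <- list(learning_rate = 1e-5, batch_size = 10L, iterations = 1e6,
              lambda_reg = 1, timesteps = 1000L, beta_start = 1e-4, beta_end = 0.02,
              seed = 0L, log_every = 100L, profile = profile)
  if (profile == "desk")
    cfg[c("learning_rate", "batch_size", "iterations", "timesteps")] <-
      list(2e-3, 1L, 2000L, 100L)
  cfg <- modifyList(cfg, list(...))
  for (f in c("learning_rate", "batch_size", "iterations", "lambda_reg", "timesteps"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) stop("`", f, "` must be non-negative")
  cfg$iterations <- as.integer(cfg$iterations)
  cfg$batch_size <- as.integer(cfg$batch_size)
  cfg$timesteps <- as.integer(cfg$timesteps)
  structure(cfg, class = "train_config")
}

adam_new <- function() list(m = list(), v = list(), step = 0L)

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$step <- state$step + 1L
  t <- state$step
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) { state$m[[nm]] <- g * 0; state$v[[nm]] <- g * 0 }
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^t)
    vhat <- state$v[[nm]] / (1 - b2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the conditional denoiser
#'
#' Each iteration draws a volume, a uniform time step `t`, Gaussian noise, and
#' optimizes the `x0`-prediction loss ([training_loss()]) with Adam. Training
#' is conditioned exactly as at inference: the network sees
#' `(x_t, DWT(m1), DWT(m2))` built from the supplied masks.
#'
#' @param volumes list of preprocessed [volume_image]s of one common shape
#'   with even, power-of-two-compatible extents.
#' @param masks list of inpainting [binary_mask]s (one per volume), or a
#'   function `(volume, iteration) -> binary_mask` implementing a sampling
#'   policy (e.g. jittered bowls around the patella).
#' @param cfg a [train_config()].
#' @param net an optional pre-built [build_denoiser()] network; defaults to a
#'   desk-scale tiny network sized for the volumes.
#' @param resume an optional checkpoint returned by a previous call; training
#'   continues with its weights, optimizer state and iteration counter.
#' @return A checkpoint: list with `net`, `sched`, `loss_history`, `cfg`,
#'   `adam_state` and `iteration`, of class `denoiser_checkpoint`.
#' @export
train_denoiser <- function(volumes, masks, cfg = train_config("desk"),
                           net = NULL, resume = NULL) {
  if (!length(volumes)) stop("`volumes` must be a non-empty list")
  shp <- dim(volumes[[1]]$data)
  for (v in volumes) if (!identical(dim(v$data), shp))
    stop("all training volumes must share one shape; found ",
         paste(dim(v$data), collapse = "x"), " vs ", paste(shp, collapse = "x"))
  if (any(shp %% 2L != 0L)) stop("volume extents must be even for the wavelet transform")

  if (!is.null(resume)) {
    net <- resume$net
    adam_state <- resume$adam_state
    it0 <- resume$iteration
    loss_history <- resume$loss_history
  } else {
    if (is.null(net)) net <- build_denoiser(tiny_denoiser_config(), seed = cfg$seed)
    adam_state <- adam_new()
    it0 <- 0L
    loss_history <- numeric(0)
  }
  sched <- make_linear_schedule(cfg$timesteps, cfg$beta_start, cfg$beta_end)

  mask_fun <- if (is.function(masks)) masks else {
    if (length(masks) != length(volumes))
      stop("`masks` must match `volumes` in length (or be a sampling function)")
    function(vol, it) masks[[which(vapply(volumes, identical, logical(1), vol))[1]]]
  }
  fixed_masks <- !is.function(masks)
  items <- lapply(seq_along(volumes), function(i) {
    v <- volumes[[i]]
    it <- list(vol = v, x0 = unclass_wt(dwt3(v)))
    if (fixed_masks) {
      pair <- build_conditioning(v, masks[[i]])
      it$m1w <- unclass_wt(dwt3(pair$m1))
      it$m2w <- unclass_wt(dwt3(array(as.numeric(masks[[i]]$data), shp)))
    }
    it
  })

  run_with_seed(cfg$seed + it0, {
    for (it in seq_len(cfg$iterations)) {
      gacc <- NULL
      lsum <- 0
      for (b in seq_len(cfg$batch_size)) {
        i <- sample.int(length(items), 1L)
        itm <- items[[i]]
        if (!fixed_masks) {
          m2 <- mask_fun(itm$vol, it0 + it)
          pair <- build_conditioning(itm$vol, m2)
          itm$m1w <- unclass_wt(dwt3(pair$m1))
          itm$m2w <- unclass_wt(dwt3(array(as.numeric(m2$data), shp)))
        }
        t <- sample.int(sched$timesteps, 1L)
        eps <- array(rnorm(length(itm$x0)), dim(itm$x0))
        x_t <- sqrt(sched$alpha_bar[t]) * itm$x0 + sqrt(1 - sched$alpha_bar[t]) * eps
        xin <- concat_channels(x_t, itm$m1w, itm$m2w)
        fw <- denoiser_forward(net, xin, t)
        pred <- wavelet_tensor(fw$out)
        x0wt <- wavelet_tensor(itm$x0)
        lsum <- lsum + training_loss(pred, x0wt, cfg$lambda_reg)
        gout <- training_loss_grad(pred, x0wt, cfg$lambda_reg)
        g <- tape_backward(fw$tape, fw$out_id, gout)
        gacc <- if (is.null(gacc)) g else {
          for (nm in names(g)) gacc[[nm]] <- (gacc[[nm]] %||% 0) + g[[nm]]
          gacc
        }
      }
      if (cfg$batch_size > 1L) for (nm in names(gacc)) gacc[[nm]] <- gacc[[nm]] / cfg$batch_size
      upd <- adam_step(net$params, gacc, adam_state, cfg$learning_rate)
      net$params <- upd$params
      adam_state <- upd$state
      loss_history <- c(loss_history, lsum / cfg$batch_size)
    }
  })
  net$timesteps <- sched$timesteps
  structure(list(net = net, sched = sched, loss_history = loss_history,
                 cfg = cfg, adam_state = adam_state,
                 iteration = it0 + cfg$iterations),
            class = "denoiser_checkpoint")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tiny desk-scale denoiser configuration
#'
#' Sized for 16x16x8 volumes (8x8x4 wavelet grids): base 8 channels,
#' multipliers (1, 2), one residual block per scale, bottleneck attention.
#'
#' @return A [denoiser_config()].
#' @export
tiny_denoiser_config <- function() {
  denoiser_config(base_channels = 8L, channel_mult = c(1, 2), res_blocks = 1L)
}

#' Save / load a checkpoint
#'
#' Checkpoints bundle weights, configuration and the noise schedule, so a
#' loaded checkpoint can resume training or run inference as-is.
#'
#' @param ckpt a `denoiser_checkpoint`.
#' @param path file path (`.rds`).
#' @return `path` / the checkpoint.
#' @export
save_checkpoint <- function(ckpt, path) { saveRDS(ckpt, path); invisible(path) }

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "denoiser_checkpoint")) stop("not a denoiser checkpoint: ", path)
  ckpt
}

#' Inpaint a pathological volume with a trained model
#'
#' Runs the masking pipeline (unless a mask is supplied), builds the
#' conditioning pair and samples the reverse diffusion chain. Voxels outside
#' the inpainting mask are returned bit-identical to the input.
#'
#' @param ckpt a `denoiser_checkpoint` (or a path to one).
#' @param vol the preprocessed pathological [volume_image].
#' @param mask optional inpainting [binary_mask]; when `NULL` the full
#'   [mask_pathology()] pipeline is run.
#' @param seed integer seed for the sampling trajectory.
#' @param out_path optional NIfTI output path; a JSON sidecar with the seed
#'   and mask statistics is written next to it when jsonlite is available.
#' @param ... passed to [mask_pathology()] (e.g. `fallback`, `offset_mm`).
#' @return List with `volume` (inpainted), `m2`, and `seed`.
#' @export
infer_pseudo_healthy <- function(ckpt, vol, mask = NULL, seed = NULL,
                                 out_path = NULL, ...) {
  if (is.character(ckpt)) ckpt <- load_checkpoint(ckpt)
  if (is.null(mask)) {
    mp <- mask_pathology(vol, ...)
    pair <- mp$pair
    m2 <- mp$m2
  } else {
    m2 <- mask
    pair <- build_conditioning(vol, m2)
  }
  out <- inpaint_sample(ckpt$net, pair, ckpt$sched, seed = seed)
  if (!is.null(out_path)) {
    write_volume(out, out_path)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      side <- sub("\\.nii(\\.gz)?$", ".json", out_path)
      jsonlite::write_json(list(seed = seed, mask_voxels = sum(m2$data),
                                timesteps = ckpt$sched$timesteps,
                                beta = c(ckpt$sched$beta_start, ckpt$sched$beta_end)),
                           side, auto_unbox = TRUE, pretty = TRUE)
    }
  }
  list(volume = out, m2 = m2, seed = seed)
}
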