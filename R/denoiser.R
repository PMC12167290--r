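#' Configuration of the conditional denoiser U-Net
#'
#' A 3D U-Net over wavelet coefficients predicting the clean `x0` from the
#' concatenated input `(x_t, DWT(m1), DWT(m2))` (8 + 8 + 8 = 24 channels) and
#' a time step. The design follows current 3D wavelet-diffusion practice:
#' residual blocks with group normalization, SiLU activations and per-block
#' time-embedding injection; stride-free up/down sampling inside dedicated
#' residual blocks (average pooling / nearest-neighbour); additive skip
#' connections from encoder to decoder; single-head self-attention at the
#' bottleneck; zero-initialized output projections.
#'
#' The default full-scale configuration (base 64, multipliers (1,2,2,4,4),
#' 2 residual blocks per scale) has 57,954,120 trainable parameters.
#'
#' @param base_channels channels at the first scale, default 64.
#' @param channel_mult per-scale channel multipliers, default `c(1, 2, 2, 4, 4)`.
#' @param res_blocks residual blocks per scale, default 2.
#' @param in_channels input channels; 24 for the 8-subband conditioned setup.
#' @param out_channels output channels; 8 subbands.
#' @param time_embed_dim width of the time embedding, default `base_channels`.
#' @param bottleneck_attention place a self-attention block at the bottleneck.
#' @return An object of class `denoiser_config`.
#' @export
denoiser_config <- function(base_channels = 64L, channel_mult = c(1, 2, 2, 4, 4),
                            res_blocks = 2L, in_channels = 24L, out_channels = 8L,
                            time_embed_dim = base_channels, bottleneck_attention = TRUE) {
  cfg <- list(base_channels = as.integer(base_channels),
              channel_mult = as.integer(channel_mult),
              res_blocks = as.integer(res_blocks),
              in_channels = as.integer(in_channels),
              out_channels = as.integer(out_channels),
              time_embed_dim = as.integer(time_embed_dim),
              bottleneck_attention = isTRUE(bottleneck_attention))
  if (any(cfg$channel_mult <= 0) || length(cfg$channel_mult) < 1L)
    stop("`channel_mult` must be a non-empty vector of positive multipliers")
  if (cfg$res_blocks < 1L) stop("`res_blocks` must be >= 1")
  if (cfg$base_channels < 1L || cfg$in_channels < 1L || cfg$out_channels < 1L)
    stop("channel counts must be positive")
  structure(cfg, class = "denoiser_config")
}

# ordered layout shared by parameter init and the forward pass
denoiser_layout <- function(cfg) {
  L <- length(cfg$channel_mult)
  chans <- cfg$base_channels * cfg$channel_mult
  steps <- list()
  add <- function(x) steps[[length(steps) + 1L]] <<- x
  add(list(kind = "conv", name = "in.conv", cin = cfg$in_channels, cout = chans[1],
           k = 3L, zero = FALSE))
  ch <- chans[1]
  for (lev in seq_len(L)) {
    for (b in seq_len(cfg$res_blocks)) {
      add(list(kind = "res", name = sprintf("enc.l%d.b%d", lev, b),
               cin = ch, cout = chans[lev], updown = "none"))
      ch <- chans[lev]
      add(list(kind = "push"))
    }
    if (lev < L)
      add(list(kind = "res", name = sprintf("enc.l%d.down", lev),
               cin = ch, cout = ch, updown = "down"))
  }
  add(list(kind = "res", name = "mid.b1", cin = ch, cout = ch, updown = "none"))
  if (cfg$bottleneck_attention) add(list(kind = "attn", name = "mid.attn", ch = ch))
  add(list(kind = "res", name = "mid.b2", cin = ch, cout = ch, updown = "none"))
  for (lev in rev(seq_len(L))) {
    for (b in seq_len(cfg$res_blocks)) {
      add(list(kind = "res", name = sprintf("dec.l%d.b%d", lev, b),
               cin = ch, cout = chans[lev], updown = "none"))
      ch <- chans[lev]
      add(list(kind = "pop"))
    }
    if (lev > 1L)
      add(list(kind = "res", name = sprintf("dec.l%d.up", lev),
               cin = ch, cout = ch, updown = "up"))
  }
  add(list(kind = "gn", name = "out.norm", ch = ch))
  add(list(kind = "silu"))
  add(list(kind = "conv", name = "out.conv", cin = ch, cout = cfg$out_channels,
           k = 3L, zero = TRUE))
  steps
}

denoiser_param_shapes <- function(cfg) {
  ted <- cfg$time_embed_dim
  shapes <- list()
  put <- function(name, d, zero = FALSE) shapes[[name]] <<- list(dim = d, zero = zero)
  put("time.l1.w", c(cfg$base_channels, ted)); put("time.l1.b", ted)
  put("time.l2.w", c(ted, ted)); put("time.l2.b", ted)
  for (s in denoiser_layout(cfg)) {
    if (s$kind == "conv") {
      put(paste0(s$name, ".w"), c(s$k^3 * s$cin, s$cout), zero = s$zero)
      put(paste0(s$name, ".b"), s$cout)
    } else if (s$kind == "res") {
      p <- s$name
      put(paste0(p, ".gn1.g"), s$cin); put(paste0(p, ".gn1.b"), s$cin)
      put(paste0(p, ".conv1.w"), c(27L * s$cin, s$cout)); put(paste0(p, ".conv1.b"), s$cout)
      put(paste0(p, ".emb.w"), c(ted, s$cout)); put(paste0(p, ".emb.b"), s$cout)
      put(paste0(p, ".gn2.g"), s$cout); put(paste0(p, ".gn2.b"), s$cout)
      put(paste0(p, ".conv2.w"), c(27L * s$cout, s$cout), zero = TRUE)
      put(paste0(p, ".conv2.b"), s$cout)
      if (s$cin != s$cout) {
        put(paste0(p, ".skip.w"), c(s$cin, s$cout)); put(paste0(p, ".skip.b"), s$cout)
      }
    } else if (s$kind == "attn") {
      p <- s$name
      put(paste0(p, ".gn.g"), s$ch); put(paste0(p, ".gn.b"), s$ch)
      put(paste0(p, ".qkv.w"), c(s$ch, 3L * s$ch)); put(paste0(p, ".qkv.b"), 3L * s$ch)
      put(paste0(p, ".proj.w"), c(s$ch, s$ch), zero = TRUE); put(paste0(p, ".proj.b"), s$ch)
    } else if (s$kind == "gn") {
      put(paste0(s$name, ".g"), s$ch); put(paste0(s$name, ".b"), s$ch)
    }
  }
  shapes
}

#' Count the trainable parameters implied by a configuration
#'
#' A pure function of the configuration (no weights are allocated).
#'
#' @param cfg a [denoiser_config()].
#' @return Integer parameter count.
#' @export
count_denoiser_params <- function(cfg) {
  sum(vapply(denoiser_param_shapes(cfg), function(s) prod(s$dim), numeric(1)))
}

#' Build (initialize) a denoiser network
#'
#' Weights use scaled Gaussian (He) initialization; the second convolution of
#' every residual block, the attention output projection and the final output
#' convolution start at zero, so an untrained network predicts exactly zero.
#'
#' @param cfg a [denoiser_config()].
#' @param seed integer seed for the weight draw (reproducible builds).
#' @return An object of class `denoiser_network`.
#' @export
build_denoiser <- function(cfg, seed = 0L) {
  if (!inherits(cfg, "denoiser_config")) stop("`cfg` must be a denoiser_config")
  shapes <- denoiser_param_shapes(cfg)
  params <- run_with_seed(seed, {
    lapply(shapes, function(s) {
      n <- prod(s$dim)
      # weights: He-scaled Gaussians; biases and zero-tagged tensors: 0
      v <- if (s$zero || length(s$dim) == 1L) numeric(n) else
        rnorm(n, sd = sqrt(2 / s$dim[1]))
      if (length(s$dim) > 1L) matrix(v, s$dim[1], s$dim[2]) else v
    })
  })
  # group-norm gains start at 1
  for (nm in names(params)) if (grepl("\\.g$", nm) && grepl("(gn|norm)", nm))
    params[[nm]] <- params[[nm]] + 1
  structure(list(config = cfg, params = params, timesteps = NULL),
            class = "denoiser_network")
}

#' Number of trainable parameters of a built network
#'
#' @param net a `denoiser_network`.
#' @return Integer count, equal to [count_denoiser_params()] of its config.
#' @export
n_parameters <- function(net) {
  sum(vapply(net$params, length, numeric(1)))
}

#' @export
print.denoiser_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<denoiser_network> base %d, mult (%s), %d res/scale, %d -> %d channels, %s parameters\n",
              cfg$base_channels, paste(cfg$channel_mult, collapse = ","),
              cfg$res_blocks, cfg$in_channels, cfg$out_channels,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

# forward pass on the tape; x is (X, Y, Z, in_channels)
denoiser_forward <- function(net, x, t) {
  cfg <- net$config
  d <- dim(x)
  if (length(d) != 4L || d[4] != cfg$in_channels)
    stop("denoiser input must be (X, Y, Z, ", cfg$in_channels, "); got (",
         paste(d, collapse = ", "), ")")
  down <- 2^(length(cfg$channel_mult) - 1L)
  if (any(d[1:3] %% down != 0))
    stop("spatial extents (", paste(d[1:3], collapse = ", "),
         ") must be divisible by ", down, " for ", length(cfg$channel_mult), " scales")
  tape <- tape_new(net$params)
  eid <- op_input(tape, sinusoidal_embedding(t, cfg$base_channels))
  eid <- op_linear(tape, eid, "time.l1.w", "time.l1.b")
  eid <- op_silu(tape, eid)
  eid <- op_linear(tape, eid, "time.l2.w", "time.l2.b")

  res_block <- function(xid, s) {
    p <- s$name
    h <- op_groupnorm(tape, xid, paste0(p, ".gn1.g"), paste0(p, ".gn1.b"))
    h <- op_silu(tape, h)
    xres <- xid
    if (s$updown == "down") { h <- op_avgpool2(tape, h); xres <- op_avgpool2(tape, xres) }
    if (s$updown == "up") { h <- op_upsample2(tape, h); xres <- op_upsample2(tape, xres) }
    h <- op_conv3(tape, h, paste0(p, ".conv1.w"), paste0(p, ".conv1.b"))
    ev <- op_silu(tape, eid)
    ev <- op_linear(tape, ev, paste0(p, ".emb.w"), paste0(p, ".emb.b"))
    h <- op_add_channel_bias(tape, h, ev)
    h <- op_groupnorm(tape, h, paste0(p, ".gn2.g"), paste0(p, ".gn2.b"))
    h <- op_silu(tape, h)
    h <- op_conv3(tape, h, paste0(p, ".conv2.w"), paste0(p, ".conv2.b"))
    if (s$cin != s$cout) {
      # 1x1 projection of the residual path
      xv <- tape_val(tape, xres)
      dd <- dim(xv)
      W <- tape$params[[paste0(p, ".skip.w")]]; b <- tape$params[[paste0(p, ".skip.b")]]
      Xm <- matrix(xv, prod(dd[1:3]), dd[4])
      Y <- sweep(Xm %*% W, 2L, b, `+`)
      xres_local <- xres
      xres <- tape_node(tape, array(Y, c(dd[1:3], ncol(W))), local({
        Xm_c <- Xm; W_c <- W; dd_c <- dd; p_c <- p; xres_c <- xres_local
        function(g) {
          gY <- matrix(g, nrow = nrow(Xm_c))
          tape_pgrad_add(tape, paste0(p_c, ".skip.w"), crossprod(Xm_c, gY))
          tape_pgrad_add(tape, paste0(p_c, ".skip.b"), colSums(gY))
          tape_addgrad(tape, xres_c, array(gY %*% t(W_c), dd_c))
        }
      }))
    }
    op_add(tape, xres, h)
  }

  skips <- integer(0)
  hid <- NULL
  for (s in denoiser_layout(cfg)) {
    if (s$kind == "conv") {
      hid <- if (is.null(hid)) op_conv3(tape, op_input(tape, x),
                                        paste0(s$name, ".w"), paste0(s$name, ".b"))
             else op_conv3(tape, hid, paste0(s$name, ".w"), paste0(s$name, ".b"))
    } else if (s$kind == "res") {
      hid <- res_block(hid, s)
    } else if (s$kind == "push") {
      skips <- c(skips, hid)
    } else if (s$kind == "pop") {
      sk <- skips[length(skips)]
      skips <- skips[-length(skips)]
      hid <- op_add(tape, hid, sk)
    } else if (s$kind == "attn") {
      nid <- op_groupnorm(tape, hid, paste0(s$name, ".gn.g"), paste0(s$name, ".gn.b"))
      hid <- op_attention(tape, nid, hid, s$name)
    } else if (s$kind == "gn") {
      hid <- op_groupnorm(tape, hid, paste0(s$name, ".g"), paste0(s$name, ".b"))
    } else if (s$kind == "silu") {
      hid <- op_silu(tape, hid)
    }
  }
  list(tape = tape, out_id = hid, out = tape_val(tape, hid))
}

#' @rdname predict_x0
#' @export
predict_x0.denoiser_network <- function(model, x_t, condition, t) {
  xin <- concat_channels(unclass_wt(x_t), unclass_wt(condition$m1), unclass_wt(condition$m2))
  fw <- denoiser_forward(model, xin, t)
  wavelet_tensor(fw$out, attr(x_t, "spacing_mm"))
}

concat_channels <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  array(do.call(c, lapply(parts, as.numeric)),
        c(d[1:3], sum(vapply(parts, function(p) dim(p)[4], numeric(1)))))
}
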