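# Reverse-mode autodiff tape and the layer set used by the denoiser U-Net.
#
# Activations are numeric arrays (X, Y, Z, C); parameters live in a flat named
# list. Each op returns a node id on the tape and registers a closure that
# pushes gradients to its parents and accumulates parameter gradients.

tape_new <- function(params) {
  t <- new.env(parent = emptyenv())
  t$n <- 0L
  t$vals <- list()
  t$backs <- list()
  t$grads <- list()
  t$pgrad <- new.env(parent = emptyenv())
  t$params <- params
  t
}

tape_node <- function(tape, val, back = NULL) {
  tape$n <- tape$n + 1L
  tape$vals[[tape$n]] <- val
  tape$backs[[tape$n]] <- back
  tape$n
}

tape_val <- function(tape, id) { force(id); tape$vals[[id]] }

tape_addgrad <- function(tape, id, g) {
  cur <- if (id <= length(tape$grads)) tape$grads[[id]] else NULL
  tape$grads[[id]] <- if (is.null(cur)) g else cur + g
}

tape_pgrad_add <- function(tape, name, g) {
  cur <- get0(name, envir = tape$pgrad, inherits = FALSE)
  assign(name, if (is.null(cur)) g else cur + g, envir = tape$pgrad)
}

tape_backward <- function(tape, out_id, gout) {
  tape$grads <- vector("list", tape$n)
  tape$grads[[out_id]] <- gout
  for (id in seq(tape$n, 1L)) {
    g <- tape$grads[[id]]
    if (is.null(g) || is.null(tape$backs[[id]])) next
    tape$backs[[id]](g)
    tape$grads[[id]] <- NULL   # free
  }
  as.list(tape$pgrad)
}

op_input <- function(tape, x) tape_node(tape, x)

op_conv3 <- function(tape, xid, wname, bname, stride = 1L, pad = 1L) {
  x <- tape_val(tape, xid)
  d <- dim(x)
  W <- tape$params[[wname]]          # (k^3 * cin) x cout
  b <- tape$params[[bname]]
  k <- as.integer(round((nrow(W) / d[4])^(1 / 3)))
  stopifnot(k^3 * d[4] == nrow(W))
  M <- .cpp_im2col3(as.numeric(x), d, k, pad, stride)
  Y <- M %*% W
  Y <- sweep(Y, 2L, b, `+`)
  od <- c((d[1:3] + 2L * pad - k) %/% stride + 1L, ncol(W))
  out <- array(Y, od)
  tape_node(tape, out, function(g) {
    gY <- matrix(g, nrow = nrow(M))
    tape_pgrad_add(tape, wname, crossprod(M, gY))
    tape_pgrad_add(tape, bname, colSums(gY))
    gX <- .cpp_col2im3(gY %*% t(W), d, k, pad, stride)
    tape_addgrad(tape, xid, array(gX, d))
  })
}

gn_groups <- function(c) {
  g <- min(32L, c)
  while (c %% g != 0L) g <- g - 1L
  g
}

op_groupnorm <- function(tape, xid, gname, bname, eps = 1e-5) {
  x <- tape_val(tape, xid)
  d <- dim(x)
  C <- d[4]; S <- prod(d[1:3])
  G <- gn_groups(C); cg <- C %/% G
  xm <- matrix(x, S, C)
  xhat <- xm
  mu <- numeric(G); sdv <- numeric(G)
  for (g in seq_len(G)) {
    cols <- ((g - 1L) * cg + 1L):(g * cg)
    v <- xm[, cols]
    mu[g] <- mean(v)
    sdv[g] <- sqrt(mean((v - mu[g])^2) + eps)
    xhat[, cols] <- (v - mu[g]) / sdv[g]
  }
  gamma <- tape$params[[gname]]; beta <- tape$params[[bname]]
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  tape_node(tape, array(y, d), function(gr) {
    gy <- matrix(gr, S, C)
    tape_pgrad_add(tape, gname, colSums(gy * xhat))
    tape_pgrad_add(tape, bname, colSums(gy))
    gx <- matrix(0, S, C)
    for (g in seq_len(G)) {
      cols <- ((g - 1L) * cg + 1L):(g * cg)
      dxh <- sweep(gy[, cols, drop = FALSE], 2L, gamma[cols], `*`)
      xh <- xhat[, cols, drop = FALSE]
      n <- length(dxh)
      gx[, cols] <- (dxh - mean(dxh) - xh * mean(dxh * xh)) / sdv[g]
    }
    tape_addgrad(tape, xid, array(gx, d))
  })
}

op_silu <- function(tape, xid) {
  x <- tape_val(tape, xid)
  s <- 1 / (1 + exp(-x))
  y <- x * s
  tape_node(tape, y, function(g) {
    tape_addgrad(tape, xid, g * (s * (1 + x * (1 - s))))
  })
}

op_linear <- function(tape, xid, wname, bname) {
  x <- tape_val(tape, xid)        # vector
  W <- tape$params[[wname]]       # in x out
  b <- tape$params[[bname]]
  y <- drop(x %*% W) + b
  tape_node(tape, y, function(g) {
    tape_pgrad_add(tape, wname, outer(x, g))
    tape_pgrad_add(tape, bname, g)
    tape_addgrad(tape, xid, drop(W %*% g))
  })
}

op_add <- function(tape, aid, bid) {
  a <- tape_val(tape, aid); b <- tape_val(tape, bid)
  tape_node(tape, a + b, function(g) {
    tape_addgrad(tape, aid, g)
    tape_addgrad(tape, bid, g)
  })
}

# broadcast-add a channel vector (node) over the spatial grid
op_add_channel_bias <- function(tape, xid, vid) {
  x <- tape_val(tape, xid)
  v <- tape_val(tape, vid)
  d <- dim(x)
  y <- array(sweep(matrix(x, prod(d[1:3]), d[4]), 2L, v, `+`), d)
  tape_node(tape, y, function(g) {
    tape_addgrad(tape, xid, g)
    tape_addgrad(tape, vid, colSums(matrix(g, prod(d[1:3]), d[4])))
  })
}

pool_avg2 <- function(x) {
  d <- dim(x)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  x <- (x[i1, , , , drop = FALSE] + x[i2, , , , drop = FALSE]) / 2
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  x <- (x[, j1, , , drop = FALSE] + x[, j2, , , drop = FALSE]) / 2
  k1 <- seq(1L, d[3], 2L); k2 <- seq(2L, d[3], 2L)
  (x[, , k1, , drop = FALSE] + x[, , k2, , drop = FALSE]) / 2
}

up_nearest2 <- function(x) {
  d <- dim(x)
  x <- x[rep(seq_len(d[1]), each = 2L), , , , drop = FALSE]
  x <- x[, rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
  x[, , rep(seq_len(d[3]), each = 2L), , drop = FALSE]
}

op_avgpool2 <- function(tape, xid) {
  x <- tape_val(tape, xid)
  tape_node(tape, pool_avg2(x), function(g) {
    tape_addgrad(tape, xid, up_nearest2(g) / 8)
  })
}

op_upsample2 <- function(tape, xid) {
  x <- tape_val(tape, xid)
  tape_node(tape, up_nearest2(x), function(g) {
    tape_addgrad(tape, xid, pool_avg2(g) * 8)
  })
}

# single-head self-attention over the flattened spatial grid; qkv reads the
# (pre-normalized) `xid` activation, the residual connection bypasses from
# `resid` (guided pre-norm layout: y = resid + proj(attn(norm(x))))
op_attention <- function(tape, xid, resid, prefix) {
  x <- tape_val(tape, xid)
  d <- dim(x)
  C <- d[4]; Nt <- prod(d[1:3])
  Wqkv <- tape$params[[paste0(prefix, ".qkv.w")]]
  bqkv <- tape$params[[paste0(prefix, ".qkv.b")]]
  Wp <- tape$params[[paste0(prefix, ".proj.w")]]
  bp <- tape$params[[paste0(prefix, ".proj.b")]]
  Xm <- matrix(x, Nt, C)
  QKV <- sweep(Xm %*% Wqkv, 2L, bqkv, `+`)
  Q <- QKV[, 1:C, drop = FALSE]
  K <- QKV[, (C + 1):(2 * C), drop = FALSE]
  V <- QKV[, (2 * C + 1):(3 * C), drop = FALSE]
  sc <- 1 / sqrt(C)
  S <- (Q %*% t(K)) * sc
  S <- S - apply(S, 1L, max)
  A <- exp(S); A <- A / rowSums(A)
  O <- A %*% V
  Y <- sweep(O %*% Wp, 2L, bp, `+`)
  xres <- matrix(tape_val(tape, resid), Nt, C)
  tape_node(tape, array(xres + Y, d), function(g) {
    gY <- matrix(g, Nt, C)
    tape_addgrad(tape, resid, g)   # residual branch
    tape_pgrad_add(tape, paste0(prefix, ".proj.w"), crossprod(O, gY))
    tape_pgrad_add(tape, paste0(prefix, ".proj.b"), colSums(gY))
    gO <- gY %*% t(Wp)
    gA <- gO %*% t(V)
    gV <- crossprod(A, gO)
    gS <- A * (gA - rowSums(gA * A))
    gQ <- (gS %*% K) * sc
    gK <- (crossprod(gS, Q)) * sc
    gQKV <- cbind(gQ, gK, gV)
    tape_pgrad_add(tape, paste0(prefix, ".qkv.w"), crossprod(Xm, gQKV))
    tape_pgrad_add(tape, paste0(prefix, ".qkv.b"), colSums(gQKV))
    tape_addgrad(tape, xid, array(gQKV %*% t(Wqkv), d))
  })
}

sinusoidal_embedding <- function(t, dim) {
  half <- dim %/% 2L
  freqs <- exp(-log(10000) * (seq_len(half) - 1L) / half)
  c(sin(t * freqs), cos(t * freqs))
}
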