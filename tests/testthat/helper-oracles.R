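# independent brute-force oracles used to validate the implementation paths

# exhaustive between-class-variance maximizer over the fixed 256-bin histogram
otsu_bruteforce <- function(x, bins = 256L) {
  x <- pmin(pmax(as.numeric(x), 0), 1)
  edges <- seq(0, 1, length.out = bins + 1L)
  centers <- (edges[-1] + edges[-(bins + 1L)]) / 2
  h <- tabulate(pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), bins),
                nbins = bins)
  sb <- rep(-Inf, bins - 1L)
  for (t in seq_len(bins - 1L)) {
    w0 <- sum(h[1:t]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:t] * centers[1:t]) / w0
    mu1 <- sum(h[(t + 1):bins] * centers[(t + 1):bins]) / w1
    sb[t] <- (w0 / sum(h)) * (w1 / sum(h)) * (mu0 - mu1)^2
  }
  # same tie rule as the implementation: middle of the optimal plateau
  top <- which(sb >= max(sb) - 1e-12)
  edges[as.integer(round(mean(top))) + 1L]
}

# direct per-voxel SSIM with a Gaussian window and symmetric padding
ssim_loop <- function(a, b, window = 7L, sigma = 1.5, data_range = 1) {
  d <- dim(a)
  half <- window %/% 2L
  k1 <- exp(-((-half):half)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  w3 <- outer(outer(k1, k1), k1)
  mirror <- function(i, n) { i <- ifelse(i < 1L, 1L - i, i); ifelse(i > n, 2L * n + 1L - i, i) }
  c1 <- (0.01 * data_range)^2; c2 <- (0.03 * data_range)^2
  out <- array(NA_real_, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    ix <- mirror(x + (-half):half, d[1])
    iy <- mirror(y + (-half):half, d[2])
    iz <- mirror(z + (-half):half, d[3])
    pa <- a[ix, iy, iz]; pb <- b[ix, iy, iz]
    mu1 <- sum(w3 * pa); mu2 <- sum(w3 * pb)
    v1 <- sum(w3 * pa^2) - mu1^2; v2 <- sum(w3 * pb^2) - mu2^2
    cv <- sum(w3 * pa * pb) - mu1 * mu2
    out[x, y, z] <- ((2 * mu1 * mu2 + c1) * (2 * cv + c2)) /
      ((mu1^2 + mu2^2 + c1) * (v1 + v2 + c2))
  }
  out
}

# analytic parameter count of the U-Net, summed layer by layer from the
# architecture definition (independent of the builder's bookkeeping)
count_params_by_hand <- function(base, mults, nres, in_ch = 24L, out_ch = 8L,
                                 ted = base, attn = TRUE) {
  lin <- function(i, o) i * o + o
  conv3 <- function(i, o) 27 * i * o + o
  gn <- function(c) 2 * c
  res <- function(i, o) {
    n <- gn(i) + conv3(i, o) + lin(ted, o) + gn(o) + conv3(o, o)
    if (i != o) n <- n + (i * o + o)
    n
  }
  att <- function(c) gn(c) + (3 * c * c + 3 * c) + (c * c + c)
  chans <- base * mults
  L <- length(mults)
  total <- lin(base, ted) + lin(ted, ted) + conv3(in_ch, chans[1])
  ch <- chans[1]
  for (lev in seq_len(L)) {
    for (b in seq_len(nres)) { total <- total + res(ch, chans[lev]); ch <- chans[lev] }
    if (lev < L) total <- total + res(ch, ch)
  }
  total <- total + res(ch, ch) + (if (attn) att(ch) else 0) + res(ch, ch)
  for (lev in rev(seq_len(L))) {
    for (b in seq_len(nres)) { total <- total + res(ch, chans[lev]); ch <- chans[lev] }
    if (lev > 1) total <- total + res(ch, ch)
  }
  total + gn(ch) + conv3(ch, out_ch)
}
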