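# Matrix primitives for the encoder and fusion layers: forward passes with
# caches and hand-derived backward passes. Inputs are row-major activation
# matrices (one row per token). Gradients are exact; tests check them against
# central finite differences on small configurations.

linear_fwd <- function(x, W, b) {
  out <- x %*% W
  out <- sweep(out, 2L, b, "+")
  list(out = out, x = x)
}

linear_bwd <- function(dout, cache, W) {
  list(dx = dout %*% t(W),
       dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

relu_fwd <- function(x) {
  m <- x > 0
  list(out = x * m, mask = m)
}

relu_bwd <- function(dout, cache) {
  dout * cache$mask
}

# Per-row layer normalization with learned gain/offset.
layernorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * inv_sd
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = out, xhat = xhat, inv_sd = inv_sd)
}

layernorm_bwd <- function(dout, cache, gamma) {
  xhat <- cache$xhat
  dxhat <- sweep(dout, 2L, gamma, "*")
  # dx = inv_sd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)), row-wise
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv_sd
  list(dx = dx,
       dgamma = colSums(dout * xhat),
       dbeta = colSums(dout))
}

# Row-wise softmax, numerically stabilised. Accepts -Inf entries (masked).
softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# Backward through row-wise softmax: dlogits = p * (dp - sum(p * dp)).
softmax_rows_bwd <- function(dp, p) {
  p * (dp - rowSums(p * dp))
}

# Inverted dropout; identity when not training or rate == 0.
dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = x, mask = NULL))
  }
  keep <- (matrix(stats::runif(length(x)), nrow(x), ncol(x)) >= rate) / (1 - rate)
  list(out = x * keep, mask = keep)
}

dropout_bwd <- function(dout, cache) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

# Gaussian(0, sd) initialiser; draws consume the current RNG stream.
init_mat <- function(nrow, ncol, sd = 0.02) {
  matrix(stats::rnorm(nrow * ncol, sd = sd), nrow, ncol)
}

# Column index block for attention head h of dim d_head.
head_cols <- function(h, d_head) {
  ((h - 1L) * d_head + 1L):(h * d_head)
}
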