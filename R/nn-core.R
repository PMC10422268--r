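# Primitive differentiable ops for the segmentation network. Feature maps are
# numeric arrays dim (H, W, C); convolution weights are (kh*kw*Cin) x Cout
# matrices (column-major flattening of a (kh, kw, Cin, Cout) kernel array),
# heavy lifting in C++ (im2col + GEMM). Every *_fwd returns what its *_bwd
# needs; no implicit state.

nn_conv_fwd <- function(x, w, b, k = 3L) {
  .cpp_conv2d_fwd(x, w, b, k, k)
}

nn_conv_bwd <- function(x, w, dy, k = 3L) {
  .cpp_conv2d_bwd(x, w, dy, k, k)
}

# Per-sample spatial normalization: each channel is standardized over its own
# H*W pixels (learned gain/shift). Identical behaviour in training and
# inference, so single-tile gradient accumulation stays exact.
nn_norm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = n)
  inv <- 1 / sqrt(colMeans(xc * xc) + eps)
  xhat <- xc * rep(inv, each = n)
  y <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(y = array(y, d), xhat = xhat, inv = inv, n = n, d = d)
}

nn_norm_bwd <- function(cache, gamma, dy) {
  n <- cache$n; d <- cache$d
  dym <- matrix(dy, n, d[3])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * rep(gamma, each = n)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- (dxhat - rep(s1 / n, each = n) -
           cache$xhat * rep(s2 / n, each = n)) * rep(cache$inv, each = n)
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

nn_relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

nn_maxpool_fwd <- function(x) .cpp_maxpool2_fwd(x)

nn_maxpool_bwd <- function(idx, dy, H, W) .cpp_maxpool2_bwd(idx, dy, H, W)

# 2x nearest-neighbour upsampling.
nn_upsample_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

nn_upsample_bwd <- function(dy) {
  d <- dim(dy)
  io <- seq(1L, d[1], by = 2L); jo <- seq(1L, d[2], by = 2L)
  dy[io, jo, , drop = FALSE] + dy[io + 1L, jo, , drop = FALSE] +
    dy[io, jo + 1L, , drop = FALSE] + dy[io + 1L, jo + 1L, , drop = FALSE]
}

nn_concat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[1:2] == db[1:2]))
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

nn_split <- function(dy, ca) {
  d <- dim(dy)
  list(da = dy[, , seq_len(ca), drop = FALSE],
       db = dy[, , (ca + 1L):d[3], drop = FALSE])
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Per-pixel softmax cross-entropy against integer class codes (0-based).
# Returns loss (mean over pixels), probabilities and d(loss)/d(logits).
nn_softmax_ce <- function(logits, y_codes, want_grad = TRUE) {
  d <- dim(logits); n <- d[1] * d[2]; k <- d[3]
  lm <- matrix(logits, n, k)
  lm <- lm - apply(lm, 1, max)
  el <- exp(lm)
  p <- el / rowSums(el)
  truth <- as.vector(y_codes) + 1L
  idx <- cbind(seq_len(n), truth)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  out <- list(loss = loss, prob = array(p, d))
  if (want_grad) {
    g <- p
    g[idx] <- g[idx] - 1
    out$dlogits <- array(g / n, d)
  }
  out
}

nn_softmax <- function(logits) {
  d <- dim(logits); n <- d[1] * d[2]
  lm <- matrix(logits, n, d[3])
  lm <- lm - apply(lm, 1, max)
  el <- exp(lm)
  array(el / rowSums(el), d)
}

# He-normal initializer for a conv kernel, returned in matrix layout.
init_conv <- function(k, cin, cout) {
  w <- matrix(rnorm(k * k * cin * cout) * sqrt(2 / (k * k * cin)),
              k * k * cin, cout)
  w
}

col_max_idx <- function(m) {
  # index of the max of each column; ties -> first (deterministic)
  max.col(t(m), ties.method = "first")
}
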