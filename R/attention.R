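# Convolutional block attention: a channel gate from globally pooled
# statistics through a shared bottleneck perceptron, then a spatial gate from
# channel-wise pooled maps through a 7x7 convolution; both squashed by a
# sigmoid and applied multiplicatively. Neither changes the feature shape.

#' Channel-attention parameters
#'
#' A shared two-layer perceptron: `W0` compresses the pooled `C`-vector to
#' `max(1, floor(C/r))` units (ReLU), `W1` expands back to `C`. The same
#' perceptron (including biases) is applied to the average-pooled and
#' max-pooled vectors; the outputs are summed before the sigmoid.
#'
#' @param C number of input channels.
#' @param r compression ratio (bottleneck `C/r`); default 8.
#' @param W0,b0,W1,b1 optional explicit weights (matrices `C/r x C`,
#'   `C x C/r` and bias vectors); drawn He-normal when omitted.
#' @return object of class `channel_attention_params`.
#' @export
channel_attention_params <- function(C, r = 8L, W0 = NULL, b0 = NULL,
                                     W1 = NULL, b1 = NULL) {
  cr <- max(1L, C %/% r)
  if (is.null(W0)) W0 <- matrix(rnorm(cr * C) * sqrt(2 / C), cr, C)
  if (is.null(b0)) b0 <- numeric(cr)
  if (is.null(W1)) W1 <- matrix(rnorm(C * cr) * sqrt(2 / cr), C, cr)
  if (is.null(b1)) b1 <- numeric(C)
  stopifnot(nrow(W0) == cr, ncol(W0) == C, nrow(W1) == C, ncol(W1) == cr)
  structure(list(W0 = W0, b0 = b0, W1 = W1, b1 = b1, C = C, r = r),
            class = "channel_attention_params")
}

#' Spatial-attention parameters
#'
#' One 7x7 convolution kernel over the 2-channel concatenation of the
#' channel-wise mean and max maps.
#'
#' @param kernel optional `(7*7*2) x 1` weight matrix (column-major layout of
#'   a 7x7x2 kernel); He-normal when omitted.
#' @param bias scalar bias.
#' @return object of class `spatial_attention_params`.
#' @export
spatial_attention_params <- function(kernel = NULL, bias = 0) {
  if (is.null(kernel)) kernel <- init_conv(7L, 2L, 1L)
  stopifnot(nrow(kernel) == 7L * 7L * 2L, ncol(kernel) == 1L)
  structure(list(k = kernel, b = bias), class = "spatial_attention_params")
}

ca_fwd <- function(x, p) {
  d <- dim(x); n <- d[1] * d[2]
  if (d[3] != p$C)
    stop("channel attention expects ", p$C, " channels, got ", d[3])
  xm <- matrix(x, n, d[3])
  favg <- colMeans(xm)
  imax <- col_max_idx(xm)
  fmax <- xm[cbind(imax, seq_len(d[3]))]
  pre_a <- drop(p$W0 %*% favg) + p$b0
  pre_m <- drop(p$W0 %*% fmax) + p$b0
  h_a <- pmax(pre_a, 0); h_m <- pmax(pre_m, 0)
  g <- sigmoid(drop(p$W1 %*% h_a) + drop(p$W1 %*% h_m) + 2 * p$b1)
  y <- array(xm * rep(g, each = n), d)
  list(y = y, gate = g, xm = xm, favg = favg, fmax = fmax, imax = imax,
       pre_a = pre_a, pre_m = pre_m, h_a = h_a, h_m = h_m, d = d, n = n)
}

ca_bwd <- function(cache, p, dy) {
  n <- cache$n; C <- cache$d[3]
  dym <- matrix(dy, n, C)
  dg <- colSums(dym * cache$xm)
  dxm <- dym * rep(cache$gate, each = n)
  dz <- dg * cache$gate * (1 - cache$gate)
  dh_a <- drop(crossprod(p$W1, dz)); dh_m <- dh_a
  dpre_a <- dh_a * (cache$pre_a > 0)
  dpre_m <- dh_m * (cache$pre_m > 0)
  dW1 <- dz %*% t(cache$h_a + cache$h_m)
  db1 <- 2 * dz
  dW0 <- dpre_a %*% t(cache$favg) + dpre_m %*% t(cache$fmax)
  db0 <- dpre_a + dpre_m
  dfavg <- drop(crossprod(p$W0, dpre_a))
  dfmax <- drop(crossprod(p$W0, dpre_m))
  dxm <- dxm + matrix(dfavg / n, n, C, byrow = TRUE)
  dxm[cbind(cache$imax, seq_len(C))] <-
    dxm[cbind(cache$imax, seq_len(C))] + dfmax
  list(dx = array(dxm, cache$d), dW0 = dW0, db0 = db0, dW1 = dW1, db1 = db1)
}

sa_fwd <- function(x, p) {
  d <- dim(x); n <- d[1] * d[2]; C <- d[3]
  xm <- matrix(x, n, C)
  savg <- rowMeans(xm)
  imaxc <- max.col(xm, ties.method = "first")
  smax <- xm[cbind(seq_len(n), imaxc)]
  S <- array(c(savg, smax), c(d[1], d[2], 2L))
  z <- nn_conv_fwd(S, p$k, p$b, k = 7L)
  g <- sigmoid(as.vector(z))
  y <- array(xm * g, d)
  list(y = y, gate = matrix(g, d[1], d[2]), xm = xm, S = S, imaxc = imaxc,
       g = g, d = d, n = n)
}

sa_bwd <- function(cache, p, dy) {
  d <- cache$d; n <- cache$n; C <- d[3]
  dym <- matrix(dy, n, C)
  dg <- rowSums(dym * cache$xm)
  dxm <- dym * cache$g
  dz <- array(dg * cache$g * (1 - cache$g), c(d[1], d[2], 1L))
  cb <- nn_conv_bwd(cache$S, p$k, dz, k = 7L)
  dsavg <- as.vector(cb$dx[, , 1L])
  dsmax <- as.vector(cb$dx[, , 2L])
  dxm <- dxm + dsavg / C
  dxm[cbind(seq_len(n), cache$imaxc)] <-
    dxm[cbind(seq_len(n), cache$imaxc)] + dsmax
  list(dx = array(dxm, d), dk = cb$dw, db = sum(cb$db))
}

#' Channel-attention gate
#'
#' Global average- and max-pools the feature map to two `C`-vectors, pushes
#' both through the shared bottleneck perceptron, sums, and squashes with a
#' sigmoid: one multiplicative weight per channel, strictly in (0, 1).
#'
#' @param F numeric feature map, dim `(H, W, C)`.
#' @param params a [channel_attention_params()] with matching `C`.
#' @param apply if `TRUE` return the gated feature map instead of the gate.
#' @return numeric gate vector of length `C`, or the refined map.
#' @export
channel_attention <- function(F, params, apply = FALSE) {
  f <- ca_fwd(F, params)
  if (apply) f$y else f$gate
}

#' Spatial-attention gate
#'
#' Concatenates the channel-wise mean and max maps, convolves with a 7x7
#' kernel (same padding) and applies a sigmoid: one multiplicative weight per
#' pixel, strictly in (0, 1).
#'
#' @param F numeric feature map, dim `(H, W, C)`.
#' @param params a [spatial_attention_params()].
#' @param apply if `TRUE` return the gated feature map instead of the gate.
#' @return numeric `H x W` gate matrix, or the refined map.
#' @export
spatial_attention <- function(F, params, apply = FALSE) {
  f <- sa_fwd(F, params)
  if (apply) f$y else f$gate
}

#' Convolutional block attention (channel then spatial)
#'
#' Applies the channel gate first and the spatial gate to the result:
#' `F' = M_s(F_c) * F_c` with `F_c = M_c(F) * F`. Output shape equals input
#' shape.
#'
#' @param F numeric feature map, dim `(H, W, C)`.
#' @param cparams a [channel_attention_params()].
#' @param sparams a [spatial_attention_params()].
#' @return refined feature map, same dim as `F`.
#' @export
cbam <- function(F, cparams, sparams) {
  sa_fwd(ca_fwd(F, cparams)$y, sparams)$y
}
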