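# Encoder-decoder segmentation network. Five encoder stages of 3x3
# conv-norm-ReLU blocks (counts 2,2,3,3,3) each ending in an optional
# attention block (channel then spatial gate) followed by 2x2 max pooling.
# The max-location unpooling of the classic design is replaced by skip
# connections: each stage's pre-pool feature map is routed (through its own
# attention block when enabled) to the decoder, where stages run
# upsample -> convs -> concat(skip); the final stage is upsample ->
# concat(skip) -> two convs -> per-pixel softmax. For a 256x256 input at
# default widths this reproduces the stage dimensions 128x128x64, 64x64x128,
# 32x32x256, 8x8x512 (encoder output) and decoder concatenations of 1024,
# 768, 384, 192 and 256 channels.

#' Network configuration
#'
#' @param in_channels input channels (default 8, the feature stack).
#' @param input_size nominal input side length (default 256); any input with
#'   sides divisible by 32 is accepted at run time.
#' @param k_classes number of output classes (default 3).
#' @param conv_counts convolutions per encoder stage (fixed-length 5).
#' @param widths encoder stage channel widths.
#' @param attention insert an attention block (channel + spatial gate) between
#'   the last convolution and the pooling of every encoder stage.
#' @param skip_attention route each skip connection through its own,
#'   separately parameterized attention block.
#' @param r channel-attention compression ratio (default 8).
#' @param norm use per-sample spatial normalization inside conv blocks.
#' @return object of class `network_config`.
#' @export
network_config <- function(in_channels = 8L, input_size = 256L, k_classes = 3L,
                           conv_counts = c(2L, 2L, 3L, 3L, 3L),
                           widths = c(64L, 128L, 256L, 512L, 512L),
                           attention = TRUE, skip_attention = attention,
                           r = 8L, norm = TRUE) {
  if (length(conv_counts) != 5L || length(widths) != 5L)
    stop("the encoder has five stages: conv_counts and widths must have length 5")
  if (input_size %% 32L != 0L)
    stop("input_size must be divisible by 32 (five 2x2 poolings)")
  if (k_classes < 2L) stop("need at least two classes")
  dec_widths <- c(widths[5], pmax(1L, widths[4] %/% 2L),
                  pmax(1L, widths[3] %/% 2L), pmax(1L, widths[2] %/% 2L))
  structure(list(in_channels = as.integer(in_channels),
                 input_size = as.integer(input_size),
                 k_classes = as.integer(k_classes),
                 conv_counts = as.integer(conv_counts),
                 widths = as.integer(widths),
                 dec_counts = c(3L, 3L, 3L, 2L),
                 dec_widths = as.integer(dec_widths),
                 attention = isTRUE(attention),
                 skip_attention = isTRUE(skip_attention),
                 r = as.integer(r), norm = isTRUE(norm)),
            class = "network_config")
}

conv_block_params <- function(cin, cout, norm) {
  p <- list(w = init_conv(3L, cin, cout), b = numeric(cout))
  if (norm) { p$g <- rep(1, cout); p$be <- numeric(cout) }
  p
}

# Gate biases start positive (gates ~ 0.9) so a freshly built attention
# network behaves like the plain network and learns to suppress features,
# rather than starting with every activation halved; the shared perceptron
# bias b1 enters the channel gate twice (once per pooled branch).
attn_params <- function(C, r, gate_bias = 2) {
  ca <- unclass(channel_attention_params(C, r))
  sa <- unclass(spatial_attention_params(bias = gate_bias))
  ca$b1 <- rep(gate_bias / 2, C)
  list(ca = ca[c("W0", "b0", "W1", "b1")], sa = sa[c("k", "b")])
}

#' Build the segmentation network
#'
#' Initializes all parameters (He-normal) for the architecture described by
#' `cfg`. With `attention = FALSE, skip_attention = FALSE` the same graph
#' without gates serves as the plain encoder-decoder baseline.
#'
#' @param cfg a [network_config()].
#' @param seed integer seed for weight initialization.
#' @return object of class `segnet` with elements `cfg` and `params`.
#' @export
build_segnet <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  set.seed(seed)
  P <- list(enc = vector("list", 5L), skip = vector("list", 5L),
            dec = vector("list", 4L))
  cin <- cfg$in_channels
  for (s in 1:5) {
    st <- list(conv = vector("list", cfg$conv_counts[s]))
    for (i in seq_len(cfg$conv_counts[s])) {
      st$conv[[i]] <- conv_block_params(cin, cfg$widths[s], cfg$norm)
      cin <- cfg$widths[s]
    }
    if (cfg$attention) st$attn <- attn_params(cfg$widths[s], cfg$r)
    P$enc[[s]] <- st
    if (cfg$skip_attention)
      P$skip[[s]] <- attn_params(cfg$widths[s], cfg$r)
  }
  din <- cfg$widths[5]
  for (t in 1:4) {
    st <- list(conv = vector("list", cfg$dec_counts[t]))
    for (i in seq_len(cfg$dec_counts[t])) {
      st$conv[[i]] <- conv_block_params(din, cfg$dec_widths[t], cfg$norm)
      din <- cfg$dec_widths[t]
    }
    P$dec[[t]] <- st
    din <- din + cfg$widths[6L - t]  # concat with skip(6 - t)
  }
  head_in <- din + cfg$widths[1]     # fifth concat
  P$head <- list(conv1 = conv_block_params(head_in, cfg$widths[1], cfg$norm),
                 conv2 = list(w = init_conv(3L, cfg$widths[1], cfg$k_classes),
                              b = numeric(cfg$k_classes)))
  structure(list(cfg = cfg, params = P), class = "segnet")
}

#' @export
print.segnet <- function(x, ...) {
  cat(sprintf(paste0("<segnet> %d-channel input, %d classes, widths (%s), ",
                     "attention %s, %s parameters\n"),
              x$cfg$in_channels, x$cfg$k_classes,
              paste(x$cfg$widths, collapse = ","),
              if (x$cfg$attention) "on" else "off",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Total number of trainable parameters
#' @param net a `segnet`.
#' @return integer count; a pure function of the [network_config()].
#' @export
count_parameters <- function(net) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else n <<- n + length(x)
    invisible(NULL)
  }
  walk(net$params)
  n
}

block_fwd <- function(x, p, norm) {
  y <- nn_conv_fwd(x, p$w, p$b)
  nf <- NULL
  if (norm) { nf <- nn_norm_fwd(y, p$g, p$be); y <- nf$y }
  mask <- y > 0
  list(y = y * mask, cache = list(x = x, nf = nf, mask = mask))
}

block_bwd <- function(dy, p, cache, norm) {
  dy <- dy * cache$mask
  g <- list()
  if (norm) {
    nb <- nn_norm_bwd(cache$nf, p$g, dy)
    dy <- nb$dx; g$g <- nb$dgamma; g$be <- nb$dbeta
  }
  cb <- nn_conv_bwd(cache$x, p$w, dy)
  g$w <- cb$dw; g$b <- cb$db
  list(dx = cb$dx, grads = g)
}

as_ca_params <- function(p) {
  p$C <- nrow(p$W1)
  structure(p, class = "channel_attention_params")
}

attn_fwd <- function(x, p) {
  ca <- ca_fwd(x, as_ca_params(p$ca))
  sa <- sa_fwd(ca$y, p$sa)
  list(y = sa$y, ca = ca, sa = sa)
}

attn_bwd <- function(dy, p, cache) {
  sb <- sa_bwd(cache$sa, p$sa, dy)
  cb <- ca_bwd(cache$ca, as_ca_params(p$ca), sb$dx)
  list(dx = cb$dx,
       grads = list(ca = list(W0 = cb$dW0, b0 = cb$db0,
                              W1 = cb$dW1, b1 = cb$db1),
                    sa = list(k = sb$dk, b = sb$db)))
}

dim_str <- function(d) paste(d, collapse = " x ")

#' Forward pass
#'
#' @param net a `segnet` from [build_segnet()].
#' @param x input array `(H, W, in_channels)` with `H`, `W` divisible by 32.
#' @param want_cache keep intermediate activations for [segnet_backward()].
#' @param want_shapes record the named intermediate shapes (for audit).
#' @param want_features also return the penultimate-layer feature map.
#' @return list with `prob` (per-pixel class probabilities, `(H, W, k)`),
#'   `logits`, and optionally `cache`, `shapes`, `features`.
#' @export
segnet_forward <- function(net, x, want_cache = FALSE, want_shapes = FALSE,
                           want_features = FALSE) {
  cfg <- net$cfg; P <- net$params
  d <- dim(x)
  if (length(d) != 3L || d[3] != cfg$in_channels)
    stop("input must be (H, W, ", cfg$in_channels, ")")
  if (any(d[1:2] %% 32L != 0L))
    stop("input sides must be divisible by 32")
  shapes <- list()
  note <- function(nm, v) if (want_shapes) shapes[[nm]] <<- dim(v)
  keep <- function(v) if (want_cache) v else NULL
  cache <- list(enc = vector("list", 5L), dec = vector("list", 5L))
  skips <- vector("list", 5L)
  h <- x
  for (s in 1:5) {
    st <- list(conv = vector("list", cfg$conv_counts[s]))
    for (i in seq_len(cfg$conv_counts[s])) {
      bf <- block_fwd(h, P$enc[[s]]$conv[[i]], cfg$norm)
      st$conv[[i]] <- keep(bf$cache)
      h <- bf$y
    }
    if (cfg$attention) {
      af <- attn_fwd(h, P$enc[[s]]$attn)
      st$attn <- keep(af[c("ca", "sa")])
      h <- af$y
    }
    note(sprintf("enc%d_prepool", s), h)
    if (cfg$skip_attention) {
      sf <- attn_fwd(h, P$skip[[s]])
      st$skip <- keep(sf[c("ca", "sa")])
      skips[[s]] <- sf$y
    } else skips[[s]] <- h
    note(sprintf("skip%d", s), skips[[s]])
    mp <- nn_maxpool_fwd(h)
    st$pool_idx <- keep(mp$idx)
    st$prepool_dim <- dim(h)
    h <- mp$y
    note(sprintf("enc%d_postpool", s), h)
    cache$enc[[s]] <- st
  }
  note("encoder_output", h)
  for (t in 1:4) {
    st <- list(conv = vector("list", cfg$dec_counts[t]))
    st$pre_up_dim <- dim(h)
    h <- nn_upsample_fwd(h)
    for (i in seq_len(cfg$dec_counts[t])) {
      bf <- block_fwd(h, P$dec[[t]]$conv[[i]], cfg$norm)
      st$conv[[i]] <- keep(bf$cache)
      h <- bf$y
    }
    st$dec_channels <- dim(h)[3]
    h <- nn_concat(h, skips[[6L - t]])
    note(sprintf("dec%d_concat", t), h)
    cache$dec[[t]] <- st
  }
  st <- list(pre_up_dim = dim(h))
  h <- nn_upsample_fwd(h)
  note("dec5_upsample", h)
  st$dec_channels <- dim(h)[3]
  h <- nn_concat(h, skips[[1L]])
  note("dec5_concat", h)
  b1 <- block_fwd(h, P$head$conv1, cfg$norm)
  st$conv1 <- keep(b1$cache)
  feat <- b1$y
  logits <- nn_conv_fwd(feat, P$head$conv2$w, P$head$conv2$b)
  st$feat <- keep(feat)
  cache$dec[[5]] <- st
  note("output", logits)
  out <- list(prob = nn_softmax(logits), logits = logits)
  if (want_cache) out$cache <- cache
  if (want_shapes) out$shapes <- shapes
  if (want_features) out$features <- feat
  out
}

#' Backward pass
#'
#' @param net a `segnet`.
#' @param cache the cache from `segnet_forward(..., want_cache = TRUE)`.
#' @param dlogits gradient of the loss with respect to the logits.
#' @return nested gradient list parallel to `net$params`.
#' @export
segnet_backward <- function(net, cache, dlogits) {
  cfg <- net$cfg; P <- net$params
  G <- list(enc = vector("list", 5L), skip = vector("list", 5L),
            dec = vector("list", 4L))
  dskips <- vector("list", 5L)
  st <- cache$dec[[5]]
  cb <- nn_conv_bwd(st$feat, P$head$conv2$w, dlogits)
  Ghead <- list(conv2 = list(w = cb$dw, b = cb$db))
  bb <- block_bwd(cb$dx, P$head$conv1, st$conv1, cfg$norm)
  Ghead$conv1 <- bb$grads
  G$head <- Ghead
  sp <- nn_split(bb$dx, st$dec_channels)
  dskips[[1]] <- sp$db
  dh <- nn_upsample_bwd(sp$da)
  for (t in 4:1) {
    st <- cache$dec[[t]]
    sp <- nn_split(dh, st$dec_channels)
    dskips[[6L - t]] <- sp$db
    dh <- sp$da
    Gd <- list(conv = vector("list", cfg$dec_counts[t]))
    for (i in rev(seq_len(cfg$dec_counts[t]))) {
      bb <- block_bwd(dh, P$dec[[t]]$conv[[i]], st$conv[[i]], cfg$norm)
      Gd$conv[[i]] <- bb$grads
      dh <- bb$dx
    }
    G$dec[[t]] <- Gd
    dh <- nn_upsample_bwd(dh)
  }
  for (s in 5:1) {
    st <- cache$enc[[s]]
    dpre <- nn_maxpool_bwd(st$pool_idx, dh, st$prepool_dim[1], st$prepool_dim[2])
    if (cfg$skip_attention) {
      ab <- attn_bwd(dskips[[s]], P$skip[[s]], st$skip)
      G$skip[[s]] <- ab$grads
      dpre <- dpre + ab$dx
    } else dpre <- dpre + dskips[[s]]
    Ge <- list(conv = vector("list", cfg$conv_counts[s]))
    if (cfg$attention) {
      ab <- attn_bwd(dpre, P$enc[[s]]$attn, st$attn)
      Ge$attn <- ab$grads
      dpre <- ab$dx
    }
    for (i in rev(seq_len(cfg$conv_counts[s]))) {
      bb <- block_bwd(dpre, P$enc[[s]]$conv[[i]], st$conv[[i]], cfg$norm)
      Ge$conv[[i]] <- bb$grads
      dpre <- bb$dx
    }
    G$enc[[s]] <- Ge
    dh <- dpre
  }
  G
}

#' Per-layer shape summary
#'
#' Builds (or reuses) a network and reports every named intermediate shape for
#' a square input, for audit against the published stage dimensions.
#'
#' @param net a `segnet` or a [network_config()].
#' @param input_size input side length; default from the config.
#' @return data.frame with columns `stage` and `shape`.
#' @export
network_summary <- function(net, input_size = NULL) {
  if (inherits(net, "network_config")) net <- build_segnet(net, seed = 1L)
  cfg <- net$cfg
  if (is.null(input_size)) input_size <- cfg$input_size
  x <- array(0, c(input_size, input_size, cfg$in_channels))
  fw <- segnet_forward(net, x, want_shapes = TRUE)
  data.frame(stage = names(fw$shapes),
             shape = vapply(fw$shapes, dim_str, ""),
             stringsAsFactors = FALSE)
}

#' Predict class codes for one tile
#' @param net a `segnet`.
#' @param x feature tile `(H, W, in_channels)`.
#' @return integer matrix of 0-based class codes.
#' @export
segnet_predict_tile <- function(net, x) {
  p <- segnet_forward(net, x)$prob
  d <- dim(p)
  matrix(max.col(matrix(p, d[1] * d[2], d[3]), ties.method = "first") - 1L,
         d[1], d[2])
}

#' Predict a whole region with edge-ignoring tiling and stitching
#'
#' @param net a `segnet`.
#' @param features rank-3 feature array covering the scene (already
#'   normalized with the training statistics).
#' @param region a `scene_region`.
#' @param spec a [tile_spec()].
#' @return integer matrix of 0-based class codes with the region's dimensions.
#' @export
predict_region <- function(net, features, region, spec) {
  ts <- tile_test_region(features, region, spec)
  preds <- lapply(ts$tiles, function(t) segnet_predict_tile(net, t$x))
  stitch_predictions(preds, ts)
}

# ---- parameter-tree utilities (training support) ----

tree_map <- function(x, f) {
  if (is.null(x)) NULL
  else if (is.list(x)) lapply(x, tree_map, f = f)
  else f(x)
}

# Combine two parallel parameter/gradient trees leaf-wise. Subtrees are
# matched by name when names are present (construction order of gradient
# lists need not mirror the parameter lists), by position otherwise.
tree_map2 <- function(a, b, f) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    nms <- names(a)
    for (i in seq_along(a)) {
      bi <- if (!is.null(nms) && nzchar(nms[i])) b[[nms[i]]] else b[[i]]
      val <- tree_map2(a[[i]], bi, f)
      if (!is.null(val)) out[[i]] <- val
    }
    out
  } else f(a, b)
}

tree_sum_sq <- function(x) {
  tot <- 0
  walk <- function(v) {
    if (is.list(v)) lapply(v, walk) else tot <<- tot + sum(v * v)
    invisible(NULL)
  }
  walk(x)
  tot
}
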