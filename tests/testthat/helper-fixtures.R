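# Shared fixtures, built in code at test time.

# small scene with explicit per-band constants (no noise unless asked)
const_scene <- function(vals, H = 4, W = 5) {
  arr <- array(NA_real_, c(H, W, length(vals)))
  for (b in seq_along(vals)) arr[, , b] <- vals[b]
  multispectral_scene(arr)
}

# label raster with a vertical straight boundary: left class / right class
split_labels <- function(H, W, left = 1L, right = 2L) {
  m <- matrix(right, H, W)
  m[, seq_len(W %/% 2)] <- left
  label_raster(m)
}

# tiny network configuration that still exercises all five stages
tiny_cfg <- function(in_channels = 8, k = 3, attention = TRUE,
                     widths = c(4, 4, 4, 4, 4), r = 2) {
  network_config(in_channels = in_channels, input_size = 32, k_classes = k,
                 widths = widths, r = r, attention = attention,
                 skip_attention = attention)
}

# naive 4-loop "same"-padded 2-D convolution oracle (single output channel)
naive_conv <- function(x, kernel_arr, bias = 0) {
  kh <- dim(kernel_arr)[1]; kw <- dim(kernel_arr)[2]; C <- dim(kernel_arr)[3]
  ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
  H <- dim(x)[1]; W <- dim(x)[2]
  out <- matrix(bias, H, W)
  for (i in seq_len(H)) for (j in seq_len(W))
    for (di in seq_len(kh)) for (dj in seq_len(kw)) {
      ii <- i + di - 1 - ph; jj <- j + dj - 1 - pw
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        for (c in seq_len(C))
          out[i, j] <- out[i, j] + x[ii, jj, c] * kernel_arr[di, dj, c]
    }
  out
}

# flood-fill connected components (4-neighbour) on an integer matrix;
# independent of the generator's internals
connected_components <- function(m) {
  H <- nrow(m); W <- ncol(m)
  comp <- matrix(0L, H, W)
  cur <- 0L
  for (start in which(comp == 0L)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    cls <- m[start]
    comp[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]; queue <- queue[-length(queue)]
      i <- (p - 1L) %% H + 1L; j <- (p - 1L) %/% H + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1L && ii <= H && jj >= 1L && jj <= W) {
          q <- (jj - 1L) * H + ii
          if (comp[q] == 0L && m[q] == cls) { comp[q] <- cur; queue <- c(queue, q) }
        }
      }
    }
  }
  comp
}

# brute-force per-pixel metric tally, independent of the eval module
naive_metrics <- function(pred, truth, k) {
  cm <- matrix(0, k, k)
  for (i in seq_along(pred)) cm[pred[i] + 1, truth[i] + 1] <- cm[pred[i] + 1, truth[i] + 1] + 1
  N <- sum(cm)
  oa <- sum(diag(cm)) / N
  iou <- numeric(0)
  for (c in seq_len(k)) {
    denom <- sum(cm[c, ]) + sum(cm[, c]) - cm[c, c]
    if (denom > 0) iou <- c(iou, cm[c, c] / denom)
  }
  chance <- sum(rowSums(cm) * colSums(cm))
  kap <- if (N^2 == chance) NA_real_ else (N * sum(diag(cm)) - chance) / (N^2 - chance)
  list(cm = cm, oa = oa, miou = mean(iou), kappa = kap)
}
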