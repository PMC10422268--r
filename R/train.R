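# Optimization recipe: Adam with L2 weight decay on per-pixel cross-entropy,
# batch accumulation, reduce-on-plateau learning rate, and early stopping on
# the monitored accuracy (training accuracy by default). No data augmentation
# is applied anywhere in the loop.

#' Training configuration
#'
#' Defaults follow the published recipe: initial learning rate 0.1 (note:
#' aggressive - 0.01 is the usual choice, and scaled-down experiments in this
#' package use smaller rates), batch size 8, weight decay 0.001, at most 150
#' epochs, early stopping after 30 epochs without improvement of training
#' accuracy, Adam optimizer. The learning rate is reduced on plateau of the
#' training loss (factor 0.1, patience 10).
#'
#' @param lr initial learning rate.
#' @param batch_size tiles per optimizer step.
#' @param weight_decay L2 penalty added to weight gradients (not biases or
#'   normalization parameters).
#' @param epochs maximum number of epochs.
#' @param patience early-stopping patience in epochs.
#' @param monitor `"train_acc"` (default) or `"val_acc"`.
#' @param plateau_factor,plateau_patience reduce-on-plateau schedule on the
#'   training loss.
#' @param seed integer seed controlling shuffling.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 0.1, batch_size = 8L, weight_decay = 0.001,
                         epochs = 150L, patience = 30L,
                         monitor = c("train_acc", "val_acc"),
                         plateau_factor = 0.1, plateau_patience = 10L,
                         seed = 1L) {
  monitor <- match.arg(monitor)
  stopifnot(lr > 0, batch_size >= 1, weight_decay >= 0, epochs >= 1,
            patience >= 1, patience < epochs || epochs == 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 patience = as.integer(patience), monitor = monitor,
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

DECAY_LEAVES <- c("w", "W0", "W1", "k")

adam_init <- function(params) {
  z <- tree_map(params, function(x) x * 0)
  list(m = z, v = z, t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  rec <- function(p, g, m, v, nm) {
    if (is.null(p)) return(list(p = NULL, m = NULL, v = NULL))
    if (is.list(p)) {
      nms <- names(p)
      for (i in seq_along(p)) {
        leaf_nm <- if (!is.null(nms)) nms[i] else ""
        gi <- if (!is.null(nms) && nzchar(leaf_nm)) g[[leaf_nm]] else g[[i]]
        r <- rec(p[[i]], gi, m[[i]], v[[i]], leaf_nm)
        if (!is.null(r$p)) { p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v }
      }
      list(p = p, m = m, v = v)
    } else {
      if (weight_decay > 0 && nm %in% DECAY_LEAVES) g <- g + weight_decay * p
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  r <- rec(params, grads, state$m, state$v, "")
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

tile_codes <- function(y) {
  if (inherits(y, "label_raster")) y$values else y
}

# loss + accuracy + gradients for one tile
tile_pass <- function(net, tile, want_grad = TRUE) {
  y <- tile_codes(tile$y)
  fw <- segnet_forward(net, tile$x, want_cache = want_grad)
  sm <- nn_softmax_ce(fw$logits, y, want_grad = want_grad)
  d <- dim(fw$prob)
  pred <- max.col(matrix(fw$prob, d[1] * d[2], d[3]), ties.method = "first") - 1L
  acc <- mean(pred == as.vector(y))
  out <- list(loss = sm$loss, acc = acc)
  if (want_grad) out$grads <- segnet_backward(net, fw$cache, sm$dlogits)
  out
}

#' Mean loss and pixel accuracy over a tile set (no updates)
#'
#' @param net a `segnet`.
#' @param tiles list of tiles with elements `x` (features) and `y` (labels),
#'   or a `tile_set`.
#' @return list with `loss` (mean per-pixel cross-entropy) and `accuracy`.
#' @export
evaluate_epoch <- function(net, tiles) {
  if (inherits(tiles, "tile_set")) tiles <- tiles$tiles
  if (!length(tiles)) stop("empty tile set")
  res <- lapply(tiles, function(t) tile_pass(net, t, want_grad = FALSE))
  list(loss = mean(vapply(res, `[[`, 0, "loss")),
       accuracy = mean(vapply(res, `[[`, 0, "acc")))
}

#' Train the network
#'
#' Optimizes per-pixel cross-entropy with Adam and weight decay, accumulating
#' gradients over `batch_size` tiles per step. Training halts at `epochs` or
#' when the monitored accuracy has not improved for `patience` consecutive
#' epochs; the best-performing parameters are restored before returning.
#'
#' @param net a `segnet` from [build_segnet()].
#' @param train_tiles list of training tiles (`x`, `y`), or a `tile_set`
#'   (its `"train"` tiles are used and `"val"` tiles become `val_tiles`
#'   unless supplied).
#' @param val_tiles optional validation tiles.
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with `net` (best checkpoint) and `history` (data.frame of
#'   epoch, loss, train_acc, val_acc, lr; plus `best_epoch` attribute).
#' @export
train_network <- function(net, train_tiles, val_tiles = NULL,
                          cfg = train_config(), verbose = FALSE) {
  if (inherits(train_tiles, "tile_set")) {
    roles <- vapply(train_tiles$tiles, `[[`, "", "role")
    if (is.null(val_tiles) && any(roles == "val"))
      val_tiles <- train_tiles$tiles[roles == "val"]
    train_tiles <- train_tiles$tiles[roles == "train"]
  }
  if (!length(train_tiles)) stop("empty training tile set")
  bad <- vapply(train_tiles, function(t) any(tile_codes(t$y) >= net$cfg$k_classes),
                NA)
  if (any(bad)) stop("label codes must be < k_classes")
  set.seed(cfg$seed)
  state <- adam_init(net$params)
  lr <- cfg$lr
  hist <- data.frame(epoch = integer(), loss = double(), train_acc = double(),
                     val_acc = double(), lr = double())
  best_metric <- -Inf; best_epoch <- 0L; best_params <- net$params
  best_loss <- Inf; loss_stall <- 0L
  n <- length(train_tiles)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- accs <- double(0)
    b <- 1L
    while (b <= n) {
      idx <- ord[b:min(b + cfg$batch_size - 1L, n)]
      gsum <- NULL
      for (i in idx) {
        tp <- tile_pass(net, train_tiles[[i]])
        if (!is.finite(tp$loss))
          stop("training diverged: non-finite loss at epoch ", epoch,
               " (learning rate ", lr, ")")
        losses <- c(losses, tp$loss); accs <- c(accs, tp$acc)
        gsum <- if (is.null(gsum)) tp$grads else
          tree_map2(gsum, tp$grads, `+`)
      }
      gsum <- tree_map(gsum, function(g) g / length(idx))
      up <- adam_step(net$params, gsum, state, lr, cfg$weight_decay)
      net$params <- up$params; state <- up$state
      b <- b + cfg$batch_size
    }
    ep_loss <- mean(losses); ep_acc <- mean(accs)
    val_acc <- NA_real_
    if (!is.null(val_tiles) && length(val_tiles))
      val_acc <- evaluate_epoch(net, val_tiles)$accuracy
    hist <- rbind(hist, data.frame(epoch = epoch, loss = ep_loss,
                                   train_acc = ep_acc, val_acc = val_acc,
                                   lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.4f  val %.4f  lr %.2g",
                      epoch, ep_loss, ep_acc, val_acc, lr))
    metric <- if (cfg$monitor == "val_acc" && !is.na(val_acc)) val_acc else ep_acc
    if (metric > best_metric + 1e-12) {
      best_metric <- metric; best_epoch <- epoch; best_params <- net$params
    }
    if (epoch - best_epoch >= cfg$patience) break
    if (ep_loss < best_loss - 1e-6) {
      best_loss <- ep_loss; loss_stall <- 0L
    } else {
      loss_stall <- loss_stall + 1L
      if (loss_stall >= cfg$plateau_patience) {
        lr <- lr * cfg$plateau_factor
        loss_stall <- 0L
        if (verbose) message("  reducing learning rate to ", lr)
      }
    }
  }
  net$params <- best_params
  attr(hist, "best_epoch") <- best_epoch
  list(net = net, history = hist)
}
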