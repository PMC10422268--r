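# Confusion-matrix metrics: overall accuracy, per-class IoU / mean IoU, and
# Cohen's kappa, all derived from a k x k count matrix with rows = predicted
# class, columns = reference class. Plus misclassification maps, 2-D feature
# embeddings with a silhouette separability score, and the cross-domain
# (simulated cross-year) transfer harness.

#' Confusion matrix of two aligned label rasters
#'
#' @param pred predicted labels: [label_raster()] or integer matrix of codes
#'   in `[0, k)`.
#' @param truth reference labels, same shape.
#' @param k number of classes.
#' @param mask optional logical matrix; `FALSE` pixels are ignored.
#' @return `k x k` integer matrix `N[i, j]` = pixels predicted `i-1` with
#'   truth `j-1`, of class `confusion_matrix`.
#' @export
confusion_matrix <- function(pred, truth, k = 3L, mask = NULL) {
  p <- if (inherits(pred, "label_raster")) pred$values else pred
  t <- if (inherits(truth, "label_raster")) truth$values else truth
  stopifnot_aligned(p, t)
  if (!is.null(mask)) { p <- p[mask]; t <- t[mask] }
  p <- as.vector(p); t <- as.vector(t)
  if (any(p < 0 | p >= k) || any(t < 0 | t >= k))
    stop("label codes outside [0, ", k, ")")
  cm <- table(factor(p, levels = 0:(k - 1)), factor(t, levels = 0:(k - 1)))
  cm <- matrix(as.integer(cm), k, k,
               dimnames = list(pred = 0:(k - 1), truth = 0:(k - 1)))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

as_cm <- function(cm) {
  cm <- unclass(cm)
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), all(cm >= 0))
  storage.mode(cm) <- "double"  # counts can overflow integer arithmetic
  cm
}

#' Overall accuracy: trace over total
#' @param cm a confusion matrix (any square count matrix).
#' @return `sum(diag(cm)) / sum(cm)`.
#' @export
overall_accuracy <- function(cm) {
  cm <- as_cm(cm)
  N <- sum(cm)
  if (N == 0) stop("empty confusion matrix")
  sum(diag(cm)) / N
}

#' Per-class intersection over union
#' @param cm a confusion matrix.
#' @return numeric vector `N_ii / (N_i+ + N_+i - N_ii)` per class; `NaN` for
#'   classes absent from both prediction and reference.
#' @export
class_iou <- function(cm) {
  cm <- as_cm(cm)
  di <- diag(cm)
  denom <- rowSums(cm) + colSums(cm) - di
  ifelse(denom > 0, di / denom, NaN)
}

#' Mean intersection over union
#'
#' Mean of the per-class IoU over the evaluated classes. Classes absent from
#' both prediction and reference are excluded with a warning; a degenerate
#' single-class matrix with perfect agreement gives 1.
#'
#' @param cm a confusion matrix.
#' @param classes optional integer vector of 0-based class codes to average
#'   over (e.g. `c(1, 2)` to restrict to the two crops).
#' @return mean IoU in `[0, 1]`.
#' @export
mean_iou <- function(cm, classes = NULL) {
  iou <- class_iou(cm)
  if (!is.null(classes)) iou <- iou[classes + 1L]
  if (anyNA(iou)) {
    warning("class(es) absent from both prediction and reference excluded")
    iou <- iou[!is.na(iou)]
  }
  if (!length(iou)) stop("no evaluable classes")
  mean(iou)
}

#' Cohen's kappa coefficient
#'
#' Chance-corrected agreement
#' `(N * sum(N_ii) - sum(N_i+ N_+i)) / (N^2 - sum(N_i+ N_+i))`.
#'
#' @param cm a confusion matrix.
#' @return kappa in `[-1, 1]`; `NA` with a warning when the marginals are
#'   degenerate (`N^2 == sum(N_i+ N_+i)`).
#' @export
kappa_coefficient <- function(cm) {
  cm <- as_cm(cm)
  N <- sum(cm)
  if (N == 0) stop("empty confusion matrix")
  chance <- sum(rowSums(cm) * colSums(cm))
  denom <- N^2 - chance
  if (denom == 0) {
    warning("degenerate marginals: kappa undefined")
    return(NA_real_)
  }
  (N * sum(diag(cm)) - chance) / denom
}

#' Full metrics report from predictions and truth
#'
#' @inheritParams confusion_matrix
#' @param class_names optional class names.
#' @return object of class `metrics_report`: list with `cm`, `oa`, `iou`,
#'   `miou`, `kappa`, `n`.
#' @export
metrics_report <- function(pred, truth, k = 3L, mask = NULL,
                           class_names = names(DEFAULT_CLASSES)) {
  cm <- confusion_matrix(pred, truth, k, mask)
  iou <- class_iou(cm)
  if (!is.null(class_names) && length(class_names) == k)
    names(iou) <- class_names
  structure(list(cm = cm, oa = overall_accuracy(cm), iou = iou,
                 miou = mean_iou(cm), kappa = kappa_coefficient(cm),
                 n = sum(cm)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d pixels\n", x$n))
  cat(sprintf("  OA    %.4f\n  MIoU  %.4f\n  Kappa %.4f\n",
              x$oa, x$miou, x$kappa))
  cat("  per-class IoU:",
      paste(sprintf("%s=%.4f", names(x$iou), x$iou), collapse = "  "), "\n")
  invisible(x)
}

#' Binary misclassification map
#'
#' @param pred,truth aligned label rasters or integer matrices.
#' @return integer matrix: 1 where `pred != truth`, 0 elsewhere.
#' @export
misclassification_map <- function(pred, truth) {
  p <- if (inherits(pred, "label_raster")) pred$values else pred
  t <- if (inherits(truth, "label_raster")) truth$values else truth
  stopifnot_aligned(p, t)
  matrix(as.integer(p != t), nrow(p), ncol(p))
}

# mean silhouette width by class on Euclidean distances
silhouette_score <- function(xmat, labels) {
  labels <- as.integer(labels)
  D <- as.matrix(dist(xmat))
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- labels == labels[i]; same[i] <- FALSE
    others <- setdiff(unique(labels), labels[i])
    if (!any(same) || !length(others)) { s[i] <- 0; next }
    a <- mean(D[i, same])
    b <- min(vapply(others, function(cl) mean(D[i, labels == cl]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Export 2-D embeddings of raw vs. network features for crop pixels
#'
#' Randomly samples `n` corn/soybean pixels, extracts (a) their raw 8-channel
#' feature vectors and (b) their penultimate-layer network features (obtained
#' by tiled prediction over the sampled region), and projects each set to 2-D
#' with a nonlinear mapping (Sammon projection; classical scaling fallback on
#' degenerate distances). A mean silhouette by class quantifies separability
#' of each set.
#'
#' @param net a `segnet`.
#' @param features normalized feature array covering the scene.
#' @param labels a [label_raster()] aligned with `features`.
#' @param region optional `scene_region` to sample from (default: whole
#'   scene).
#' @param spec a [tile_spec()] used to tile the region for feature
#'   extraction.
#' @param n number of crop pixels to sample (default 3000; all available are
#'   used, with a warning, when fewer exist).
#' @param seed integer sampling seed.
#' @return list with data.frames `raw` and `network` (columns `dim1`, `dim2`,
#'   `class`) and silhouettes `silhouette_raw`, `silhouette_network`.
#' @export
export_embedding <- function(net, features, labels, region = NULL,
                             spec = tile_spec(), n = 3000L, seed = 1L) {
  lab <- tile_codes(labels)
  stopifnot_aligned(features, lab)
  if (is.null(region))
    region <- region_new(c(1L, nrow(lab)), c(1L, ncol(lab)))
  ts <- tile_test_region(features, region, spec)
  # stitch the penultimate feature maps over the region
  nf <- NULL
  for (i in seq_along(ts$tiles)) {
    t <- ts$tiles[[i]]
    fw <- segnet_forward(net, t$x, want_features = TRUE)
    if (is.null(nf)) {
      rd <- region_dims(region)
      nf <- array(NA_real_, c(rd[1], rd[2], dim(fw$features)[3]))
    }
    kr <- t$keep$rows; kc <- t$keep$cols
    nf[(kr[1]:kr[2]) - region$rows[1] + 1L,
       (kc[1]:kc[2]) - region$cols[1] + 1L, ] <-
      fw$features[(kr[1]:kr[2]) - t$origin[1] + 1L,
                  (kc[1]:kc[2]) - t$origin[2] + 1L, , drop = FALSE]
  }
  rl <- lab[region$rows[1]:region$rows[2], region$cols[1]:region$cols[2]]
  crop <- which(rl == DEFAULT_CLASSES[["corn"]] |
                  rl == DEFAULT_CLASSES[["soybean"]])
  if (length(crop) < n) {
    warning("only ", length(crop), " crop pixels available; using all")
    n <- length(crop)
  }
  set.seed(seed)
  pick <- sample(crop, n)
  rd <- region_dims(region)
  ij <- cbind((pick - 1L) %% rd[1] + 1L, (pick - 1L) %/% rd[1] + 1L)
  raw_sub <- features[region$rows[1]:region$rows[2],
                      region$cols[1]:region$cols[2], , drop = FALSE]
  raw <- t(apply(ij, 1, function(rc) raw_sub[rc[1], rc[2], ]))
  netf <- t(apply(ij, 1, function(rc) nf[rc[1], rc[2], ]))
  cls <- names(DEFAULT_CLASSES)[match(rl[ij], DEFAULT_CLASSES)]
  embed2d <- function(m) {
    # deduplicate for the distance-based mapping; jitter exact duplicates
    d <- dist(m)
    if (any(d == 0)) d <- d + runif(length(d), 0, 1e-9)
    out <- tryCatch(MASS::sammon(d, k = 2, trace = FALSE)$points,
                    error = function(e) cmdscale(d, k = 2))
    data.frame(dim1 = out[, 1], dim2 = out[, 2], class = cls)
  }
  list(raw = embed2d(raw), network = embed2d(netf),
       silhouette_raw = silhouette_score(raw, match(cls, names(DEFAULT_CLASSES))),
       silhouette_network = silhouette_score(netf,
                                             match(cls, names(DEFAULT_CLASSES))))
}

#' Cross-domain (cross-year) evaluation
#'
#' Evaluates a model trained on domain A against a scene from domain B: the
#' B scene's feature stack is normalized with A's training statistics,
#' predicted with edge-ignoring tiling, stitched, and scored against B's
#' labels.
#'
#' @param net a `segnet` trained on domain A.
#' @param scene_b the [multispectral_scene()] of domain B.
#' @param labels_b the [label_raster()] of domain B.
#' @param stats_a the normalization statistics of A's training region (from
#'   [normalize_stack()]).
#' @param region optional `scene_region` of B to evaluate (default: whole
#'   scene).
#' @param spec a [tile_spec()].
#' @param index_choice eighth feature channel, as in [build_feature_stack()].
#' @return a [metrics_report()].
#' @export
cross_domain_eval <- function(net, scene_b, labels_b, stats_a,
                              region = NULL, spec = tile_spec(),
                              index_choice = "rededge") {
  fs <- normalize_stack(build_feature_stack(scene_b, index_choice), stats_a)
  lab <- tile_codes(labels_b)
  if (is.null(region))
    region <- region_new(c(1L, nrow(lab)), c(1L, ncol(lab)))
  pred <- predict_region(net, fs, region, spec)
  truth <- lab[region$rows[1]:region$rows[2], region$cols[1]:region$cols[2]]
  metrics_report(pred, truth, k = net$cfg$k_classes)
}

#' Pairwise transfer matrix over a set of domains
#'
#' Runs [cross_domain_eval()] for every (model, domain) pair and reports the
#' mean-IoU matrix, mirroring grouped cross-year comparisons.
#'
#' @param nets named list of trained `segnet`s (one per source domain).
#' @param domains named list of domains, each a list with `scene`, `labels`,
#'   `stats` (the source-domain training statistics for that net).
#' @param spec a [tile_spec()].
#' @param ... passed to [cross_domain_eval()].
#' @return numeric matrix of MIoU values, rows = model domain, cols = test
#'   domain.
#' @export
transfer_matrix <- function(nets, domains, spec = tile_spec(), ...) {
  out <- matrix(NA_real_, length(nets), length(domains),
                dimnames = list(model = names(nets), test = names(domains)))
  for (a in seq_along(nets)) for (b in seq_along(domains)) {
    d <- domains[[b]]
    rep <- cross_domain_eval(nets[[a]], d$scene, d$labels,
                             domains[[a]]$stats, spec = spec, ...)
    out[a, b] <- rep$miou
  }
  out
}
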