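# Confusion-matrix metrics, misclassification maps, embeddings, transfer.

test_that("confusion matrix counts match a hand tally", {
  pred <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  truth <- matrix(c(0L, 1L, 1L, 1L), 2, 2)
  cm <- confusion_matrix(pred, truth, k = 3)
  # pairs (pred, truth): (0,0), (1,1), (2,1), (1,1)
  expect_equal(unclass(cm)[,],
               matrix(c(1L, 0L, 0L,
                        0L, 2L, 0L,
                        0L, 1L, 0L), 3, 3,
                      dimnames = dimnames(cm), byrow = TRUE))
  expect_equal(sum(cm), 4)
  # identical rasters give a diagonal matrix
  cmd <- confusion_matrix(truth, truth, k = 3)
  expect_true(all(cmd[upper.tri(cmd) | lower.tri(cmd)] == 0))
  # masked pixels are excluded
  mask <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  expect_equal(sum(confusion_matrix(pred, truth, k = 3, mask = mask)), 3)
  expect_error(confusion_matrix(matrix(5L, 2, 2), truth, k = 3), "outside")
  expect_error(confusion_matrix(pred, matrix(0L, 3, 3), k = 3), "aligned")
})

test_that("the worked 2x2 matrix reproduces OA, MIoU and kappa", {
  cm <- matrix(c(50, 10, 5, 35), 2, 2, byrow = TRUE)
  expect_equal(overall_accuracy(cm), 0.85)
  expect_equal(class_iou(cm), c(50 / 65, 35 / 50))
  expect_equal(mean_iou(cm), (50 / 65 + 35 / 50) / 2)
  expect_equal(mean_iou(cm), 0.7346, tolerance = 1e-4)
  expect_equal(kappa_coefficient(cm), (100 * 85 - 5100) / (10000 - 5100))
  expect_equal(kappa_coefficient(cm), 0.6939, tolerance = 1e-4)
})

test_that("metrics agree with a naive tally over all 2x2 3-class labelings", {
  grids <- as.matrix(expand.grid(0:2, 0:2, 0:2, 0:2))
  for (pi in seq_len(nrow(grids))) {
    pred <- matrix(grids[pi, ], 2, 2)
    # a deterministic subset of truths against every prediction keeps the
    # loop exhaustive per pixel pattern but fast
    for (ti in seq(1, nrow(grids), by = 8)) {
      truth <- matrix(grids[ti, ], 2, 2)
      cm <- confusion_matrix(pred, truth, k = 3)
      ref <- naive_metrics(as.vector(pred), as.vector(truth), 3)
      expect_equal(unclass(cm)[,], ref$cm, ignore_attr = TRUE)
      expect_equal(overall_accuracy(cm), ref$oa)
      expect_equal(suppressWarnings(mean_iou(cm)), ref$miou)
      if (is.na(ref$kappa)) {
        expect_warning(expect_true(is.na(kappa_coefficient(cm))), "degenerate")
      } else {
        expect_equal(kappa_coefficient(cm), ref$kappa)
      }
    }
  }
})

test_that("kappa is at most 1, zero-centred under label permutation", {
  # sign consistency: kappa > 0 iff observed agreement beats chance
  set.seed(20)
  truth <- sample(0:2, 400, TRUE, prob = c(0.5, 0.3, 0.2))
  kaps <- replicate(300, {
    cm <- confusion_matrix(matrix(sample(truth), 20, 20),
                           matrix(truth, 20, 20), k = 3)
    kappa_coefficient(cm)
  })
  expect_true(all(kaps <= 1))
  expect_lt(abs(mean(kaps)), 0.02)
  # sign consistency: kappa > 0 exactly when OA exceeds chance agreement
  set.seed(30)
  for (rep in 1:20) {
    cm <- matrix(sample(0:9, 9, TRUE), 3, 3)
    if (sum(cm) == 0) next
    chance <- sum(rowSums(cm) * colSums(cm)) / sum(cm)^2
    kap <- suppressWarnings(kappa_coefficient(cm))
    if (!is.na(kap) && abs(overall_accuracy(cm) - chance) > 1e-12)
      expect_equal(kap > 0, overall_accuracy(cm) > chance)
  }
  # perfect agreement
  cm <- confusion_matrix(matrix(truth, 20, 20), matrix(truth, 20, 20), k = 3)
  expect_equal(kappa_coefficient(cm), 1)
})

test_that("degenerate matrices are handled as documented", {
  expect_equal(mean_iou(matrix(7, 1, 1)), 1)
  expect_warning(k <- kappa_coefficient(matrix(7, 1, 1)), "degenerate")
  expect_true(is.na(k))
  expect_error(overall_accuracy(matrix(0, 2, 2)), "empty")
  expect_warning(m <- mean_iou(matrix(c(5, 0, 0, 0), 2, 2)), "absent")
  expect_equal(m, 1)
})

test_that("misclassification map is consistent with the confusion matrix", {
  set.seed(21)
  pred <- matrix(sample(0:2, 900, TRUE), 30, 30)
  truth <- matrix(sample(0:2, 900, TRUE), 30, 30)
  mm <- misclassification_map(pred, truth)
  cm <- confusion_matrix(pred, truth, k = 3)
  expect_equal(sum(mm), sum(cm) - sum(diag(cm)))
  expect_true(all(misclassification_map(truth, truth) == 0))
  # on a noiseless straight-boundary scene every error sits at the boundary
  lab <- split_labels(40, 40)
  pred2 <- lab$values
  pred2[, 20] <- 2L  # flip the last left-class column
  mm2 <- misclassification_map(pred2, lab$values)
  zone <- cropseg:::boundary_zone(lab$values, 1L)
  expect_equal(sum(mm2[!zone]), 0)
  expect_equal(sum(mm2), 40)
})

test_that("embedding export is seed-deterministic with the requested size", {
  cfg <- mosaic_config(height = 256, width = 256, plot_size = c(30, 60),
                       seed = 22)
  sim <- simulate_scene(cfg)
  fs <- normalize_stack(build_feature_stack(sim$scene))
  net <- build_segnet(tiny_cfg(), seed = 23)
  spec <- tile_spec(size = 64, margin = 8, count = 2, n_train = 1, n_val = 1)
  e1 <- export_embedding(net, fs, sim$labels, spec = spec, n = 80, seed = 5)
  e2 <- export_embedding(net, fs, sim$labels, spec = spec, n = 80, seed = 5)
  expect_equal(nrow(e1$raw), 80)
  expect_equal(nrow(e1$network), 80)
  expect_identical(e1$raw, e2$raw)
  expect_true(all(e1$raw$class %in% c("corn", "soybean")))
  expect_true(is.finite(e1$silhouette_raw) &&
                is.finite(e1$silhouette_network))
  # asking for more pixels than exist falls back to all, with a warning
  small <- label_raster(matrix(0L, 256, 256))
  small$values[1:4, 1:4] <- 1L
  expect_warning(e3 <- export_embedding(net, fs, small, spec = spec,
                                        n = 50, seed = 1), "available")
  expect_equal(nrow(e3$raw), 16)
})

test_that("identity year shift reproduces in-domain evaluation exactly", {
  cfg <- mosaic_config(height = 256, width = 256, seed = 24)
  sim <- simulate_scene(cfg)
  fs <- build_feature_stack(sim$scene)
  stats <- attr(normalize_stack(fs), "stats")
  net <- build_segnet(tiny_cfg(), seed = 25)
  spec <- tile_spec(size = 64, margin = 8, count = 2, n_train = 1, n_val = 1)
  in_domain <- cross_domain_eval(net, sim$scene, sim$labels, stats, spec = spec)
  shifted <- simulate_year_shift(sim$scene, year_shift(1, 0))
  cross <- cross_domain_eval(net, shifted, sim$labels, stats, spec = spec)
  expect_identical(unclass(in_domain$cm), unclass(cross$cm))
  expect_equal(in_domain$miou, cross$miou)
})
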