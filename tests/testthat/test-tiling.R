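# Train/test splitting, crop sampling, edge-ignoring tiling and stitching.

test_that("tile_spec defaults encode the published sampling protocol", {
  spec <- tile_spec()
  expect_equal(spec$size, 256L)
  expect_equal(spec$count, 800L)
  expect_equal(spec$n_train, 600L)
  expect_equal(spec$n_val, 200L)
  expect_equal(spec$ratio, 0.6)
  expect_error(tile_spec(size = 64, margin = 32), "margin")
  expect_error(tile_spec(count = 10, n_train = 5, n_val = 4), "n_train")
})

test_that("6:4 split puts the boundary at the expected pixel line", {
  sp <- split_train_test(c(1000, 300), ratio = 0.6, axis = "row")
  expect_equal(sp$train$rows, c(1L, 600L))
  expect_equal(sp$test$rows, c(601L, 1000L))
  # exact halves on an even dimension
  sp2 <- split_train_test(c(100, 80), ratio = 0.5, axis = "col")
  expect_equal(sp2$train$cols, c(1L, 40L))
  expect_equal(sp2$test$cols, c(41L, 80L))
  # partition property: disjoint union covering the scene
  cover <- matrix(0L, 100, 80)
  for (r in sp2) cover[r$rows[1]:r$rows[2], r$cols[1]:r$cols[2]] <-
    cover[r$rows[1]:r$rows[2], r$cols[1]:r$cols[2]] + 1L
  expect_true(all(cover == 1L))
})

test_that("training crops are deterministic windows inside the region", {
  set.seed(8)
  feat <- array(rnorm(120 * 150 * 2), c(120, 150, 2))
  lab <- matrix(sample(0:2, 120 * 150, TRUE), 120, 150)
  region <- cropseg:::region_new(c(21, 120), c(1, 130))
  spec <- tile_spec(size = 32, margin = 8, count = 12, n_train = 8, n_val = 4,
                    seed = 42)
  ts <- sample_training_tiles(feat, lab, region, spec)
  expect_length(ts$tiles, 12)
  expect_equal(sum(vapply(ts$tiles, `[[`, "", "role") == "train"), 8)
  for (t in ts$tiles) {
    o <- t$origin
    expect_true(o[1] >= 21 && o[1] + 31 <= 120)
    expect_true(o[2] >= 1 && o[2] + 31 <= 130)
    expect_identical(t$x, feat[o[1]:(o[1] + 31), o[2]:(o[2] + 31), , drop = FALSE])
    expect_identical(t$y, lab[o[1]:(o[1] + 31), o[2]:(o[2] + 31)])
  }
  ts2 <- sample_training_tiles(feat, lab, region, spec)
  expect_identical(lapply(ts$tiles, `[[`, "origin"),
                   lapply(ts2$tiles, `[[`, "origin"))
  expect_error(sample_training_tiles(feat, lab,
                                     cropseg:::region_new(c(1, 20), c(1, 20)),
                                     spec), "smaller than tile")
})

test_that("edge-ignoring layout matches the stride arithmetic", {
  # single-tile degenerate case: whole region from the only tile
  feat <- array(rnorm(256 * 256), c(256, 256, 1))
  region <- cropseg:::region_new(c(1, 256), c(1, 256))
  spec <- tile_spec(size = 256, margin = 32, count = 2, n_train = 1, n_val = 1)
  ts <- tile_test_region(feat, region, spec)
  expect_length(ts$tiles, 1)
  expect_equal(ts$tiles[[1]]$keep$rows, c(1L, 256L))
  expect_equal(ts$tiles[[1]]$keep$cols, c(1L, 256L))

  # 704 rows, size 256, margin 32 -> stride 192 -> ceil((704-256)/192)+1 = 4
  layout <- cropseg:::axis_layout(1L, 704L, 256L, 32L)
  expect_equal(nrow(layout), 4)
  expect_equal(layout$origin[2] - layout$origin[1], 192)
})

test_that("retained central windows cover every pixel exactly once", {
  set.seed(9)
  for (rep in 1:5) {
    H <- sample(70:220, 1); W <- sample(70:220, 1)
    feat <- array(0, c(H, W, 1))
    region <- cropseg:::region_new(c(1, H), c(1, W))
    spec <- tile_spec(size = 64, margin = 8, count = 2, n_train = 1, n_val = 1)
    ts <- tile_test_region(feat, region, spec)
    cover <- matrix(0L, H, W)
    for (t in ts$tiles) {
      kr <- t$keep$rows; kc <- t$keep$cols
      cover[kr[1]:kr[2], kc[1]:kc[2]] <- cover[kr[1]:kr[2], kc[1]:kc[2]] + 1L
      # retained window lies inside the tile
      expect_true(kr[1] >= t$origin[1] && kr[2] <= t$origin[1] + 63)
      expect_true(kc[1] >= t$origin[2] && kc[2] <= t$origin[2] + 63)
    }
    expect_true(all(cover == 1L))
  }
})

test_that("identity predictions stitch back to the original labels", {
  set.seed(10)
  lab <- matrix(sample(0:2, 200 * 140, TRUE), 200, 140)
  feat <- array(0, c(200, 140, 1))
  region <- cropseg:::region_new(c(41, 200), c(11, 140))
  spec <- tile_spec(size = 64, margin = 8, count = 2, n_train = 1, n_val = 1)
  ts <- tile_test_region(feat, region, spec)
  preds <- lapply(ts$tiles, function(t)
    lab[t$origin[1]:(t$origin[1] + 63), t$origin[2]:(t$origin[2] + 63)])
  out <- stitch_predictions(preds, ts)
  expect_identical(out, lab[41:200, 11:140])
})

test_that("conflicting edge predictions resolve to the owning central window", {
  feat <- array(0, c(64, 150, 1))
  region <- cropseg:::region_new(c(1, 64), c(1, 150))
  spec <- tile_spec(size = 64, margin = 8, count = 2, n_train = 1, n_val = 1)
  ts <- tile_test_region(feat, region, spec)
  expect_gt(length(ts$tiles), 1)
  # tile i predicts constant i everywhere; overlaps conflict by construction
  preds <- lapply(seq_along(ts$tiles), function(i) matrix(i, 64, 64))
  out <- stitch_predictions(preds, ts)
  for (i in seq_along(ts$tiles)) {
    kc <- ts$tiles[[i]]$keep$cols
    expect_true(all(out[, kc[1]:kc[2]] == i))
  }
  expect_error(stitch_predictions(preds[-1], ts), "expected")
})
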