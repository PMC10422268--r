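# Feature stack: vegetation indices, stacking order, normalization.

test_that("NDVI follows (NIR - R)/(NIR + R) with safe zero handling", {
  sc <- const_scene(c(0.05, 0.1, 0.1, 0.2, 0.3, 0.5))  # R = 0.1, NIR = 0.5
  expect_equal(compute_ndvi(sc)[1, 1], 0.4 / 0.6)
  sc2 <- const_scene(c(0.05, 0.1, 0.3, 0.2, 0.3, 0.3))  # NIR = R
  expect_true(all(compute_ndvi(sc2) == 0))
  # zero denominator: flagged, finite
  sc3 <- const_scene(c(0, 0, 0, 0, 0, 0))
  nd <- compute_ndvi(sc3)
  expect_true(all(nd == 0))
  expect_true(all(attr(nd, "flagged")))

  set.seed(1)
  arr <- array(runif(16 * 16 * 6), c(16, 16, 6))
  nd <- compute_ndvi(multispectral_scene(arr))
  expect_true(all(nd >= -1 & nd <= 1))
})

test_that("red-edge NDVI equals NDVI applied to substituted bands", {
  sc <- const_scene(c(0.05, 0.1, 0.1, 0.2, 0.4, 0.5))
  expect_equal(compute_rededge_index(sc)[1, 1], 0.2 / 0.6)
  sc2 <- const_scene(c(0.05, 0.1, 0.1, 0.3, 0.3, 0.5))
  expect_true(all(compute_rededge_index(sc2) == 0))

  set.seed(2)
  arr <- array(runif(12 * 12 * 6), c(12, 12, 6))
  sc3 <- multispectral_scene(arr)
  swapped <- arr
  swapped[, , 3] <- arr[, , 4 + 0]  # band4 slot <- band5 values
  swapped[, , 6] <- arr[, , 5]      # band8 slot <- band6 values
  # oracle: red-edge index == NDVI of the swapped scene
  expect_equal(compute_rededge_index(sc3),
               compute_ndvi(multispectral_scene(swapped)),
               ignore_attr = TRUE)
})

test_that("EVI matches hand evaluation and a scalar-loop oracle", {
  sc <- const_scene(c(0.05, 0.1, 0.1, 0.2, 0.3, 0.5))  # B=0.05 R=0.1 NIR=0.5
  expect_equal(compute_evi(sc)[1, 1], 2.5 * 0.4 / (0.5 + 0.6 - 0.375 + 1),
               tolerance = 1e-12)
  expect_equal(compute_evi(sc)[1, 1], 0.5797, tolerance = 1e-4)
  sc2 <- const_scene(c(0.05, 0.1, 0.3, 0.2, 0.3, 0.3))
  expect_true(all(compute_evi(sc2) == 0))

  set.seed(3)
  arr <- array(runif(9 * 7 * 6), c(9, 7, 6))
  sc3 <- multispectral_scene(arr)
  evi <- compute_evi(sc3)
  for (i in 1:9) for (j in 1:7) {
    nir <- arr[i, j, 6]; r <- arr[i, j, 3]; b <- arr[i, j, 1]
    expect_equal(evi[i, j], 2.5 * (nir - r) / (nir + 6 * r - 7.5 * b + 1))
  }
})

test_that("feature stack has 8 channels in the documented order", {
  set.seed(4)
  arr <- array(runif(16 * 16 * 6, 0.05, 0.6), c(16, 16, 6))
  sc <- multispectral_scene(arr)
  fs <- build_feature_stack(sc)
  expect_equal(dim(fs)[3], 8L)
  expect_identical(fs[, , 1], arr[, , 1])           # channel 1 is band 2
  expect_equal(fs[, , 7], compute_ndvi(sc), ignore_attr = TRUE)
  expect_equal(fs[, , 8], compute_rededge_index(sc), ignore_attr = TRUE)
  fe <- build_feature_stack(sc, index_choice = "evi")
  expect_equal(fe[, , 8], compute_evi(sc), ignore_attr = TRUE)
  expect_error(build_feature_stack(
    multispectral_scene(arr[, , 1:3], bands = c("band2", "band3", "band4"))),
    "six raw bands")
})

test_that("indices are invariant under uniform multiplicative band scaling", {
  set.seed(5)
  for (rep in 1:5) {
    arr <- array(runif(6 * 6 * 6, 0.01, 0.5), c(6, 6, 6))
    sc <- multispectral_scene(arr)
    g <- runif(1, 0.5, 1.9)
    scg <- multispectral_scene(pmin(arr * g, 1))
    expect_equal(compute_ndvi(scg), compute_ndvi(sc), ignore_attr = TRUE)
    expect_equal(compute_rededge_index(scg), compute_rededge_index(sc),
                 ignore_attr = TRUE)
  }
})

test_that("normalization: self stats give z-scores, supplied stats are reused", {
  set.seed(6)
  arr <- array(runif(32 * 32 * 6, 0.05, 0.6), c(32, 32, 6))
  fs <- build_feature_stack(multispectral_scene(arr))
  nz <- normalize_stack(fs)
  for (ch in 1:8) {
    expect_equal(mean(nz[, , ch]), 0, tolerance = 1e-10)
    expect_equal(sd(nz[, , ch]), 1, tolerance = 1e-10)
  }
  # idempotence: re-normalizing an already-standardized stack with its own
  # (mean 0, sd 1) statistics changes nothing
  nz2 <- normalize_stack(nz, list(mean = rep(0, 8), sd = rep(1, 8)))
  expect_equal(as.vector(nz2), as.vector(nz))
  # training stats on different data differ from self-normalization
  arr2 <- array(runif(32 * 32 * 6, 0.2, 0.9), c(32, 32, 6))
  fs2 <- build_feature_stack(multispectral_scene(arr2))
  with_train <- normalize_stack(fs2, attr(nz, "stats"))
  self_norm <- normalize_stack(fs2)
  expect_gt(max(abs(with_train - self_norm)), 0.01)
})

test_that("zero-variance channels normalize with a unit divisor and warning", {
  arr <- array(0.3, c(8, 8, 6))
  fs <- build_feature_stack(multispectral_scene(arr))
  expect_warning(nz <- normalize_stack(fs), "zero variance")
  expect_true(all(is.finite(nz)))
})

test_that("resampler utility preserves constant rasters and shapes", {
  m <- matrix(1:24, 4, 6)
  nn <- resample_raster(m, c(8, 12), "nearest")
  expect_equal(dim(nn), c(8L, 12L))
  expect_setequal(unique(as.vector(nn)), as.vector(m))
  bl <- resample_raster(matrix(5, 4, 4), c(9, 3), "bilinear")
  expect_equal(max(abs(bl - 5)), 0, tolerance = 1e-12)
})
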