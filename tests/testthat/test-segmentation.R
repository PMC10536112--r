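test_that("tiling a 620x476 image follows the flush-anchor grid", {
  img <- matrix(0, 476, 620)
  msk <- matrix(0, 476, 620)
  tiles <- tile_image(img, msk, 160, 160)
  offs <- t(vapply(tiles, function(t) t$offset, c(row = 0L, col = 0L)))
  expect_equal(sort(unique(offs[, "col"])), c(0, 160, 320, 460))
  expect_equal(sort(unique(offs[, "row"])), c(0, 160, 316))
  expect_length(tiles, 12)
  # full coverage
  cov <- matrix(0, 476, 620)
  for (t in tiles) cov[t$offset["row"] + 1:160, t$offset["col"] + 1:160] <- 1
  expect_true(all(cov == 1))
})

test_that("tiling degenerate and strided cases follow the grid arithmetic", {
  img <- matrix(runif(160 * 160, 0, 255), 160, 160)
  tiles <- tile_image(img, matrix(1, 160, 160))
  expect_length(tiles, 1)
  expect_equal(unname(tiles[[1]]$offset), c(0, 0))
  expect_equal(tiles[[1]]$image, img / 255)
  expect_true(all(tiles[[1]]$image >= 0 & tiles[[1]]$image <= 1))
  # stride 80 on a 320x160 image: 3 column anchors
  wide <- matrix(0, 160, 320)
  t3 <- tile_image(wide, matrix(1, 160, 320), 160, 80)
  expect_equal(sort(vapply(t3, function(t) t$offset[["col"]], 0L)),
               c(0L, 80L, 160L))
  expect_error(tile_image(matrix(0, 100, 100), NULL, 160), "smaller")
})

test_that("the sparse-mask filter keeps tiles at or above 200 white pixels", {
  mk <- function(n) {
    m <- matrix(0, 160, 160); if (n > 0) m[seq_len(n)] <- 1
    list(image = matrix(0.5, 160, 160), mask = m, source_id = "x",
         offset = c(row = 0L, col = 0L), rotation = 0,
         white_pixels = as.integer(n))
  }
  tiles <- lapply(c(0, 199, 200, 5000), mk)
  kept <- filter_sparse_tiles(tiles, 200)
  expect_length(kept, 2)
  expect_equal(vapply(kept, function(t) t$white_pixels, 0L), c(200L, 5000L))
  # monotone non-increasing in the threshold
  counts <- vapply(c(0, 100, 200, 1000, 10000),
                   function(tl) length(filter_sparse_tiles(tiles, tl)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("rotation augmentation behaves geometrically", {
  set.seed(23)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  msk <- matrix(0, 64, 64); msk[10:20, 30:50] <- 1
  expect_error(augment_rotations(img, msk, c(90, 360)), "strictly inside")
  # k equally spaced angles -> k pairs plus the original
  aug <- augment_rotations(img, msk, rotation_angles(3))
  expect_length(aug, 4)
  expect_equal(vapply(aug, function(a) a$rotation, 0), c(0, 90, 180, 270))
  # 180-degree rotation of the mask equals its point reflection
  m180 <- aug[[3]]$mask
  expect_gt(sum(m180 * msk[64:1, 64:1]) / sum(msk | m180[64:1, 64:1]), 0.95)
  # rotation then inverse rotation recovers the mask within a boundary band
  fwd <- augment_rotations(img, msk, 33)[[2]]
  back <- (rotate_image(fwd$mask, -33, bilinear = FALSE) >= 0.5) + 0
  mism <- which(back != msk, arr.ind = TRUE)
  if (nrow(mism) > 0) {
    # every mismatching pixel lies within 1.5 px of the mask boundary
    bnd <- which(msk == 1, arr.ind = TRUE)
    for (q in seq_len(nrow(mism))) {
      d <- sqrt(min((mism[q, 1] - bnd[, 1])^2 + (mism[q, 2] - bnd[, 2])^2))
      expect_lt(d, 2.5)
    }
  }
  expect_true(all(fwd$mask %in% c(0, 1)))
})

test_that("class weights are inverse-frequency with the minority up-weighted", {
  mk <- function(nwhite) {
    m <- matrix(0, 160, 160); m[seq_len(nwhite)] <- 1
    list(image = matrix(0, 160, 160), mask = m, source_id = "x",
         offset = c(row = 0L, col = 0L), rotation = 0,
         white_pixels = as.integer(nwhite))
  }
  # balanced: both weights 1
  w <- compute_class_weights(list(mk(160 * 160 / 2)))
  expect_equal(unname(w), c(1, 1))
  # 90% black / 10% white -> (0.556, 5.0)
  w2 <- compute_class_weights(list(mk(160 * 160 / 10)))
  expect_equal(unname(w2), c(1 / 1.8, 5), tolerance = 1e-12)
  expect_equal(unname(w2[2] / w2[1]), 9, tolerance = 1e-12)
  expect_error(compute_class_weights(list(mk(160 * 160))), "degenerate")
  expect_error(compute_class_weights(list(mk(0))), "degenerate")
})

test_that("the network honours its shape contract", {
  spec <- network_spec(c(4, 8, 12, 16), input_size = 32)
  expect_error(network_spec(c(4, 8, 12, 16), input_size = 50), "divisible")
  net <- build_network(spec, seed = 1)
  p <- capiflow:::.cpp_unet_forward(net$params, matrix(0, 32, 32),
                                    spec$encoder_filters)
  expect_equal(dim(p), c(32, 32))
  expect_true(all(p >= 0 & p <= 1))
  # reproducible initialization
  net2 <- build_network(spec, seed = 1)
  expect_identical(net$params, net2$params)
  expect_false(identical(net$params, build_network(spec, seed = 2)$params))
})

test_that("training reduces the loss and prediction is binary at input size", {
  set.seed(31)
  spec <- network_spec(c(4, 8, 12, 16), input_size = 32)
  # trivial separable task: dark blob = foreground
  mk_tile <- function() {
    m <- matrix(0, 32, 32)
    ci <- sample(8:24, 1); cj <- sample(8:24, 1)
    m[pmax(1, ci - 4):pmin(32, ci + 4), pmax(1, cj - 4):pmin(32, cj + 4)] <- 1
    img <- matrix(0.8, 32, 32) + matrix(rnorm(1024, 0, 0.02), 32, 32)
    img[m == 1] <- img[m == 1] - 0.4
    list(image = pmin(pmax(img, 0), 1), mask = m, source_id = "s",
         offset = c(row = 0L, col = 0L), rotation = 0,
         white_pixels = as.integer(sum(m)))
  }
  tiles <- replicate(10, mk_tile(), simplify = FALSE)
  net <- build_network(spec, seed = 4)
  fit <- train_network(net, tiles[1:8], tiles[9:10],
                       training_config(epochs = 4, seed = 9))
  expect_true(fit$trained)
  expect_lt(fit$history$val_loss[4], fit$history$val_loss[1])
  pred <- predict_mask(fit, matrix(200, 64, 64), stride = 32)
  expect_equal(dim(pred), c(64, 64))
  expect_true(all(pred %in% c(0, 1)))
  expect_error(predict_mask(build_network(spec), matrix(0, 32, 32)),
               "untrained")
})

test_that("overlapping tile predictions merge by averaging foreground probability", {
  spec <- network_spec(c(4, 8, 12, 16), input_size = 32)
  net <- build_network(spec, seed = 5)
  net$trained <- TRUE
  img <- matrix(runif(32 * 64, 0, 255), 32, 64)
  pred <- predict_mask(net, img, stride = 16)
  prob <- attr(pred, "probability")
  # manual merge oracle at a pixel covered by two tiles
  offs <- tile_offsets(64, 32, 16)
  tile_probs <- lapply(offs, function(o)
    capiflow:::.cpp_unet_forward(net$params, img[, o + 1:32] / 255,
                                 spec$encoder_filters))
  # column 40 (0-based 39) covered by tiles at offsets 8,16,24,32 ... find them
  j <- 40
  covering <- which(vapply(offs, function(o) j > o & j <= o + 32, TRUE))
  vals <- vapply(covering, function(ci) tile_probs[[ci]][10, j - offs[ci]], 0)
  expect_equal(prob[10, j], mean(vals), tolerance = 1e-12)
  expect_equal(unname(pred[10, j]), as.numeric(mean(vals) > 0.5))
})

test_that("LOOCV excludes every held-out tile from its training fold", {
  sp <- phantom_spec(width = 96, height = 96, n_frames = 1, n_vessels = 2,
                     vessel_width = c(3, 5), blob_features = 5, seed = 77)
  ds <- phantom_dataset(sp, n_images = 3)
  td <- prepare_tiles(ds$images, ds$masks, ds$ids, angles = rotation_angles(1),
                      tile_size = 32, stride = 32, min_white = 20)
  expect_gte(length(td$tiles), 6)
  res <- train_loocv(td, ds$images, ds$masks,
                     spec = network_spec(c(2, 4, 6, 8), input_size = 32),
                     cfg = training_config(epochs = 1, seed = 2))
  expect_length(res, 3)
  for (f in seq_along(res)) {
    held <- res[[f]]$held_out_id
    expect_false(held %in% td$manifest$source_id[res[[f]]$train_tiles])
    expect_true(all(td$manifest$source_id[res[[f]]$val_tiles] == held))
    expect_setequal(c(res[[f]]$train_tiles, res[[f]]$val_tiles),
                    seq_along(td$tiles))
    expect_equal(dim(res[[f]]$predicted_mask), dim(ds$images[[f]]))
  }
  agg <- attr(res, "aggregate")
  expect_true(is.finite(agg$mean["jaccard"]))
})
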