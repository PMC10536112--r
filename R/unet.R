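# R-side surface of the encoder-decoder segmentation network: architecture
# specification, parameter initialization, Adam training with per-class
# loss weights and min-validation-loss checkpointing, leave-one-out
# cross-validation, and tiled full-image prediction.

#' Segmentation network architecture specification
#'
#' Four contracting blocks (two 3x3 convolutions + ReLU each, 2x2 max
#' pooling between levels), a mirrored expanding path with 2x2
#' up-convolutions and skip concatenations, and a final 1x1 convolution to
#' two per-pixel class scores, so the output has the spatial dimensions of
#' the input. The input side must be divisible by 8 (three poolings).
#'
#' @param encoder_filters filter counts of the four contracting blocks.
#' @param input_size tile side in pixels.
#' @return list of class `network_spec`.
#' @export
network_spec <- function(encoder_filters = c(32, 64, 128, 256),
                         input_size = 160) {
  stopifnot(length(encoder_filters) == 4, all(encoder_filters >= 1))
  if (input_size %% 8 != 0)
    stop("input size must be divisible by 2^(blocks - 1) = 8")
  structure(list(encoder_filters = as.integer(encoder_filters),
                 input_size = as.integer(input_size)),
            class = "network_spec")
}

#' Training configuration
#'
#' @param epochs training epochs (default 20).
#' @param learning_rate Adam step size.
#' @param class_weights per-class loss weights `c(background, capillary)`;
#'   `NULL` derives inverse-frequency weights from the training tiles.
#' @param seed master seed for initialization and shuffling.
#' @return list of class `training_config`.
#' @export
training_config <- function(epochs = 20, learning_rate = 1e-3,
                            class_weights = NULL, seed = 1) {
  stopifnot(epochs >= 1, learning_rate > 0)
  if (!is.null(class_weights))
    stopifnot(length(class_weights) == 2, all(is.finite(class_weights)),
              all(class_weights > 0))
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 class_weights = class_weights, seed = seed),
            class = "training_config")
}

#' Build (initialize) a segmentation network
#'
#' He-normal weight initialization, zero biases; reproducible given `seed`.
#'
#' @param spec [network_spec].
#' @param seed RNG seed for the initialization.
#' @return list of class `capiflow_unet` with fields `params` (flat
#'   parameter vector), `spec`, and `trained` (FALSE until fitted).
#' @export
build_network <- function(spec = network_spec(), seed = 1) {
  layout <- .cpp_unet_layout(spec$encoder_filters)
  with_preserved_rng({
    set.seed(seed)
    params <- numeric(sum(layout$wsize + layout$bsize))
    off <- 0
    for (l in seq_len(nrow(layout))) {
      fan_in <- layout$k[l]^2 * layout$cin[l]
      params[off + seq_len(layout$wsize[l])] <-
        rnorm(layout$wsize[l], 0, sqrt(2 / fan_in))
      off <- off + layout$wsize[l] + layout$bsize[l]  # biases stay 0
    }
    structure(list(params = params, spec = spec, trained = FALSE),
              class = "capiflow_unet")
  })
}

#' @export
print.capiflow_unet <- function(x, ...) {
  cat(sprintf("capiflow_unet: filters (%s), input %dx%d, %d parameters%s\n",
              paste(x$spec$encoder_filters, collapse = ", "),
              x$spec$input_size, x$spec$input_size, length(x$params),
              if (isTRUE(x$trained)) ", trained" else ", untrained"))
  invisible(x)
}

tile_loss <- function(params, tile, clsw, filters) {
  .cpp_unet_loss_grad(params, tile$image, tile$mask, clsw, filters, FALSE)$loss
}

#' Train the segmentation network on tiles
#'
#' Adam optimization of the per-pixel class-weighted softmax cross-entropy,
#' one tile per step, shuffled each epoch. After every epoch the mean loss
#' on the validation tiles is computed and the parameters achieving the
#' minimum validation loss are kept as the checkpoint (training still runs
#' all epochs).
#'
#' @param model `capiflow_unet` from [build_network()].
#' @param train_tiles,val_tiles lists of tiles (with masks).
#' @param cfg [training_config].
#' @return trained `capiflow_unet` with fields `history` (data.frame of
#'   epoch losses), `best_epoch`, and `class_weights`.
#' @export
train_network <- function(model, train_tiles, val_tiles, cfg = training_config()) {
  if (length(train_tiles) == 0) stop("empty training tile set")
  if (length(val_tiles) == 0) stop("empty validation tile set")
  clsw <- cfg$class_weights
  if (is.null(clsw)) clsw <- compute_class_weights(train_tiles)
  filters <- model$spec$encoder_filters
  with_preserved_rng({
    set.seed(cfg$seed)
    p <- model$params
    m <- numeric(length(p)); v <- numeric(length(p))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
    best <- Inf; best_p <- p; best_epoch <- NA_integer_
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric())
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(length(train_tiles))
      tl <- 0
      for (i in ord) {
        g <- .cpp_unet_loss_grad(p, train_tiles[[i]]$image,
                                 train_tiles[[i]]$mask, clsw, filters, TRUE)
        t <- t + 1
        m <- b1 * m + (1 - b1) * g$grad
        v <- b2 * v + (1 - b2) * g$grad^2
        p <- p - cfg$learning_rate * (m / (1 - b1^t)) /
          (sqrt(v / (1 - b2^t)) + eps)
        tl <- tl + g$loss
      }
      vl <- mean(vapply(val_tiles, function(tt)
        tile_loss(p, tt, clsw, filters), 0))
      hist <- rbind(hist, data.frame(epoch = ep,
                                     train_loss = tl / length(train_tiles),
                                     val_loss = vl))
      if (vl < best) { best <- vl; best_p <- p; best_epoch <- ep }
    }
    model$params <- best_p
    model$trained <- TRUE
    model$history <- hist
    model$best_epoch <- best_epoch
    model$class_weights <- clsw
    model
  })
}

#' Predict a binary capillary mask for a full image
#'
#' The image is tiled exactly as in [tile_image()] (flush-anchored grid);
#' per-tile foreground probabilities are predicted, overlapping tile
#' predictions are merged by averaging the foreground probability, and the
#' merged map is binarized at 0.5 (arg-max of the two classes).
#'
#' @param model trained `capiflow_unet`.
#' @param image intensity matrix in \[0, 255\], at least tile-sized.
#' @param stride tiling stride (defaults to the tile size).
#' @return 0/1 mask matrix of the image's dimensions; the merged foreground
#'   probability map is attached as attribute `"probability"`.
#' @export
predict_mask <- function(model, image, stride = model$spec$input_size) {
  if (!isTRUE(model$trained)) stop("model is untrained")
  ts <- model$spec$input_size
  tiles <- tile_image(image, NULL, ts, stride)
  acc <- matrix(0, nrow(image), ncol(image))
  cnt <- matrix(0, nrow(image), ncol(image))
  for (t in tiles) {
    pr <- .cpp_unet_forward(model$params, t$image, model$spec$encoder_filters)
    ri <- t$offset["row"] + seq_len(ts); ci <- t$offset["col"] + seq_len(ts)
    acc[ri, ci] <- acc[ri, ci] + pr
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  prob <- acc / cnt
  mask <- (prob > 0.5) + 0
  attr(mask, "probability") <- prob
  mask
}

#' Leave-one-out cross-validation over source images
#'
#' One training per source image: all tiles derived from the held-out image
#' (augmentations included) are excluded from that fold's training set and
#' serve as the validation set; the checkpoint at minimum validation loss
#' predicts the held-out full image, which is scored against its
#' ground-truth mask. Per-fold seeds are derived deterministically from
#' `cfg$seed`.
#'
#' @param dataset `tile_dataset` from [prepare_tiles()].
#' @param images,masks full-size source images and ground-truth masks
#'   (parallel to `dataset$ids`).
#' @param spec [network_spec].
#' @param cfg [training_config].
#' @return list of fold results (class `loocv_result`), each with
#'   `held_out_id`, `predicted_mask`, `metrics` ([report()]), `best_epoch`,
#'   and `history`; the cross-fold aggregate from [aggregate_folds()] is
#'   attached as attribute `"aggregate"`.
#' @export
train_loocv <- function(dataset, images, masks, spec = network_spec(),
                        cfg = training_config()) {
  ids <- dataset$ids
  if (length(ids) < 2) stop("need at least 2 source images for LOOCV")
  src <- dataset$manifest$source_id
  folds <- vector("list", length(ids))
  for (f in seq_along(ids)) {
    held <- ids[f]
    tr <- dataset$tiles[src != held]
    va <- dataset$tiles[src == held]
    if (length(tr) == 0 || length(va) == 0)
      stop("fold with empty training or validation tile set: ", held)
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + f
    model <- build_network(spec, seed = cfg$seed + 1000 + f)
    model <- train_network(model, tr, va, fold_cfg)
    pred <- predict_mask(model, images[[f]])
    folds[[f]] <- structure(list(held_out_id = held,
                                 predicted_mask = pred,
                                 metrics = evaluate_masks(pred, masks[[f]]),
                                 best_epoch = model$best_epoch,
                                 history = model$history,
                                 model = model,
                                 train_tiles = which(src != held),
                                 val_tiles = which(src == held)),
                            class = "loocv_fold")
  }
  attr(folds, "aggregate") <- aggregate_folds(folds)
  class(folds) <- "loocv_result"
  folds
}

#' @export
print.loocv_result <- function(x, ...) {
  agg <- attr(x, "aggregate")
  cat(sprintf("loocv_result: %d fold(s); mean Jaccard %.4f, mean accuracy %.4f\n",
              length(x), agg$mean["jaccard"], agg$mean["accuracy"]))
  invisible(x)
}
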