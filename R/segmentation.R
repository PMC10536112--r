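# Tile-dataset preparation and leave-one-out training orchestration for the
# encoder-decoder capillary segmenter. Images are rotated for augmentation,
# cut into 160x160 tiles on a flush-anchored grid, and tiles whose mask
# carries fewer than 200 white pixels are discarded as uninformative.

#' Tile offsets along one dimension
#'
#' Regular grid with the given stride starting at 0; a final offset flush
#' with the border is appended so the tiles cover the full extent (possible
#' overlap of the last tile).
#'
#' @param extent image extent in pixels.
#' @param size tile size.
#' @param stride grid stride.
#' @return integer vector of 0-based offsets.
#' @export
tile_offsets <- function(extent, size, stride) {
  if (extent < size) stop("image smaller than tile size")
  off <- seq(0, extent - size, by = stride)
  if (off[length(off)] + size < extent) off <- c(off, extent - size)
  as.integer(off)
}

#' Cut an image/mask pair into tiles
#'
#' Tiles are cut on a regular grid (top-left anchored, given stride) with a
#' final row/column flush with the border, guaranteeing full coverage of
#' images whose size is not a multiple of the tile size. Tile images are
#' scaled to \[0, 1\].
#'
#' @param image intensity matrix in \[0, 255\].
#' @param mask 0/1 matrix of the same size (optional: `NULL` for
#'   prediction-time tiling).
#' @param tile_size tile side in pixels.
#' @param stride grid stride (defaults to `tile_size`: non-overlapping
#'   interior grid).
#' @param source_id identifier of the parent image.
#' @param rotation augmentation angle recorded on each tile.
#' @return list of tiles; each tile is a list with `image` (\[0, 1\]
#'   matrix), `mask` (0/1 matrix or `NULL`), `source_id`, `offset`
#'   (0-based row/col of the top-left corner), `rotation`, and
#'   `white_pixels`.
#' @export
tile_image <- function(image, mask = NULL, tile_size = 160,
                       stride = tile_size, source_id = "image",
                       rotation = 0) {
  if (!is.null(mask) && !identical(dim(image), dim(mask)))
    stop("image and mask dimensions differ")
  rows <- tile_offsets(nrow(image), tile_size, stride)
  cols <- tile_offsets(ncol(image), tile_size, stride)
  tiles <- list()
  for (r in rows) for (cc in cols) {
    ri <- r + seq_len(tile_size); ci <- cc + seq_len(tile_size)
    mt <- if (is.null(mask)) NULL else mask[ri, ci]
    tiles[[length(tiles) + 1]] <- list(
      image = image[ri, ci] / 255, mask = mt, source_id = source_id,
      offset = c(row = r, col = cc), rotation = rotation,
      white_pixels = if (is.null(mt)) NA_integer_ else as.integer(sum(mt)))
  }
  tiles
}

#' Rotation augmentation of an image/mask pair
#'
#' Each pair is rotated about the image center by every requested angle;
#' the image is interpolated bilinearly, the mask by nearest neighbour and
#' re-binarized; uncovered corners are filled with background (0). The
#' original (unrotated) pair is returned first.
#'
#' @param image intensity matrix.
#' @param mask 0/1 matrix.
#' @param angles rotation angles in degrees, each strictly inside
#'   (0, 360).
#' @return list of `(image, mask, rotation)` triples: the original plus one
#'   per angle.
#' @export
augment_rotations <- function(image, mask, angles) {
  if (length(angles) && any(angles <= 0 | angles >= 360))
    stop("angles must lie strictly inside (0, 360)")
  out <- list(list(image = image, mask = mask, rotation = 0))
  for (a in angles) {
    out[[length(out) + 1]] <- list(
      image = rotate_image(image, a, bilinear = TRUE, fill = 0),
      mask = (rotate_image(mask, a, bilinear = FALSE, fill = 0) >= 0.5) + 0,
      rotation = a)
  }
  out
}

#' Equally spaced augmentation angles inside (0, 360)
#'
#' @param k number of angles.
#' @return numeric vector, e.g. `k = 3` gives 90, 180, 270.
#' @export
rotation_angles <- function(k) {
  if (k <= 0) return(numeric())
  360 * seq_len(k) / (k + 1)
}

#' Drop tiles with sparse masks
#'
#' Retains tiles whose mask contains at least `min_white` white pixels
#' (the rule is "fewer than `min_white` are removed", so a tile with
#' exactly `min_white` is kept).
#'
#' @param tiles list of tiles from [tile_image()].
#' @param min_white threshold (default 200).
#' @return filtered tile list.
#' @export
filter_sparse_tiles <- function(tiles, min_white = 200) {
  Filter(function(t) !is.na(t$white_pixels) && t$white_pixels >= min_white,
         tiles)
}

#' Build the training tile dataset for a set of source images
#'
#' For every source image, the image/mask pair is rotated by the
#' augmentation angles (original included), every rotated pair is cut into
#' tiles, and sparse-mask tiles are removed — in that order.
#'
#' @param images,masks,ids parallel lists as returned by
#'   [phantom_dataset()].
#' @param angles augmentation angles (degrees), e.g. [rotation_angles()].
#' @param tile_size,stride tiling geometry.
#' @param min_white sparse-mask threshold.
#' @return list of class `tile_dataset` with fields `tiles`, `manifest`
#'   (data.frame: tile, source_id, offset_row, offset_col, rotation,
#'   white_pixels), and the preparation parameters.
#' @export
prepare_tiles <- function(images, masks, ids = NULL, angles = numeric(),
                          tile_size = 160, stride = tile_size,
                          min_white = 200) {
  if (is.null(ids)) ids <- sprintf("image_%03d", seq_along(images))
  tiles <- list()
  for (i in seq_along(images)) {
    for (pair in augment_rotations(images[[i]], masks[[i]], angles)) {
      tt <- tile_image(pair$image, pair$mask, tile_size, stride,
                       source_id = ids[i], rotation = pair$rotation)
      tiles <- c(tiles, tt)
    }
  }
  tiles <- filter_sparse_tiles(tiles, min_white)
  manifest <- data.frame(
    tile = seq_along(tiles),
    source_id = vapply(tiles, function(t) t$source_id, ""),
    offset_row = vapply(tiles, function(t) t$offset["row"], 0L),
    offset_col = vapply(tiles, function(t) t$offset["col"], 0L),
    rotation = vapply(tiles, function(t) t$rotation, 0),
    white_pixels = vapply(tiles, function(t) t$white_pixels, 0L))
  structure(list(tiles = tiles, manifest = manifest, tile_size = tile_size,
                 stride = stride, min_white = min_white, angles = angles,
                 ids = ids),
            class = "tile_dataset")
}

#' @export
print.tile_dataset <- function(x, ...) {
  cat(sprintf("tile_dataset: %d tile(s) from %d source image(s), %dx%d px\n",
              length(x$tiles), length(unique(x$manifest$source_id)),
              x$tile_size, x$tile_size))
  invisible(x)
}

#' Inverse-frequency class weights from a tile dataset
#'
#' `w_c = total_pixels / (2 * count_c)` for background (black) and
#' capillary (white): the minority class receives the larger weight,
#' compensating the strong class imbalance of capillary masks.
#'
#' @param dataset `tile_dataset` (or plain list of tiles with masks).
#' @return numeric vector `c(background, capillary)`.
#' @export
compute_class_weights <- function(dataset) {
  tiles <- if (inherits(dataset, "tile_dataset")) dataset$tiles else dataset
  if (length(tiles) == 0) stop("empty dataset")
  white <- sum(vapply(tiles, function(t) sum(t$mask), 0))
  total <- sum(vapply(tiles, function(t) length(t$mask), 0))
  black <- total - white
  if (white == 0 || black == 0)
    stop("degenerate dataset: a class has zero pixels")
  c(background = total / (2 * black), capillary = total / (2 * white))
}
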