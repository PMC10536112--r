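#' Construct a frame sequence
#'
#' A frame sequence is the working representation of a capillaroscopy video:
#' an ordered list of equally sized 8-bit grayscale frames (numeric matrices
#' with values in \[0, 255\], row = image row, column = image column, origin
#' top-left) plus the acquisition frame rate. Frames are indexed 0-based in
#' all user-facing arguments, matching the temporal index k of the
#' enhancement equations.
#'
#' @param frames list of numeric matrices with identical dimensions, values
#'   in \[0, 255\].
#' @param frame_rate frames per second; the acquisition default is 120.
#' @param validity optional list of 0/1 matrices marking which pixels carry
#'   real image content (warped frames have invalid borders). `NULL` means
#'   all pixels valid.
#' @return an object of class `frame_sequence` with fields `frames`,
#'   `frame_rate`, `validity`, and `n` (frame count).
#' @export
frame_sequence <- function(frames, frame_rate = 120, validity = NULL) {
  if (!is.list(frames) || length(frames) == 0)
    stop("`frames` must be a non-empty list of matrices")
  dims <- lapply(frames, dim)
  if (any(vapply(frames, function(f) !is.matrix(f) || !is.numeric(f), TRUE)))
    stop("every frame must be a numeric matrix")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all frames must share identical dimensions")
  rng <- range(unlist(lapply(frames, range)))
  if (rng[1] < 0 || rng[2] > 255)
    stop("frame intensities must lie in [0, 255]")
  if (!is.null(validity)) {
    if (length(validity) != length(frames))
      stop("`validity` must have one mask per frame")
    ok <- vapply(validity, function(v) identical(dim(v), dim(frames[[1]])), TRUE)
    if (!all(ok)) stop("validity masks must match frame dimensions")
  }
  structure(list(frames = frames, frame_rate = frame_rate,
                 validity = validity, n = length(frames)),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("frame_sequence: %d frame(s), %d x %d px, %g fps%s\n",
              x$n, d[1], d[2], x$frame_rate,
              if (is.null(x$validity)) "" else ", with validity masks"))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) x$n

seq_dims <- function(seq) dim(seq$frames[[1]])

validity_or_ones <- function(seq, k1) {
  if (is.null(seq$validity)) array(1, dim = seq_dims(seq))
  else seq$validity[[k1]]
}

#' Convert an image array to the 8-bit grayscale working representation
#'
#' Color inputs are reduced to a single channel by Rec. 601 luminance
#' weighting (0.299 R + 0.587 G + 0.114 B); an already-gray multi-channel
#' image (all channels identical) is reduced exactly to its first channel.
#' Values are rescaled from the \[0, 1\] decoder range to \[0, 255\].
#'
#' @param img numeric matrix or H x W x C array with values in \[0, 1\]
#'   (as returned by the PNG/TIFF readers).
#' @return numeric matrix with values in \[0, 255\].
#' @export
to_gray <- function(img) {
  if (is.matrix(img)) return(round(img * 255))
  if (length(dim(img)) == 3) {
    ch <- dim(img)[3]
    if (ch >= 3) {
      if (identical(img[, , 1], img[, , 2]) && identical(img[, , 1], img[, , 3]))
        g <- img[, , 1]
      else
        g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      g <- img[, , 1]
    }
    return(round(g * 255))
  }
  stop("unsupported image array layout")
}

read_one_image <- function(f) {
  ext <- tolower(tools::file_ext(f))
  img <- switch(ext,
                png = png::readPNG(f),
                tif = ,
                tiff = tiff::readTIFF(f),
                stop("unsupported image format: ", ext))
  to_gray(img)
}

#' Read a frame sequence from disk
#'
#' The canonical exchange format is a directory of lexicographically ordered
#' 8-bit grayscale PNG or TIFF files (deterministic and codec-free). Video
#' containers are not decodable with the pure-raster backends used here and
#' raise an error directing the user to extract frames first.
#'
#' @param path directory containing the image files.
#' @param kind `"directory"` (default) or `"video"` (unsupported).
#' @param frame_rate frames per second recorded in the returned sequence.
#' @return a [frame_sequence].
#' @export
read_sequence <- function(path, kind = c("directory", "video"),
                          frame_rate = 120) {
  kind <- match.arg(kind)
  if (kind == "video")
    stop("video-container ingestion is not supported; extract frames to an ",
         "image-sequence directory (PNG/TIFF) first")
  if (!dir.exists(path)) stop("path does not exist: ", path)
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  files <- files[order(basename(files), method = "radix")]
  if (length(files) == 0) stop("no decodable frames found in ", path)
  frames <- lapply(files, read_one_image)
  frame_sequence(frames, frame_rate = frame_rate)
}

#' Write a frame sequence to disk
#'
#' Frames are written as zero-padded, lexicographically ordered 8-bit
#' grayscale images so that [read_sequence()] round-trips pixel values
#' exactly.
#'
#' @param seq a [frame_sequence].
#' @param path output directory (created if missing).
#' @param format `"png"` or `"tiff"`.
#' @param prefix file-name prefix.
#' @return invisibly, the written file paths.
#' @export
write_sequence <- function(seq, path, format = c("png", "tiff"),
                           prefix = "frame") {
  format <- match.arg(format)
  if (!inherits(seq, "frame_sequence")) stop("`seq` must be a frame_sequence")
  if (seq$n < 1) stop("cannot write an empty sequence")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  paths <- character(seq$n)
  for (k in seq_len(seq$n)) {
    f <- file.path(path, sprintf("%s_%05d.%s", prefix, k - 1,
                                 if (format == "png") "png" else "tif"))
    img <- round(seq$frames[[k]]) / 255
    if (format == "png") png::writePNG(img, f, dpi = NULL)
    else tiff::writeTIFF(img, f, bits.per.sample = 8)
    paths[k] <- f
  }
  invisible(paths)
}

#' Read a binary capillary mask
#'
#' Masks are stored on disk as 0/255 8-bit PNG (white = capillary) and held
#' in memory as 0/1 matrices.
#'
#' @param path PNG file.
#' @return 0/1 integer-valued matrix.
#' @export
read_mask <- function(path) {
  m <- read_one_image(path)
  (m > 127) + 0
}

#' Write a binary capillary mask
#'
#' @param mask 0/1 matrix (white = capillary).
#' @param path output PNG file.
#' @export
write_mask <- function(mask, path) {
  if (!all(mask %in% c(0, 1))) stop("mask values must be strictly {0, 1}")
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  png::writePNG(mask + 0, path)  # + 0: integer masks to doubles for the encoder
  invisible(path)
}
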