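# Multi-scale blob keypoint detection in the SURF family: scale-normalized
# determinant-of-Hessian responses, 3x3 spatial non-maximum suppression per
# scale, quadratic subpixel refinement, and upright 64-D gradient-grid
# descriptors. The response threshold plays the role of the detector's
# "Hessian threshold" and is the quantity lowered by the iterative
# detection loop of the stabilization module.

DETECTOR_SIGMAS <- 1.2 * 1.4^(0:3)

# Calibration of the determinant-of-Hessian response onto the customary
# Hessian-threshold scale of box-filter blob detectors on 8-bit images,
# where clear high-contrast blobs score in the 10^4..10^5 range and useful
# thresholds sit around 10^2..10^3. Gaussian-derivative responses
# sigma^4 (Lxx Lyy - Lxy^2) on the same content are roughly this factor
# smaller; without it a threshold of 1000 would reject all but the very
# strongest blobs and force the iterative detection loop to the floor.
DETECTOR_RESPONSE_SCALE <- 25

shift_mat <- function(m, di, dj) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(-Inf, H, W)
  si <- max(1, 1 - di):min(H, H - di)
  sj <- max(1, 1 - dj):min(W, W - dj)
  out[si, sj] <- m[si + di, sj + dj]
  out
}

#' Compute multi-scale determinant-of-Hessian responses for a frame
#'
#' Returns one scale-normalized response map per detection scale together
#' with the full list of candidate keypoints (strict 3x3 spatial local
#' maxima with positive response, subpixel-refined and deduplicated across
#' scales, sorted by decreasing response). Candidates are
#' threshold-independent, so the iterative detection loop of the
#' stabilization module re-thresholds this cache instead of re-detecting.
#'
#' @param frame numeric matrix, intensities in \[0, 255\].
#' @param sigmas detection scales (Gaussian sigma in pixels).
#' @return list with `responses` (list of matrices), `sigmas`, and
#'   `candidates` (data.frame: `x`, `y`, `scale`, `response`).
#' @export
doh_responses <- function(frame, sigmas = DETECTOR_SIGMAS) {
  H <- nrow(frame); W <- ncol(frame)
  resp <- lapply(sigmas, function(s) {
    G <- .cpp_gaussian_blur(frame, s)
    Lrr <- rbind(G[1, , drop = FALSE], G[-H, , drop = FALSE]) -
      2 * G + rbind(G[-1, , drop = FALSE], G[H, , drop = FALSE])
    Lcc <- cbind(G[, 1, drop = FALSE], G[, -W, drop = FALSE]) -
      2 * G + cbind(G[, -1, drop = FALSE], G[, W, drop = FALSE])
    up <- rbind(G[1, , drop = FALSE], G[-H, , drop = FALSE])
    dn <- rbind(G[-1, , drop = FALSE], G[H, , drop = FALSE])
    Lrc <- (cbind(dn[, -1, drop = FALSE], dn[, W, drop = FALSE]) +
              cbind(up[, 1, drop = FALSE], up[, -W, drop = FALSE]) -
              cbind(dn[, 1, drop = FALSE], dn[, -W, drop = FALSE]) -
              cbind(up[, -1, drop = FALSE], up[, W, drop = FALSE])) / 4
    DETECTOR_RESPONSE_SCALE * s^4 * (Lrr * Lcc - Lrc^2)
  })
  out <- list(responses = resp, sigmas = sigmas)
  out$candidates <- find_candidates(out)
  out
}

find_candidates <- function(resp) {
  border <- 2
  out <- list()
  for (si in seq_along(resp$sigmas)) {
    R <- resp$responses[[si]]
    H <- nrow(R); W <- ncol(R)
    is_max <- R > 0
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      is_max <- is_max & (R > shift_mat(R, di, dj))
    }
    is_max[c(seq_len(border), H - seq_len(border) + 1), ] <- FALSE
    is_max[, c(seq_len(border), W - seq_len(border) + 1)] <- FALSE
    idx <- which(is_max, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    i <- idx[, 1]; j <- idx[, 2]
    oi <- subpix_offset(R[cbind(i - 1, j)], R[cbind(i, j)], R[cbind(i + 1, j)])
    oj <- subpix_offset(R[cbind(i, j - 1)], R[cbind(i, j)], R[cbind(i, j + 1)])
    out[[si]] <- data.frame(x = (j - 1) + oj, y = (i - 1) + oi,
                            scale = resp$sigmas[si], response = R[cbind(i, j)])
  }
  kp <- if (length(out)) do.call(rbind, out)
  else data.frame(x = numeric(), y = numeric(), scale = numeric(),
                  response = numeric())
  if (nrow(kp) > 1) {
    kp <- kp[order(-kp$response), , drop = FALSE]
    # noise maxima are legion; only the strongest few thousand can ever
    # survive a positive threshold cap, so prune before deduplication
    if (nrow(kp) > 3000) kp <- kp[seq_len(3000), , drop = FALSE]
    # greedy radius-2.5px suppression keeping the strongest of a cluster
    keep <- rep(TRUE, nrow(kp))
    for (q in 2:nrow(kp)) {
      prev <- which(keep[seq_len(q - 1)])
      d2 <- (kp$x[q] - kp$x[prev])^2 + (kp$y[q] - kp$y[prev])^2
      if (length(d2) && min(d2) < 2.5^2) keep[q] <- FALSE
    }
    kp <- kp[keep, , drop = FALSE]
  }
  rownames(kp) <- NULL
  kp
}

subpix_offset <- function(rm, r0, rp) {
  den <- rm - 2 * r0 + rp
  off <- ifelse(abs(den) > 1e-12, 0.5 * (rm - rp) / den, 0)
  pmin(0.5, pmax(-0.5, off))
}

#' Detect blob keypoints above a response threshold
#'
#' Filters the cached candidate maxima of [doh_responses()] by response
#' threshold (the Hessian threshold). Keypoint coordinates are subpixel
#' (quadratic fit), 0-based, with `x` = column and `y` = row.
#'
#' @param resp output of [doh_responses()], or a frame matrix (responses
#'   are then computed on the fly).
#' @param threshold minimum response (the Hessian threshold).
#' @param max_keypoints cap on the number of returned keypoints (strongest
#'   kept).
#' @return data.frame with columns `x`, `y`, `scale`, `response`.
#' @export
detect_keypoints <- function(resp, threshold, max_keypoints = 500) {
  if (is.matrix(resp)) resp <- doh_responses(resp)
  kp <- resp$candidates[resp$candidates$response > threshold, , drop = FALSE]
  if (nrow(kp) > max_keypoints) kp <- kp[seq_len(max_keypoints), , drop = FALSE]
  rownames(kp) <- NULL
  kp
}

bilinear_sample <- function(img, yi, xj) {
  H <- nrow(img); W <- ncol(img)
  yi <- pmin(pmax(yi, 0), H - 1 - 1e-9)
  xj <- pmin(pmax(xj, 0), W - 1 - 1e-9)
  i0 <- floor(yi); j0 <- floor(xj)
  fi <- yi - i0; fj <- xj - j0
  i0 <- i0 + 1; j0 <- j0 + 1  # 1-based
  i1 <- pmin(i0 + 1, H); j1 <- pmin(j0 + 1, W)
  (1 - fi) * (1 - fj) * img[cbind(i0, j0)] +
    fi * (1 - fj) * img[cbind(i1, j0)] +
    (1 - fi) * fj * img[cbind(i0, j1)] +
    fi * fj * img[cbind(i1, j1)]
}

#' Compute upright 64-D descriptors for a set of keypoints
#'
#' For each keypoint a 20x20 grid of sample points spaced by the detection
#' scale is laid over the scale-matched smoothed image; local gradients are
#' Gaussian-weighted and pooled into a 4x4 grid of subregions, each
#' contributing (sum dx, sum |dx|, sum dy, sum |dy|). Descriptors are
#' L2-normalized, so matching distances live on the usual unit scale of the
#' good-match cascade constants (0.02, 0.03). No dominant-orientation
#' assignment is performed (upright variant): probe rotation between
#' consecutive frames is at most a few degrees.
#'
#' @param frame numeric matrix in \[0, 255\].
#' @param keypoints data.frame from [detect_keypoints()].
#' @return object of class `descriptor_set`: list with `keypoints` and a
#'   descriptor matrix (one row per keypoint).
#' @export
describe_keypoints <- function(frame, keypoints) {
  n <- nrow(keypoints)
  desc <- matrix(0, n, 64)
  if (n > 0) {
    gs <- seq(-9.5, 9.5, by = 1)                 # sample offsets, units of sigma
    gx <- rep(gs, each = 20); gy <- rep(gs, 20)  # 400 points
    wgt <- exp(-(gx^2 + gy^2) / (2 * 3.3^2))
    cell <- pmin(3, (rep(0:19, each = 20)) %/% 5) * 4 +
      pmin(3, (rep(0:19, 20)) %/% 5)             # 0..15 subregion id
    frame <- frame / 255
    for (s in unique(keypoints$scale)) {
      G <- .cpp_gaussian_blur(frame, s)
      sel <- which(keypoints$scale == s)
      for (q in sel) {
        px <- keypoints$x[q] + gx * s
        py <- keypoints$y[q] + gy * s
        h <- 0.5 * s
        dx <- (bilinear_sample(G, py, px + h) - bilinear_sample(G, py, px - h)) * wgt
        dy <- (bilinear_sample(G, py + h, px) - bilinear_sample(G, py - h, px)) * wgt
        v <- numeric(64)
        for (cid in 0:15) {
          m <- cell == cid
          v[cid * 4 + 1:4] <- c(sum(dx[m]), sum(abs(dx[m])),
                                sum(dy[m]), sum(abs(dy[m])))
        }
        nv <- sqrt(sum(v^2))
        desc[q, ] <- if (nv > 1e-12) v / nv else v
      }
    }
  }
  structure(list(keypoints = keypoints, descriptors = desc),
            class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("descriptor_set: %d keypoint(s), %d-D descriptors\n",
              nrow(x$keypoints), ncol(x$descriptors)))
  invisible(x)
}
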