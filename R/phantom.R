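# Synthetic capillaroscopy phantom: dark tortuous vessels on a brighter
# textured background with stationary high-contrast blobs (guaranteed
# keypoint material), intermittent per-arc vessel visibility emulating
# red-blood-cell flow, rigid per-frame probe jitter with an exact motion
# log, and additive sensor noise. The generator targets the statistical
# structure the pipeline assumes (contrast, flicker, rigid motion), not
# blood rheology.

#' Phantom scene specification
#'
#' Defaults describe the acquisition this pipeline is designed for:
#' 620 x 476 8-bit frames, a handful of capillaries a few pixels wide and
#' clearly darker than the tissue background, roughly half of each vessel
#' visible in any single frame (intermittent flow), steadied-probe jitter of
#' a couple of pixels and a fraction of a degree between consecutive frames
#' (at 120 fps larger per-frame motion would mean the probe sweeping between
#' regions, the regime handled by splitting, not stabilization), and mild
#' sensor noise.
#'
#' @param width,height frame size in pixels.
#' @param n_frames number of frames.
#' @param n_vessels number of capillaries.
#' @param vessel_width range (min, max) of vessel diameter in pixels.
#' @param tortuosity standard deviation of the per-step direction change of
#'   a centerline (radians); larger values give more tortuous vessels.
#' @param background_level mean background intensity (8-bit scale).
#' @param vessel_contrast background-minus-vessel intensity gap.
#' @param flow_visibility probability that a vessel arc is visible in a
#'   given frame (models intermittent red-blood-cell flow).
#' @param jitter_translation max |dx|, |dy| of the per-frame-pair jitter
#'   (uniform) in pixels.
#' @param jitter_rotation max |theta| of the per-frame-pair jitter in
#'   degrees.
#' @param motion_mode `"jitter"` (independent uniform per frame pair) or
#'   `"drift"` (smooth constant-velocity drift, useful for testing
#'   splitting on probe speed).
#' @param noise_sigma additive Gaussian noise standard deviation (8-bit
#'   scale).
#' @param blob_features number of stationary high-contrast texture blobs.
#' @param arc_length centerline arc length (in pixels) of the independent
#'   visibility units.
#' @param seed RNG seed; the phantom is fully deterministic given the seed.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 620, height = 476, n_frames = 20,
                         n_vessels = 4, vessel_width = c(4, 8),
                         tortuosity = 0.08, background_level = 180,
                         vessel_contrast = 60, flow_visibility = 0.6,
                         jitter_translation = 2, jitter_rotation = 0.3,
                         motion_mode = c("jitter", "drift"),
                         noise_sigma = 4, blob_features = 25,
                         arc_length = 40, seed = 1) {
  motion_mode <- match.arg(motion_mode)
  stopifnot(width > 0, height > 0, n_frames >= 1, n_vessels >= 0,
            flow_visibility >= 0, flow_visibility <= 1,
            jitter_translation >= 0, jitter_rotation >= 0, noise_sigma >= 0)
  if (max(vessel_width) >= min(width, height))
    stop("vessel wider than frame")
  structure(as.list(environment()), class = "phantom_spec")
}

with_preserved_rng <- function(expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# random smoothed centerline inside the frame region of the canvas
sample_centerline <- function(spec, pad) {
  len <- round(0.7 * min(spec$width, spec$height))
  margin <- 0.12
  x <- pad + runif(1, margin * spec$width, (1 - margin) * spec$width)
  y <- pad + runif(1, margin * spec$height, (1 - margin) * spec$height)
  ang <- runif(1, 0, 2 * pi)
  xs <- numeric(len); ys <- numeric(len)
  lo_x <- pad + 2; hi_x <- pad + spec$width - 3
  lo_y <- pad + 2; hi_y <- pad + spec$height - 3
  for (t in seq_len(len)) {
    xs[t] <- x; ys[t] <- y
    ang <- ang + rnorm(1, 0, spec$tortuosity)
    x <- x + cos(ang); y <- y + sin(ang)
    if (x < lo_x || x > hi_x) { ang <- pi - ang; x <- min(max(x, lo_x), hi_x) }
    if (y < lo_y || y > hi_y) { ang <- -ang; y <- min(max(y, lo_y), hi_y) }
  }
  cbind(x = xs, y = ys)
}

#' Generate a synthetic capillary video phantom
#'
#' Vessel centerlines are smoothed random curves dilated to the sampled
#' vessel width and darkened by `vessel_contrast` on a textured background
#' carrying stationary blobs. Centerlines are split into arcs of
#' `arc_length` pixels; each arc is independently visible in each frame
#' with probability `flow_visibility`. The whole scene is rigidly
#' transformed per frame by the sampled jitter (logged exactly in
#' `true_motions`), and noise is added last. Fully deterministic given
#' `spec$seed`; the caller's RNG state is preserved.
#'
#' @param spec [phantom_spec].
#' @return list of class `phantom_output` with fields `frames`
#'   ([frame_sequence]), `truth_mask` (full vessel network, frame-0
#'   coordinates), `true_motions` (list of `n_frames - 1` pairwise
#'   [rigid_motion]), and `per_frame_visible_masks`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_preserved_rng({
    set.seed(spec$seed)
    H <- spec$height; W <- spec$width

    # pairwise motions, then absolute poses A_k (frame-0 -> frame-k coords)
    nm <- max(0, spec$n_frames - 1)
    motions <- vector("list", nm)
    if (nm > 0) {
      if (spec$motion_mode == "jitter") {
        for (k in seq_len(nm))
          motions[[k]] <- rigid_motion(
            runif(1, -spec$jitter_translation, spec$jitter_translation),
            runif(1, -spec$jitter_translation, spec$jitter_translation),
            runif(1, -spec$jitter_rotation, spec$jitter_rotation))
      } else {
        vx <- runif(1, 0.5, 1) * spec$jitter_translation
        vy <- runif(1, 0.5, 1) * spec$jitter_translation
        for (k in seq_len(nm)) motions[[k]] <- rigid_motion(vx, vy, 0)
      }
    }
    poses <- vector("list", spec$n_frames)
    poses[[1]] <- rigid_motion()
    if (nm > 0)
      for (k in seq_len(nm))
        poses[[k + 1]] <- compose_motion(motions[[k]], poses[[k]])

    # canvas must cover every frame's footprint in frame-0 coordinates
    corners <- cbind(x = c(0, W - 1, 0, W - 1), y = c(0, 0, H - 1, H - 1))
    lo <- c(0, 0); hi <- c(W - 1, H - 1)
    for (k in seq_len(spec$n_frames)) {
      p <- apply_motion(invert_motion(poses[[k]]), corners)
      lo <- pmin(lo, apply(p, 2, min)); hi <- pmax(hi, apply(p, 2, max))
    }
    pad <- ceiling(max(0 - lo[1], 0 - lo[2], hi[1] - (W - 1),
                       hi[2] - (H - 1), 0)) + 4
    Hc <- H + 2 * pad; Wc <- W + 2 * pad

    # static background: smooth texture + fine grain + stationary blobs
    bg <- matrix(spec$background_level, Hc, Wc) +
      .cpp_gaussian_blur(matrix(rnorm(Hc * Wc, 0, 60), Hc, Wc), 12) +
      .cpp_gaussian_blur(matrix(rnorm(Hc * Wc, 0, 12), Hc, Wc), 2)
    if (spec$blob_features > 0) {
      bx <- pad + runif(spec$blob_features, 0.05 * W, 0.95 * W)
      by <- pad + runif(spec$blob_features, 0.05 * H, 0.95 * H)
      br <- runif(spec$blob_features, 2.5, 5)
      ba <- sample(c(-1, 1), spec$blob_features, replace = TRUE) *
        runif(spec$blob_features, 70, 110)
      for (q in seq_len(spec$blob_features)) {
        r <- ceiling(3 * br[q])
        i0 <- max(1, round(by[q]) - r):min(Hc, round(by[q]) + r)
        j0 <- max(1, round(bx[q]) - r):min(Wc, round(bx[q]) + r)
        d2 <- outer((i0 - 1 - by[q])^2, (j0 - 1 - bx[q])^2, "+")
        bg[i0, j0] <- bg[i0, j0] + ba[q] * exp(-d2 / (2 * br[q]^2))
      }
    }

    # vessels: centerlines -> arcs -> soft coverage maps (sparse)
    arcs <- list()
    for (v in seq_len(spec$n_vessels)) {
      cl <- sample_centerline(spec, pad)
      wv <- runif(1, spec$vessel_width[1], max(spec$vessel_width))
      n_arc <- max(1, ceiling(nrow(cl) / spec$arc_length))
      for (a in seq_len(n_arc)) {
        rows <- ((a - 1) * spec$arc_length + 1):min(a * spec$arc_length, nrow(cl))
        m <- .cpp_stamp_discs(Hc, Wc, cl[rows, "y"], cl[rows, "x"], wv / 2)
        idx <- which(m > 0)
        arcs[[length(arcs) + 1]] <- list(idx = idx, val = m[idx])
      }
    }

    full_alpha <- matrix(0, Hc, Wc)
    for (a in arcs) full_alpha[a$idx] <- pmax(full_alpha[a$idx], a$val)
    crop <- function(M) M[pad + seq_len(H), pad + seq_len(W)]
    truth_mask <- (crop(full_alpha) >= 0.5) + 0

    # per-frame visibility, render, jitter, noise
    frames <- vector("list", spec$n_frames)
    vis_masks <- vector("list", spec$n_frames)
    for (k in seq_len(spec$n_frames)) {
      visible <- if (length(arcs))
        runif(length(arcs)) < spec$flow_visibility else logical()
      alpha_k <- matrix(0, Hc, Wc)
      for (a in which(visible))
        alpha_k[arcs[[a]]$idx] <- pmax(alpha_k[arcs[[a]]$idx], arcs[[a]]$val)
      scene_k <- bg - spec$vessel_contrast * alpha_k
      # frame-k pixel (i,j) looks up scene at A_k^{-1}(p) + pad
      inv <- invert_motion(poses[[k]])
      ang <- inv$theta * pi / 180
      par <- c(cos(ang), sin(ang), inv$dy + pad,
               -sin(ang), cos(ang), inv$dx + pad)
      img <- .cpp_warp(scene_k, par, H, W, TRUE, spec$background_level)$image
      if (spec$noise_sigma > 0)
        img <- img + rnorm(H * W, 0, spec$noise_sigma)
      frames[[k]] <- pmin(pmax(round(img), 0), 255)
      vm <- .cpp_warp((alpha_k >= 0.5) + 0, par, H, W, FALSE, 0)$image
      vis_masks[[k]] <- vm
    }

    structure(list(frames = frame_sequence(frames, 120),
                   truth_mask = truth_mask,
                   true_motions = motions,
                   per_frame_visible_masks = vis_masks),
              class = "phantom_output")
  })
}

#' Generate a static phantom image dataset
#'
#' Produces `n_images` independent single-frame phantoms with fully visible
#' vessels and no jitter, sized like the study images (default 620 x 476),
#' together with their ground-truth masks — a drop-in structural replica of
#' a small expert-annotated capillaroscopy database for exercising the
#' tiling, augmentation, class-weight, and cross-validation machinery.
#'
#' @param spec [phantom_spec]; its size, vessel and noise parameters are
#'   used, while motion and flicker are disabled.
#' @param n_images number of images (at least 2 for leave-one-out use).
#' @return list with `images` (list of matrices), `masks` (list of 0/1
#'   matrices), and `ids` (character image identifiers).
#' @export
phantom_dataset <- function(spec = phantom_spec(), n_images = 2) {
  stopifnot(n_images >= 1)
  images <- vector("list", n_images)
  masks <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    si <- spec
    si$n_frames <- 1
    si$flow_visibility <- 1
    si$jitter_translation <- 0
    si$jitter_rotation <- 0
    si$seed <- spec$seed + 7919 * i
    ph <- generate_phantom(si)
    images[[i]] <- ph$frames$frames[[1]]
    masks[[i]] <- ph$truth_mask
  }
  list(images = images, masks = masks,
       ids = sprintf("phantom_%03d", seq_len(n_images)))
}
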