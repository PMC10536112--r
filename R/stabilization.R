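# Feature-based rigid stabilization: iterative keypoint detection with a
# decreasing Hessian threshold, nearest-neighbour descriptor matching, the
# cascaded good-match filter, displacement-based outlier rejection, and
# closed-form (Procrustes) rigid motion estimation between consecutive
# frames. Motions compose into a track used to warp every frame into the
# reference frame of frame 0.

#' Stabilization configuration
#'
#' Holds every tunable of the stabilization stage. Defaults follow the
#' operational definition of the algorithm: starting Hessian threshold 1000
#' lowered in steps of 20 until both frames yield at least 10 keypoints;
#' abort below 5 matches; good-match cascade thresholds
#' `max(2*min_dist, 0.02)` then `max(3*min_dist, 0.03)` with a best-4
#' fallback; matches whose displacement deviates from the mean by more than
#' 2 standard deviations are discarded.
#'
#' @param initial_hessian_threshold starting detector threshold.
#' @param threshold_decrement per-iteration reduction.
#' @param min_keypoints lower bound of keypoints per frame.
#' @param min_matches abort bound for the matcher.
#' @param good_match_factors ordered cascade stages, each `c(factor, floor)`.
#' @param outlier_sigma multiple of the displacement standard deviation.
#' @param split_speed_threshold maximum tolerated inter-frame displacement in
#'   pixels; `NULL` means 10% of the frame width (resolved at use time).
#' @return list of class `stab_config`.
#' @export
stab_config <- function(initial_hessian_threshold = 1000,
                        threshold_decrement = 20,
                        min_keypoints = 10,
                        min_matches = 5,
                        good_match_factors = list(c(2, 0.02), c(3, 0.03)),
                        outlier_sigma = 2,
                        split_speed_threshold = NULL) {
  stopifnot(initial_hessian_threshold > 0, threshold_decrement > 0,
            threshold_decrement < initial_hessian_threshold,
            min_keypoints > 0, min_matches > 0, outlier_sigma > 0)
  structure(list(initial_hessian_threshold = initial_hessian_threshold,
                 threshold_decrement = threshold_decrement,
                 min_keypoints = min_keypoints,
                 min_matches = min_matches,
                 good_match_factors = good_match_factors,
                 outlier_sigma = outlier_sigma,
                 split_speed_threshold = split_speed_threshold),
            class = "stab_config")
}

#' Rigid image-plane motion
#'
#' Maps a point `p = (x, y)` (x = column, y = row, 0-based) from the earlier
#' frame to `R(theta) p + (dx, dy)` in the later frame; rotation is about the
#' coordinate origin and `theta` is in degrees.
#'
#' @param dx,dy translation in pixels.
#' @param theta rotation in degrees.
#' @return list of class `rigid_motion`.
#' @export
rigid_motion <- function(dx = 0, dy = 0, theta = 0) {
  structure(list(dx = dx, dy = dy, theta = theta), class = "rigid_motion")
}

#' @export
print.rigid_motion <- function(x, ...) {
  cat(sprintf("rigid_motion: dx = %.3f px, dy = %.3f px, theta = %.4f deg\n",
              x$dx, x$dy, x$theta))
  invisible(x)
}

motion_matrix <- function(m) {
  a <- m$theta * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Compose two rigid motions (`m2` after `m1`)
#' @param m2,m1 [rigid_motion] objects; the result applies `m1` first.
#' @return [rigid_motion]
#' @export
compose_motion <- function(m2, m1) {
  R2 <- motion_matrix(m2)
  t1 <- c(m1$dx, m1$dy)
  t <- R2 %*% t1 + c(m2$dx, m2$dy)
  rigid_motion(t[1], t[2], m2$theta + m1$theta)
}

#' Invert a rigid motion
#' @param m [rigid_motion]
#' @return [rigid_motion] such that composing with `m` gives the identity.
#' @export
invert_motion <- function(m) {
  Ri <- t(motion_matrix(m))
  t <- -Ri %*% c(m$dx, m$dy)
  rigid_motion(t[1], t[2], -m$theta)
}

apply_motion <- function(m, xy) {
  # xy: n x 2 matrix of (x, y)
  t(motion_matrix(m) %*% t(xy)) + matrix(c(m$dx, m$dy), nrow(xy), 2,
                                         byrow = TRUE)
}

# Warp `img` so that output pixel p (0-based row/col) takes the value of
# img at motion(p): inverse warping with `motion` mapping destination
# coordinates to source coordinates.
warp_by_motion <- function(img, motion, Hout = nrow(img), Wout = ncol(img),
                           bilinear = TRUE, fill = 0) {
  a <- motion$theta * pi / 180
  par <- c(cos(a), sin(a), motion$dy,    # src_row = cos*i + sin*j + dy
           -sin(a), cos(a), motion$dx)   # src_col = -sin*i + cos*j + dx
  .cpp_warp(img, par, Hout, Wout, bilinear, fill)
}

#' Rotate an image about its center
#'
#' Counter-clockwise rotation in the (x right, y down) image coordinate
#' convention; uncovered corners are filled with `fill`.
#'
#' @param img numeric matrix.
#' @param angle degrees.
#' @param bilinear bilinear interpolation; set `FALSE` for nearest-neighbour
#'   (binary masks).
#' @param fill background fill value.
#' @return matrix of the same size.
#' @export
rotate_image <- function(img, angle, bilinear = TRUE, fill = 0) {
  cy <- (nrow(img) - 1) / 2; cx <- (ncol(img) - 1) / 2
  a <- -angle * pi / 180  # dest -> src is the inverse rotation
  par <- c(cos(a), sin(a), cy - cos(a) * cy - sin(a) * cx,
           -sin(a), cos(a), cx + sin(a) * cy - cos(a) * cx)
  .cpp_warp(img, par, nrow(img), ncol(img), bilinear, fill)$image
}

#' Iterative keypoint detection on a frame pair
#'
#' Detects keypoints on both frames at a common Hessian threshold, starting
#' from `initial_hessian_threshold` and lowering it by `threshold_decrement`
#' while either frame yields fewer than `min_keypoints` keypoints and the
#' threshold is still positive. Returns the descriptor sets found at the
#' final threshold (possibly empty for featureless frames).
#'
#' @param frame_a,frame_b numeric matrices of identical dimensions.
#' @param cfg [stab_config].
#' @param resp_a,resp_b optional precomputed [doh_responses()] caches.
#' @return list of two `descriptor_set`s with attribute
#'   `"hessian_threshold"` (final value) and `"thresholds_visited"`.
#' @export
detect_keypoints_iterative <- function(frame_a, frame_b, cfg = stab_config(),
                                       resp_a = NULL, resp_b = NULL) {
  stopifnot(identical(dim(frame_a), dim(frame_b)))
  if (is.null(resp_a)) resp_a <- doh_responses(frame_a)
  if (is.null(resp_b)) resp_b <- doh_responses(frame_b)
  th <- cfg$initial_hessian_threshold
  visited <- numeric()
  repeat {
    visited <- c(visited, th)
    kp_a <- detect_keypoints(resp_a, th)
    kp_b <- detect_keypoints(resp_b, th)
    enough <- nrow(kp_a) >= cfg$min_keypoints && nrow(kp_b) >= cfg$min_keypoints
    if (enough || th - cfg$threshold_decrement <= 0) break
    th <- th - cfg$threshold_decrement
  }
  out <- list(a = describe_keypoints(frame_a, kp_a),
              b = describe_keypoints(frame_b, kp_b))
  attr(out, "hessian_threshold") <- th
  attr(out, "thresholds_visited") <- visited
  out
}

#' Match descriptors between two frames by nearest neighbour
#'
#' Each keypoint of `a` is matched to its nearest neighbour in `b` under
#' Euclidean descriptor distance (one-directional, no ratio test). The
#' search is exact. Aborts with "matches are too few" when fewer than
#' `min_matches` matches result.
#'
#' @param a,b `descriptor_set`s (both non-empty).
#' @param min_matches abort bound (default from [stab_config()]).
#' @return object of class `match_set`: data.frame `matches` with columns
#'   `index_a`, `index_b`, `distance`, `displacement`, `xa`, `ya`, `xb`,
#'   `yb`, plus `min_dist`.
#' @export
match_descriptors <- function(a, b, min_matches = 5) {
  na <- nrow(a$keypoints); nb <- nrow(b$keypoints)
  if (na == 0 || nb == 0 || na < min_matches)
    stop("matches are too few")
  D2 <- outer(rowSums(a$descriptors^2), rowSums(b$descriptors^2), "+") -
    2 * a$descriptors %*% t(b$descriptors)
  D2[D2 < 0] <- 0
  nn <- max.col(-D2, ties.method = "first")
  dist <- sqrt(D2[cbind(seq_len(na), nn)])
  xa <- a$keypoints$x; ya <- a$keypoints$y
  xb <- b$keypoints$x[nn]; yb <- b$keypoints$y[nn]
  ms <- data.frame(index_a = seq_len(na), index_b = nn, distance = dist,
                   displacement = sqrt((xb - xa)^2 + (yb - ya)^2),
                   xa = xa, ya = ya, xb = xb, yb = yb)
  if (nrow(ms) < min_matches) stop("matches are too few")
  structure(list(matches = ms, min_dist = min(ms$distance)),
            class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("match_set: %d match(es), min_dist = %.4g\n",
              nrow(x$matches), x$min_dist))
  invisible(x)
}

match_set_from_df <- function(df) {
  structure(list(matches = df,
                 min_dist = if (nrow(df)) min(df$distance) else NA_real_),
            class = "match_set")
}

#' Cascaded good-match filter
#'
#' Keeps matches with descriptor distance below `max(2*min_dist, 0.02)`;
#' if fewer than 5 survive, retries with `max(3*min_dist, 0.03)`; if still
#' fewer than 5, keeps the 4 smallest-distance matches.
#'
#' @param ms `match_set`.
#' @param cfg [stab_config].
#' @return filtered `match_set` with attribute `"stage"` (1, 2, or
#'   `"best4"`).
#' @export
filter_good_matches <- function(ms, cfg = stab_config()) {
  df <- ms$matches
  md <- ms$min_dist
  for (s in seq_along(cfg$good_match_factors)) {
    fac <- cfg$good_match_factors[[s]]
    keep <- df[df$distance < max(fac[1] * md, fac[2]), , drop = FALSE]
    if (nrow(keep) >= 5) {
      out <- match_set_from_df(keep)
      attr(out, "stage") <- s
      return(out)
    }
  }
  keep <- df[order(df$distance)[seq_len(min(4, nrow(df)))], , drop = FALSE]
  out <- match_set_from_df(keep)
  attr(out, "stage") <- "best4"
  out
}

#' Displacement-based outlier rejection
#'
#' Removes matches whose image-plane displacement deviates from the mean
#' displacement by more than `outlier_sigma` (population) standard
#' deviations. A zero standard deviation keeps everything.
#'
#' @param ms `match_set`.
#' @param cfg [stab_config].
#' @return filtered `match_set`.
#' @export
reject_outlier_matches <- function(ms, cfg = stab_config()) {
  df <- ms$matches
  if (nrow(df) == 0) stop("empty match set")
  mu <- mean(df$displacement)
  sdev <- sqrt(mean((df$displacement - mu)^2))
  if (sdev > 0)
    df <- df[abs(df$displacement - mu) <= cfg$outlier_sigma * sdev, ,
             drop = FALSE]
  match_set_from_df(df)
}

#' Closed-form rigid motion estimation from matched keypoints
#'
#' Least-squares rigid transform (rotation + translation, no scaling)
#' mapping the keypoint positions of the earlier frame onto the later frame,
#' computed by centroid alignment and 2-D orthogonal Procrustes analysis.
#' With a single match a pure translation is returned (attribute
#' `"model" = "translation"`).
#'
#' @param ms `match_set` with at least one match.
#' @return [rigid_motion] with attribute `"rmse"` (residual) and `"model"`.
#' @export
estimate_motion <- function(ms) {
  df <- ms$matches
  if (nrow(df) == 0) stop("empty match set")
  A <- cbind(df$xa, df$ya)
  B <- cbind(df$xb, df$yb)
  ca <- colMeans(A); cb <- colMeans(B)
  model <- "rigid"
  if (nrow(df) == 1) {
    m <- rigid_motion(cb[1] - ca[1], cb[2] - ca[2], 0)
    model <- "translation"
  } else {
    Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
    scos <- sum(Ac * Bc)
    ssin <- sum(Ac[, 1] * Bc[, 2] - Ac[, 2] * Bc[, 1])
    theta <- atan2(ssin, scos)
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    t <- cb - R %*% ca
    m <- rigid_motion(t[1], t[2], theta * 180 / pi)
  }
  pred <- apply_motion(m, A)
  attr(m, "rmse") <- sqrt(mean((pred - B)^2))
  attr(m, "model") <- model
  m
}

# Full Algorithm-1 chain on one frame pair.
estimate_pair_motion <- function(frame_a, frame_b, cfg,
                                 resp_a = NULL, resp_b = NULL) {
  ds <- detect_keypoints_iterative(frame_a, frame_b, cfg, resp_a, resp_b)
  ms <- match_descriptors(ds$a, ds$b, cfg$min_matches)
  good <- filter_good_matches(ms, cfg)
  good <- reject_outlier_matches(good, cfg)
  m <- estimate_motion(good)
  attr(m, "n_keypoints_a") <- nrow(ds$a$keypoints)
  attr(m, "n_keypoints_b") <- nrow(ds$b$keypoints)
  attr(m, "n_matches") <- nrow(ms$matches)
  attr(m, "n_good_matches") <- nrow(good$matches)
  m
}

#' Stabilize a frame sequence
#'
#' Estimates the rigid motion between every pair of consecutive frames
#' (iterative detection, matching, good-match cascade, outlier rejection,
#' Procrustes estimation), composes the pairwise motions into cumulative
#' transforms, and warps every frame into the reference frame of frame 0
#' with bilinear interpolation. Out-of-canvas pixels are filled with 0 and
#' flagged in per-frame validity masks.
#'
#' @param seq [frame_sequence] with at least 2 frames.
#' @param cfg [stab_config].
#' @return list with `frames` (stabilized [frame_sequence] carrying validity
#'   masks), `motions` (list of per-pair [rigid_motion]), and `track`
#'   (data.frame: frame_pair, dx, dy, theta_deg, n_keypoints_a,
#'   n_keypoints_b, n_matches, n_good_matches).
#' @export
stabilize_sequence <- function(seq, cfg = stab_config()) {
  if (seq$n < 2) stop("need at least 2 frames to stabilize")
  resp <- vector("list", seq$n)
  motions <- vector("list", seq$n - 1)
  track <- vector("list", seq$n - 1)
  for (k in seq_len(seq$n - 1)) {
    if (is.null(resp[[k]])) resp[[k]] <- doh_responses(seq$frames[[k]])
    if (is.null(resp[[k + 1]])) resp[[k + 1]] <- doh_responses(seq$frames[[k + 1]])
    m <- tryCatch(
      estimate_pair_motion(seq$frames[[k]], seq$frames[[k + 1]], cfg,
                           resp[[k]], resp[[k + 1]]),
      error = function(e)
        stop(sprintf("frame pair %d-%d: %s", k - 1, k, conditionMessage(e)),
             call. = FALSE))
    motions[[k]] <- m
    track[[k]] <- data.frame(frame_pair = k - 1, dx = m$dx, dy = m$dy,
                             theta_deg = m$theta,
                             n_keypoints_a = attr(m, "n_keypoints_a"),
                             n_keypoints_b = attr(m, "n_keypoints_b"),
                             n_matches = attr(m, "n_matches"),
                             n_good_matches = attr(m, "n_good_matches"))
    resp[[k]] <- NA  # release cache for frames no longer needed
  }
  # cumulative map: frame-0 coordinates -> frame-k coordinates
  cum <- rigid_motion()
  frames <- list(seq$frames[[1]])
  validity <- list(matrix(1L, nrow(seq$frames[[1]]), ncol(seq$frames[[1]])))
  for (k in seq_len(seq$n - 1)) {
    cum <- compose_motion(motions[[k]], cum)
    w <- warp_by_motion(seq$frames[[k + 1]], cum)
    frames[[k + 1]] <- pmin(pmax(w$image, 0), 255)  # bilinear round-off guard
    validity[[k + 1]] <- w$valid
  }
  list(frames = frame_sequence(frames, seq$frame_rate, validity),
       motions = motions,
       track = do.call(rbind, track))
}

#' Split a sequence where the probe moved too fast
#'
#' Cuts the sequence at every frame pair whose inter-frame displacement
#' magnitude `sqrt(dx^2 + dy^2)` exceeds the split threshold. Segments of
#' length 1 are permitted.
#'
#' @param seq [frame_sequence].
#' @param motions list of per-pair [rigid_motion] (length `N - 1`), e.g.
#'   provisional pairwise estimates.
#' @param cfg [stab_config]; a `NULL` `split_speed_threshold` resolves to
#'   10% of the frame width.
#' @return list of [frame_sequence] segments partitioning the input frames.
#' @export
split_on_motion <- function(seq, motions, cfg = stab_config()) {
  if (length(motions) != seq$n - 1)
    stop("`motions` must have length N - 1")
  thr <- cfg$split_speed_threshold
  if (is.null(thr)) thr <- 0.1 * ncol(seq$frames[[1]])
  disp <- vapply(motions, function(m) sqrt(m$dx^2 + m$dy^2), 0)
  cuts <- which(disp > thr)          # cut between frame k-1 and k (1-based k)
  bounds <- c(0, cuts, seq$n)
  out <- list()
  for (s in seq_len(length(bounds) - 1)) {
    idx <- (bounds[s] + 1):bounds[s + 1]
    out[[s]] <- frame_sequence(seq$frames[idx], seq$frame_rate,
                               if (is.null(seq$validity)) NULL
                               else seq$validity[idx])
  }
  out
}

#' Cumulative poses from pairwise motions
#'
#' Composes a list of `N - 1` pairwise motions (frame k to frame k+1) into
#' `N` cumulative transforms mapping frame-0 coordinates into each frame's
#' coordinates (the first is the identity).
#'
#' @param motions list of pairwise [rigid_motion].
#' @return list of `length(motions) + 1` cumulative [rigid_motion]s.
#' @export
cumulative_motions <- function(motions) {
  out <- vector("list", length(motions) + 1)
  out[[1]] <- rigid_motion()
  for (k in seq_along(motions))
    out[[k + 1]] <- compose_motion(motions[[k]], out[[k]])
  out
}

#' Stitch motion-aligned frames onto a common canvas
#'
#' The canvas is sized to the union bounding box of all frames warped into
#' the frame-0 coordinate system; overlapping pixels are merged by averaging
#' all contributing frames, non-overlapping pixels are copied verbatim.
#'
#' @param seq [frame_sequence].
#' @param motions list of per-pair [rigid_motion] (length `N - 1`).
#' @return list with `canvas` (numeric matrix), `coverage` (contribution
#'   counts), and `origin` (row/col of the frame-0 origin on the canvas,
#'   0-based).
#' @export
stitch_frames <- function(seq, motions) {
  H <- nrow(seq$frames[[1]]); W <- ncol(seq$frames[[1]])
  if (length(motions) != seq$n - 1)
    stop("`motions` must have length N - 1")
  cums <- cumulative_motions(motions)
  corners <- cbind(x = c(0, W - 1, 0, W - 1), y = c(0, 0, H - 1, H - 1))
  lo <- c(Inf, Inf); hi <- c(-Inf, -Inf)
  for (k in seq_len(seq$n)) {
    p <- apply_motion(invert_motion(cums[[k]]), corners)  # frame-k rect in frame-0 coords
    lo <- pmin(lo, apply(p, 2, min)); hi <- pmax(hi, apply(p, 2, max))
  }
  ox <- floor(lo[1]); oy <- floor(lo[2])
  Wc <- ceiling(hi[1]) - ox + 1; Hc <- ceiling(hi[2]) - oy + 1
  acc <- matrix(0, Hc, Wc); cnt <- matrix(0, Hc, Wc)
  for (k in seq_len(seq$n)) {
    m <- cums[[k]]
    a <- m$theta * pi / 180
    # canvas (i,j) -> frame-0 coords (i+oy, j+ox) -> frame-k coords
    t1 <- m$dy + cos(a) * oy + sin(a) * ox
    t2 <- m$dx - sin(a) * oy + cos(a) * ox
    par <- c(cos(a), sin(a), t1, -sin(a), cos(a), t2)
    w <- .cpp_warp(seq$frames[[k]], par, Hc, Wc, TRUE, 0)
    acc <- acc + w$image * w$valid
    cnt <- cnt + w$valid
  }
  canvas <- acc / pmax(cnt, 1)
  list(canvas = canvas, coverage = cnt, origin = c(row = -oy, col = -ox))
}
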