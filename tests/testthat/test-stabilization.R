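test_that("iterative detection exhausts the threshold on featureless frames", {
  flat <- matrix(128, 64, 64)
  ds <- detect_keypoints_iterative(flat, flat)
  expect_equal(nrow(ds$a$keypoints), 0)
  expect_equal(nrow(ds$b$keypoints), 0)
  visited <- attr(ds, "thresholds_visited")
  expect_equal(visited[1:3], c(1000, 980, 960))
  expect_lte(visited[length(visited)] - 20, 0)
})

test_that("iterative detection stops at the first threshold giving enough keypoints", {
  ph <- generate_phantom(small_phantom_spec(jitter_translation = 0,
                                            jitter_rotation = 0))
  fa <- ph$frames$frames[[1]]; fb <- ph$frames$frames[[2]]
  cfg <- stab_config()
  ds <- detect_keypoints_iterative(fa, fb, cfg)
  expect_gte(nrow(ds$a$keypoints), cfg$min_keypoints)
  expect_gte(nrow(ds$b$keypoints), cfg$min_keypoints)
  # brute-force sweep oracle over the visited thresholds: the final one is
  # the first that satisfies the bound on both frames
  th_final <- attr(ds, "hessian_threshold")
  ra <- doh_responses(fa); rb <- doh_responses(fb)
  for (th in attr(ds, "thresholds_visited")) {
    ok <- nrow(detect_keypoints(ra, th)) >= cfg$min_keypoints &&
      nrow(detect_keypoints(rb, th)) >= cfg$min_keypoints
    if (th > th_final) expect_false(ok) else expect_true(ok)
  }
})

test_that("matching a descriptor set against itself is the identity with distance 0", {
  ph <- generate_phantom(small_phantom_spec())
  r <- doh_responses(ph$frames$frames[[1]])
  kp <- detect_keypoints(r, 100)
  ds <- describe_keypoints(ph$frames$frames[[1]], kp)
  ms <- match_descriptors(ds, ds)
  expect_equal(ms$matches$index_b, ms$matches$index_a)
  expect_equal(max(ms$matches$distance), 0, tolerance = 1e-6)
  expect_equal(ms$min_dist, 0, tolerance = 1e-6)
})

test_that("too few keypoints abort with the matches-are-too-few message", {
  kp <- data.frame(x = c(5, 10, 15, 20), y = c(5, 5, 5, 5),
                   scale = 1.2, response = 1)
  img <- matrix(runif(900, 0, 255), 30, 30)
  ds <- describe_keypoints(img, kp)
  expect_error(match_descriptors(ds, ds, min_matches = 5),
               "matches are too few")
})

test_that("nearest-neighbour matching agrees with an exhaustive oracle", {
  set.seed(42)
  for (rep in 1:3) {
    na <- sample(5:50, 1); nb <- sample(5:50, 1)
    da <- matrix(rnorm(na * 64), na, 64)
    db <- matrix(rnorm(nb * 64), nb, 64)
    a <- structure(list(keypoints = data.frame(x = runif(na), y = runif(na),
                                               scale = 1, response = 1),
                        descriptors = da), class = "descriptor_set")
    b <- structure(list(keypoints = data.frame(x = runif(nb), y = runif(nb),
                                               scale = 1, response = 1),
                        descriptors = db), class = "descriptor_set")
    ms <- match_descriptors(a, b)
    # brute force: all-pairs distances, explicit min per query
    for (q in seq_len(na)) {
      dists <- sqrt(colSums((t(db) - da[q, ])^2))
      expect_equal(ms$matches$index_b[q], which.min(dists))
      expect_equal(ms$matches$distance[q], min(dists), tolerance = 1e-12)
    }
  }
})

test_that("the good-match cascade reproduces its hand-evaluated outcomes", {
  # distances {0.01, 0.015, 0.05, 0.06, 0.07}: stage 1 keeps 2, stage 2
  # keeps 2, fallback keeps the best 4
  ms <- make_match_set(c(0.01, 0.015, 0.05, 0.06, 0.07))
  out <- filter_good_matches(ms)
  expect_identical(attr(out, "stage"), "best4")
  expect_equal(sort(out$matches$distance), c(0.01, 0.015, 0.05, 0.06))
  # all distances equal d > 0: threshold max(2d, 0.02) > d keeps everything
  ms2 <- make_match_set(rep(0.5, 6))
  out2 <- filter_good_matches(ms2)
  expect_equal(nrow(out2$matches), 6)
  expect_identical(attr(out2, "stage"), 1L)
  # perfect matches present: stage-1 threshold is the 0.02 floor
  ms3 <- make_match_set(c(0, 0.005, 0.01, 0.015, 0.019, 0.5))
  out3 <- filter_good_matches(ms3)
  expect_identical(attr(out3, "stage"), 1L)
  expect_equal(nrow(out3$matches), 5)
  expect_true(all(out3$matches$distance < 0.02))
})

test_that("good-match filtering and outlier rejection return subsets", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(5:30, 1)
    ms <- make_match_set(runif(n, 0, 0.4), runif(n, 0, 20))
    g <- filter_good_matches(ms)
    expect_true(all(g$matches$distance %in% ms$matches$distance))
    r <- reject_outlier_matches(g)
    expect_true(all(r$matches$distance %in% g$matches$distance))
    expect_lte(nrow(r$matches), nrow(g$matches))
  }
  # best-4 fallback returns exactly min(4, n)
  ms5 <- make_match_set(c(1, 2, 3, 4, 5, 6) / 10)
  expect_equal(nrow(filter_good_matches(ms5)$matches), 4)
})

test_that("2-sigma outlier rejection reproduces the hand-evaluated case", {
  disp <- c(5.0, 5.2, 4.8, 5.1, 4.9, 30.0)
  # population mean/std oracle
  mu <- mean(disp); sdev <- sqrt(mean((disp - mu)^2))
  expect_true(abs(30 - mu) > 2 * sdev)
  expect_true(all(abs(disp[1:5] - mu) <= 2 * sdev))
  ms <- make_match_set(rep(0.1, 6), disp)
  out <- reject_outlier_matches(ms)
  expect_equal(sort(out$matches$displacement), sort(disp[1:5]))
  # degenerate spread: nothing removed
  same <- make_match_set(rep(0.1, 4), rep(3, 4))
  expect_equal(nrow(reject_outlier_matches(same)$matches), 4)
  # single match kept
  one <- make_match_set(0.1, 7)
  expect_equal(nrow(reject_outlier_matches(one)$matches), 1)
})

test_that("rigid motion estimation is exact on analytic correspondences", {
  set.seed(3)
  A <- cbind(runif(12, 0, 100), runif(12, 0, 100))
  # identity
  m0 <- estimate_motion(match_set_from_points(A, A))
  expect_equal(c(m0$dx, m0$dy, m0$theta), c(0, 0, 0), tolerance = 1e-12)
  # pure translation (5, -3)
  B <- sweep(A, 2, c(-5, 3))
  m1 <- estimate_motion(match_set_from_points(A, B))
  expect_equal(c(m1$dx, m1$dy, m1$theta), c(5, -3, 0), tolerance = 1e-10)
  # 10-degree rotation about the image center (50, 50)
  C <- rotate_points(A, 10, center = c(50, 50))
  m2 <- estimate_motion(match_set_from_points(A, C))
  expect_equal(m2$theta, 10, tolerance = 1e-6)
  expect_lt(attr(m2, "rmse"), 1e-9)
  pred <- capiflow:::apply_motion(m2, A)
  expect_equal(pred, C, tolerance = 1e-9)
})

test_that("motion composition and inversion satisfy the group laws", {
  m <- rigid_motion(3.5, -2.25, 12)
  id <- compose_motion(invert_motion(m), m)
  expect_equal(c(id$dx, id$dy, id$theta), c(0, 0, 0), tolerance = 1e-12)
  set.seed(9)
  p <- cbind(runif(5, 0, 50), runif(5, 0, 50))
  a <- rigid_motion(1, 2, 5); b <- rigid_motion(-3, 0.5, -2)
  lhs <- capiflow:::apply_motion(compose_motion(b, a), p)
  rhs <- capiflow:::apply_motion(b, capiflow:::apply_motion(a, p))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("a pure shift between two frames is recovered", {
  ph <- generate_phantom(small_phantom_spec(n_frames = 1, noise_sigma = 0,
                                            flow_visibility = 1))
  f1 <- ph$frames$frames[[1]]
  # frame 2 = frame 1 shifted 7 px right (content moves right: a scene
  # point at x appears at x + 7)
  f2 <- capiflow:::warp_by_motion(f1, rigid_motion(-7, 0, 0))$image
  f2 <- pmin(pmax(f2, 0), 255)
  s <- frame_sequence(list(f1, f2))
  st <- stabilize_sequence(s)
  expect_equal(st$motions[[1]]$dx, 7, tolerance = 0.3)
  expect_equal(st$motions[[1]]$dy, 0, tolerance = 0.3)
  expect_equal(st$motions[[1]]$theta, 0, tolerance = 0.1)
})

test_that("a static sequence stabilizes to identity motions", {
  ph <- generate_phantom(small_phantom_spec(jitter_translation = 0,
                                            jitter_rotation = 0,
                                            n_frames = 3))
  st <- stabilize_sequence(ph$frames)
  for (m in st$motions) {
    expect_lt(sqrt(m$dx^2 + m$dy^2), 0.2)
    expect_lt(abs(m$theta), 0.1)
  }
  # output equals input on the valid region
  v <- st$frames$validity[[2]] > 0
  expect_equal(st$frames$frames[[2]][v], ph$frames$frames[[2]][v],
               tolerance = 2, ignore_attr = TRUE)
})

test_that("known phantom jitter is recovered within 0.5 px and 0.2 deg", {
  ph <- generate_phantom(small_phantom_spec(seed = 21, n_frames = 6,
                                            jitter_translation = 8,
                                            jitter_rotation = 2))
  st <- stabilize_sequence(ph$frames)
  for (k in seq_along(st$motions)) {
    e <- st$motions[[k]]; tr <- ph$true_motions[[k]]
    expect_lt(abs(e$dx - tr$dx), 0.5)
    expect_lt(abs(e$dy - tr$dy), 0.5)
    expect_lt(abs(e$theta - tr$theta), 0.2)
  }
  expect_equal(nrow(st$track), 5)
  expect_true(all(c("frame_pair", "dx", "dy", "theta_deg", "n_keypoints_a",
                    "n_keypoints_b", "n_matches", "n_good_matches")
                  %in% names(st$track)))
})

test_that("splitting cuts the sequence exactly at fast-motion frame pairs", {
  frames <- lapply(1:6, function(i) matrix(i, 8, 8))
  s <- frame_sequence(frames)
  slow <- lapply(1:5, function(i) rigid_motion(1, 0, 0))
  cfg <- stab_config(split_speed_threshold = 50)
  expect_length(split_on_motion(s, slow, cfg), 1)
  expect_equal(split_on_motion(s, slow, cfg)[[1]]$n, 6)
  # one 100-px jump between frames 2 and 3 -> two segments
  jump <- slow; jump[[3]] <- rigid_motion(100, 0, 0)
  segs <- split_on_motion(s, jump, cfg)
  expect_length(segs, 2)
  expect_equal(vapply(segs, function(x) x$n, 0), c(3, 3))
  expect_identical(segs[[2]]$frames[[1]], frames[[4]])
  # every pair too fast -> N singletons
  fast <- lapply(1:5, function(i) rigid_motion(60, 60, 0))
  expect_length(split_on_motion(s, fast, cfg), 6)
})

test_that("stitching merges overlaps by averaging and keeps non-overlap verbatim", {
  set.seed(11)
  f <- matrix(sample(0:255, 40 * 30, TRUE), 30, 40)
  # single frame: canvas equals the frame
  one <- stitch_frames(frame_sequence(list(f)), list())
  expect_equal(one$canvas, f, ignore_attr = TRUE)
  # two identical aligned frames: average of equal values
  two <- stitch_frames(frame_sequence(list(f, f)), list(rigid_motion()))
  expect_equal(two$canvas, f, ignore_attr = TRUE)
  # pure translation by (10, 0): scene content 10 px left in frame 2
  m <- rigid_motion(-10, 0, 0)
  f2 <- capiflow:::warp_by_motion(f, invert_motion(m))$image
  st <- stitch_frames(frame_sequence(list(f, f2)), list(m))
  expect_equal(ncol(st$canvas), 50)
  expect_equal(nrow(st$canvas), 30)
  # non-overlap strip of frame 1 copied verbatim
  expect_equal(st$canvas[, 1:10], f[, 1:10], ignore_attr = TRUE)
  expect_equal(st$canvas[, 41:50], f2[, 31:40], ignore_attr = TRUE)
})
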