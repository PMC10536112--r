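brute_window_stats <- function(frames, k, n) {
  # independent per-pixel loop oracle for the windowed mean/std (0-based k)
  N <- length(frames)
  idx <- max(0, k - n):min(N - 1, k + n)
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  B <- matrix(0, H, W); S <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    v <- vapply(idx, function(kk) frames[[kk + 1]][i, j], 0)
    B[i, j] <- mean(v)
    S[i, j] <- sqrt(mean((v - mean(v))^2))
  }
  list(B = B, sigma = S)
}

test_that("windowed statistics match the hand-derived closed forms", {
  # constant sequence: B = c, sigma = 0
  s <- frame_sequence(lapply(1:7, function(i) matrix(42, 3, 3)))
  expect_equal(temporal_mean(s, 3)[2, 2], 42)
  expect_equal(max(temporal_std(s, 3)), 0)
  # pixel value = frame index, N = 11, n = 5
  s2 <- frame_sequence(lapply(0:10, function(k) matrix(k, 2, 2)))
  expect_equal(temporal_mean(s2, 5)[1, 1], 5)
  expect_equal(temporal_mean(s2, 0)[1, 1], 2.5)   # clamped window {0..5}
  expect_equal(temporal_mean(s2, 10)[1, 1], 7.5)  # clamped window {5..10}
  # alternating 0/255 over an 11-frame window (six 0s, five 255s)
  v <- rep(c(0, 255), length.out = 11)
  s3 <- frame_sequence(lapply(v, function(x) matrix(x, 2, 2)))
  oracle <- sqrt(mean((v - mean(v))^2))
  expect_equal(temporal_std(s3, 5)[1, 1], oracle, tolerance = 1e-12)
  expect_equal(round(oracle, 2), 126.97)
  # singleton window: sigma = 0
  expect_equal(max(temporal_std(s3, 5, temporal_window(0))), 0)
  expect_error(temporal_mean(s3, 11), "out of range")
})

test_that("windowed statistics agree with a brute-force pixel loop at every k", {
  set.seed(8)
  frames <- lapply(1:9, function(i) matrix(sample(0:255, 30, TRUE), 5, 6))
  s <- frame_sequence(frames)
  for (k in 0:8) {
    o <- brute_window_stats(frames, k, 2)
    w <- temporal_window(2)
    expect_equal(temporal_mean(s, k, w), o$B, tolerance = 1e-12)
    expect_equal(temporal_std(s, k, w), o$sigma, tolerance = 1e-12)
  }
})

test_that("a static sequence enhances to the normalized, filtered input", {
  set.seed(2)
  f <- matrix(sample(0:255, 48, TRUE), 6, 8)
  s <- frame_sequence(lapply(1:5, function(i) f))
  ef <- enhance_frame(s, 2)
  expect_equal(max(ef$sigma), 0)
  expect_equal(ef$H, f)
  # HF oracle: min-max normalize then 3x3 replicate-padded median
  h <- (f - min(f)) * (255 / (max(f) - min(f)))
  med <- matrix(0, 6, 8)
  for (i in 1:6) for (j in 1:8) {
    ii <- pmin(pmax(i + (-1:1), 1), 6); jj <- pmin(pmax(j + (-1:1), 1), 8)
    med[i, j] <- median(h[ii, jj])  # replicate padding via index clamping
  }
  expect_equal(ef$HF, pmin(pmax(round(med), 0), 255))
})

test_that("a flickering pixel is enhanced per the equations (brute-force oracle)", {
  f1 <- matrix(100, 5, 5); f2 <- matrix(100, 5, 5)
  f2[3, 3] <- 200  # one flickering pixel
  s <- frame_sequence(list(f1, f2))
  ef <- enhance_frame(s, 0, temporal_window(5))
  # oracle: window = both frames; sigma = 50 at the flicker pixel, else 0
  sig <- matrix(0, 5, 5); sig[3, 3] <- 50
  expect_equal(ef$sigma, sig)
  expect_equal(ef$H, f1 - sig)
  # H range [50, 100] -> shift/scale: flicker pixel 0, rest 255
  expect_equal(ef$HF[1, 1], 255)
  # median over the 3x3 around (3,3): eight 255s and one 0 -> 255
  expect_equal(ef$HF[3, 3], 255)
})

test_that("enhancement is invariant to a constant intensity offset", {
  set.seed(4)
  frames <- lapply(1:5, function(i) matrix(sample(0:200, 24, TRUE), 4, 6))
  s1 <- frame_sequence(frames)
  s2 <- frame_sequence(lapply(frames, function(f) f + 55))
  for (k in c(0, 2, 4))
    expect_identical(enhance_frame(s1, k)$HF, enhance_frame(s2, k)$HF)
})

test_that("HF stays in [0, 255] and single-frame sequences enhance cleanly", {
  set.seed(6)
  s <- frame_sequence(list(matrix(sample(0:255, 40, TRUE), 5, 8)))
  out <- enhance_sequence(s)
  expect_equal(out$n, 1)
  expect_true(all(out$frames[[1]] >= 0 & out$frames[[1]] <= 255))
  ef <- enhance_frame(s, 0)
  expect_equal(ef$H, s$frames[[1]])  # sigma = 0 for a single frame
})

test_that("per-sequence normalization shares one scale across frames", {
  # ramp frames, singleton window (sigma = 0 so H = I): per-frame scope
  # stretches both frames to the same full-range output, per-sequence scope
  # keeps the dim frame dim
  ramp <- matrix(rep(seq(0, 255, length.out = 6), each = 4), 4, 6)
  s <- frame_sequence(list(ramp, ramp / 5))
  w <- temporal_window(0)
  per_frame <- enhance_sequence(s, w)
  per_seq <- enhance_sequence(s, w, normalization = "sequence")
  expect_equal(per_frame$frames[[1]], per_frame$frames[[2]])
  expect_equal(max(per_frame$frames[[2]]), 255)
  expect_equal(per_seq$frames[[1]], per_frame$frames[[1]])
  expect_equal(max(per_seq$frames[[2]]), 51)
  expect_true(all(unlist(per_seq$frames) >= 0 & unlist(per_seq$frames) <= 255))
})

test_that("fully invalid pixels are flagged invalid, never NaN", {
  frames <- lapply(1:5, function(i) matrix(100 + i, 4, 4))
  validity <- lapply(1:5, function(i) {
    v <- matrix(1L, 4, 4); v[, 2] <- 0L; v
  })
  s <- frame_sequence(frames, validity = validity)
  ef <- enhance_frame(s, 2)
  expect_true(all(ef$valid[, 2] == 0))
  expect_false(any(is.na(ef$HF)))
  out <- enhance_sequence(s)
  expect_false(any(vapply(out$frames, function(f) any(is.na(f)), TRUE)))
})

test_that("enhancement raises vessel contrast on intermittent-flow phantoms", {
  ph <- generate_phantom(small_phantom_spec(seed = 33, n_frames = 11,
                                            jitter_translation = 0,
                                            jitter_rotation = 0,
                                            flow_visibility = 0.5))
  k <- 5
  raw <- ph$frames$frames[[k + 1]]
  hf <- enhance_frame(ph$frames, k)$HF
  tr <- ph$truth_mask == 1
  contrast <- function(img) (mean(img[!tr]) - mean(img[tr])) /
    (max(img) - min(img))
  expect_gt(contrast(hf), contrast(raw))
})
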