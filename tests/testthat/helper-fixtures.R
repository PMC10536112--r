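# Shared fixtures: compact phantoms and hand-built descriptor/match sets.

small_phantom_spec <- function(seed = 5, n_frames = 5, ...) {
  phantom_spec(width = 320, height = 240, n_frames = n_frames, n_vessels = 2,
               blob_features = 20, seed = seed, ...)
}

# a match_set with prescribed descriptor distances and displacements
make_match_set <- function(distances, displacements = rep(0, length(distances)),
                           xa = NULL, ya = NULL, xb = NULL, yb = NULL) {
  n <- length(distances)
  if (is.null(xa)) { xa <- seq_len(n); ya <- rep(0, n) }
  if (is.null(xb)) { xb <- xa + displacements; yb <- ya }
  df <- data.frame(index_a = seq_len(n), index_b = seq_len(n),
                   distance = distances, displacement = displacements,
                   xa = xa, ya = ya, xb = xb, yb = yb)
  capiflow:::match_set_from_df(df)
}

# a match_set from explicit point correspondences (x, y matrices n x 2)
match_set_from_points <- function(A, B) {
  df <- data.frame(index_a = seq_len(nrow(A)), index_b = seq_len(nrow(A)),
                   distance = 0,
                   displacement = sqrt(rowSums((B - A)^2)),
                   xa = A[, 1], ya = A[, 2], xb = B[, 1], yb = B[, 2])
  capiflow:::match_set_from_df(df)
}

rotate_points <- function(P, theta_deg, center = c(0, 0)) {
  a <- theta_deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  sweep(sweep(P, 2, center) %*% t(R), 2, -center)
}
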