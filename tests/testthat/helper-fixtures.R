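# Shared fixtures: tiny pose series and peak sets built in code.

# A minimal valid pose array: L frames of the synthetic hand template with
# the index tip displaced by `dist` palm units from the thumb tip.
make_pose <- function(dist, fps = 60, palm = 1) {
  spec <- tap_spec(duration = length(dist) / fps, fps = fps, palm_size = palm)
  template <- tapscore:::hand_template() * palm
  L <- length(dist)
  coords <- array(rep(template, each = L), dim = c(L, 21L, 3L))
  coords[, 9L, 1] <- coords[, 5L, 1] + dist * palm
  coords[, 9L, 2] <- coords[, 5L, 2]
  coords[, 9L, 3] <- coords[, 5L, 3]
  hand_pose_series(coords, fps = fps)
}

# Peak set at regular spacing `gap` frames with given amplitudes.
make_peaks <- function(amplitudes, fps = 60, gap = 30) {
  peak_set(seq(1, by = gap, length.out = length(amplitudes)),
           amplitudes, fps)
}

# Random rigid transform (rotation + translation) applied to every frame.
rigid_transform <- function(coords, seed = 1) {
  set.seed(seed)
  M <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(M) < 0) M[, 1] <- -M[, 1]
  shift <- rnorm(3, sd = 5)
  out <- coords
  for (i in seq_len(dim(coords)[1])) {
    out[i, , ] <- coords[i, , ] %*% M + rep(shift, each = 21)
  }
  out
}

# Brute-force mean/population-variance oracle written as explicit loops,
# independent of the vectorized implementation.
oracle_mean_var <- function(x) {
  n <- length(x)
  s <- 0
  for (v in x) s <- s + v
  m <- s / n
  q <- 0
  for (v in x) q <- q + (v - m)^2
  c(mean = m, var = q / n)
}
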