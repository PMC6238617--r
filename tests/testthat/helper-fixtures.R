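# Shared fixtures. Everything is generated in code; no binary files.

# small scene for fast tests (the generator default 128 px is used where a
# test's statement demands it)
tiny_scene <- function(cell_radius = 3.2, nucleus_radius = 2.5, ...) {
  scene_spec(image_shape = c(96L, 96L), cell_radius = cell_radius,
             nucleus_radius = nucleus_radius, ...)
}

quiet_noise <- function(seed = 1L) {
  noise_spec(gaussian_sd = 0, shot_noise = FALSE, seed = seed)
}

# brute-force Otsu oracle: exhaustive search over candidate splits of the
# integer values, maximising between-class variance computed from the raw
# values. Returns the largest value assigned to the background class.
otsu_oracle_split <- function(v) {
  vals <- sort(unique(v))
  best <- -Inf
  best_cut <- vals[1L]
  for (cut in vals[-length(vals)]) {
    lo <- v[v <= cut]; hi <- v[v > cut]
    w0 <- length(lo) / length(v)
    sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-12) {  # strict: first (lowest) maximiser kept
      best <- sb
      best_cut <- cut
    }
  }
  best_cut
}

# deterministic pseudo-random integer matrix; restores the global RNG state
hash_matrix <- function(nr, nc, seed, max_val = 255L) {
  u <- polcoloc:::.with_seed(seed, stats::runif(nr * nc))
  matrix(floor(u * (max_val + 1L)), nr, nc)
}
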