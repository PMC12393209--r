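# Shared fixtures: reduced-size phantoms and schemes so unit tests stay fast.
# Geometry is scaled down (24-voxel grid, 8-16 mm annulus); tensor targets are
# the package defaults.

small_spec <- function(..., n_noise_frames = 64) {
  phantom_spec(grid_n = 24, inner_mm = 8, outer_mm = 16,
               n_noise_frames = n_noise_frames, ...)
}

quick_scheme <- function(repeats = 1, low_b_repeats = 2, seed = 1,
                         directions_per_shell = 30) {
  cardiac_dki_protocol(directions_per_shell = directions_per_shell,
                       repeats = repeats, low_b_repeats = low_b_repeats,
                       seed = seed)
}

# a uniformly random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# row normalization helper
.normalize_rows2 <- function(m) m / sqrt(rowSums(m^2))

# brute-force 81-term contraction sum_ijkl ni nj nk nl W_ijkl
contract_w_brute <- function(w15, n) {
  full <- cardiodki:::.w15_to_full(w15)
  s <- 0
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    s <- s + n[i] * n[j] * n[k] * n[l] * full[i, j, k, l]
  }
  s
}

# isotropic kurtosis tensor with Kapp = k in every direction (for isotropic D)
iso_w <- function(k) {
  w <- setNames(numeric(15), cardiodki:::.w_names)
  w[c("w1111", "w2222", "w3333")] <- k
  w[c("w1122", "w1133", "w2233")] <- k / 3
  w
}
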