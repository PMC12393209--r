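# Internal tensor bookkeeping and small numerical helpers.
#
# Conventions used throughout:
#   * b-values in s/mm^2, diffusivities in mm^2/s, kurtosis dimensionless.
#   * The diffusion tensor is stored as the length-6 vector
#     (d11, d22, d33, d12, d13, d23).
#   * The kurtosis tensor is stored as the 15 independent elements, in the
#     fixed order below; full index symmetry is implied.

.d_names <- c("d11", "d22", "d33", "d12", "d13", "d23")

# The 15 unique elements of a fully symmetric rank-4 tensor, with the number
# of distinct index permutations each represents (multiplicity).  The order is
# canonical for the whole package: design-matrix columns, fitted coefficients
# and phantom ground truth all use it.
.w_table <- data.frame(
  i = c(1, 2, 3, 1, 1, 1, 2, 1, 2, 1, 1, 2, 1, 1, 1),
  j = c(1, 2, 3, 1, 1, 2, 2, 3, 3, 1, 1, 2, 1, 2, 2),
  k = c(1, 2, 3, 1, 1, 2, 2, 3, 3, 2, 3, 3, 2, 2, 3),
  l = c(1, 2, 3, 2, 3, 2, 3, 3, 3, 2, 3, 3, 3, 3, 3),
  mult = c(1, 1, 1, 4, 4, 4, 4, 4, 4, 6, 6, 6, 12, 12, 12)
)
.w_table$name <- with(.w_table, paste0("w", i, j, k, l))

.w_names <- .w_table$name

#' Deterministic quasi-uniform directions on the sphere
#'
#' Spherical Fibonacci covering used for orientation averages (mean kurtosis).
#' Deterministic: no random number generation involved.
#'
#' @param n Number of directions.
#' @return An `n` x 3 matrix of unit vectors.
#' @keywords internal
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# row-normalize a matrix of 3-vectors
.normalize_rows <- function(m) {
  m / sqrt(rowSums(m^2))
}

.as_dir_matrix <- function(n) {
  if (is.null(dim(n))) n <- matrix(n, nrow = 1)
  stopifnot(ncol(n) == 3)
  n
}

.check_unit <- function(n, tol = 1e-8, what = "n") {
  n <- .as_dir_matrix(n)
  bad <- abs(sqrt(rowSums(n^2)) - 1) > tol
  if (any(bad)) {
    abort(sprintf("%s must be unit 3-vectors (row %d has norm %.8f)",
                  what, which(bad)[1], sqrt(sum(n[which(bad)[1], ]^2))))
  }
  invisible(n)
}

# 6-vector <-> symmetric 3x3
.d6_to_mat <- function(d) {
  matrix(c(d[1], d[4], d[5],
           d[4], d[2], d[6],
           d[5], d[6], d[3]), 3, 3)
}

.mat_to_d6 <- function(m) {
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
}

.as_d6 <- function(d) {
  if (is.matrix(d) && all(dim(d) == c(3, 3))) return(.mat_to_d6(d))
  stopifnot(length(d) == 6)
  as.numeric(d)
}

# quadratic design rows for directions: coefficients multiplying
# (d11, d22, d33, d12, d13, d23) in n' D n
.quad_design <- function(n) {
  n <- .as_dir_matrix(n)
  cbind(n[, 1]^2, n[, 2]^2, n[, 3]^2,
        2 * n[, 1] * n[, 2], 2 * n[, 1] * n[, 3], 2 * n[, 2] * n[, 3])
}

# quartic design rows: multiplicity-weighted monomials multiplying the 15
# unique W elements in sum_ijkl ni nj nk nl W_ijkl
.quartic_design <- function(n) {
  n <- .as_dir_matrix(n)
  out <- matrix(0, nrow(n), 15)
  for (m in seq_len(15)) {
    out[, m] <- .w_table$mult[m] *
      n[, .w_table$i[m]] * n[, .w_table$j[m]] *
      n[, .w_table$k[m]] * n[, .w_table$l[m]]
  }
  colnames(out) <- .w_names
  out
}

# cached maps between the 15 unique elements and the 81-entry full array
.w_cache <- new.env(parent = emptyenv())

.w_expand_matrix <- function() {
  if (is.null(.w_cache$expand)) {
    M <- matrix(0, 81, 15)
    for (m in seq_len(15)) {
      idx <- c(.w_table$i[m], .w_table$j[m], .w_table$k[m], .w_table$l[m])
      perms <- unique(.permutations4(idx))
      pos <- (perms[, 4] - 1) * 27 + (perms[, 3] - 1) * 9 +
        (perms[, 2] - 1) * 3 + perms[, 1]
      M[pos, m] <- 1
    }
    .w_cache$expand <- M
    .w_cache$reduce <- (.w_table$l - 1) * 27 + (.w_table$k - 1) * 9 +
      (.w_table$j - 1) * 3 + .w_table$i
  }
  .w_cache$expand
}

# expand 15 unique elements to the full 3x3x3x3 array
.w15_to_full <- function(w) {
  stopifnot(length(w) == 15)
  array(.w_expand_matrix() %*% as.numeric(w), c(3, 3, 3, 3))
}

# reduce a fully symmetric 3^4 array to the 15 unique elements
.full_to_w15 <- function(full) {
  .w_expand_matrix()
  setNames(as.vector(full)[.w_cache$reduce], .w_names)
}

# all permutations of a length-4 index vector (small fixed case)
.permutations4 <- function(x) {
  perms <- matrix(c(
    1, 2, 3, 4, 1, 2, 4, 3, 1, 3, 2, 4, 1, 3, 4, 2, 1, 4, 2, 3, 1, 4, 3, 2,
    2, 1, 3, 4, 2, 1, 4, 3, 2, 3, 1, 4, 2, 3, 4, 1, 2, 4, 1, 3, 2, 4, 3, 1,
    3, 1, 2, 4, 3, 1, 4, 2, 3, 2, 1, 4, 3, 2, 4, 1, 3, 4, 1, 2, 3, 4, 2, 1,
    4, 1, 2, 3, 4, 1, 3, 2, 4, 2, 1, 3, 4, 2, 3, 1, 4, 3, 1, 2, 4, 3, 2, 1
  ), ncol = 4, byrow = TRUE)
  matrix(x[perms], ncol = 4)
}

# rotate a diffusion tensor (6-vector) by rotation matrix R: D' = R D R'
.rotate_d6 <- function(R, d) {
  .mat_to_d6(R %*% .d6_to_mat(d) %*% t(R))
}

# rotate a kurtosis tensor (15 unique elements):
# W'_{abcd} = R_ai R_bj R_ck R_dl W_{ijkl}, via four cyclic mode products
.rotate_w15 <- function(R, w) {
  v <- as.vector(.w15_to_full(w))
  for (k in 1:4) {
    dim(v) <- c(3, 27)
    v <- as.vector(t(R %*% v))
  }
  .full_to_w15(array(v, c(3, 3, 3, 3)))
}

#' Minimum pairwise angle of a direction set
#'
#' Angles are computed between axes (antipodal pairs identified), in degrees.
#'
#' @param dirs Matrix of unit 3-vectors (one per row).
#' @return Smallest pairwise angle in degrees.
#' @export
min_pairwise_angle <- function(dirs) {
  dirs <- .check_unit(dirs, what = "dirs")
  g <- abs(dirs %*% t(dirs))
  g[g > 1] <- 1
  a <- acos(g) * 180 / pi
  min(a[upper.tri(a)])
}

# 1-D Gaussian kernel (unnormalized; normalization happens per-pixel so that
# truncated kernels at the image edge still average to one)
.gauss_kernel <- function(sigma_vox) {
  h <- max(1L, ceiling(4 * sigma_vox))
  x <- seq(-h, h)
  exp(-x^2 / (2 * sigma_vox^2))
}

# separable Gaussian smoothing of a 2-D matrix (numeric or complex) with
# per-pixel renormalization at the edges
.smooth2d <- function(img, sigma_vox) {
  k <- .gauss_kernel(sigma_vox)
  n1 <- nrow(img); n2 <- ncol(img)
  K1 <- .conv_matrix(n1, k)
  K2 <- .conv_matrix(n2, k)
  K1 %*% img %*% t(K2)
}

# banded row-stochastic convolution matrix for a 1-D kernel
.conv_matrix <- function(n, k) {
  h <- (length(k) - 1) / 2
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - h):(i + h)
    keep <- j >= 1 & j <= n
    M[i, j[keep]] <- k[keep]
    M[i, ] <- M[i, ] / sum(M[i, ])
  }
  M
}
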