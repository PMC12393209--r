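# Synthetic short-axis left-ventricle phantom: annular geometry, ground-truth
# tensor fields hitting prescribed global metrics, complex signal synthesis
# with smooth motion-like phase, Gaussian noise, noise-only frames and
# outlier injection.

#' Phantom specification
#'
#' Defines the geometry, ground-truth global metrics and noise conditions of
#' the synthetic LV study.  Defaults describe a mid-systolic human LV on a
#' 2.7 mm in-plane grid: three short-axis slices (base/mid/apex, mildly
#' tapered annuli), a linear transmural helix-angle ramp from +60 deg
#' (endocardium) to -60 deg (epicardium), globally homogeneous tensor targets
#' MD = 1.66e-3 mm^2/s, FA = 0.31, MK = 0.32, AK = 0.27, RK = 0.35, and an
#' SNR of 40 at b = 100 s/mm^2.
#'
#' @param grid_n In-plane grid size (voxels per side).
#' @param voxel_mm In-plane voxel spacing, mm.
#' @param n_slices Number of short-axis slices.
#' @param inner_mm,outer_mm Annulus radii at the mid slice, mm.
#' @param slice_taper Per-slice scale factors applied to both radii
#'   (recycled/truncated to `n_slices`).
#' @param ha_endo,ha_epi Helix angle at the endo- and epicardium, degrees.
#' @param target_md Ground-truth mean diffusivity, mm^2/s.
#' @param target_fa,target_mk,target_ak,target_rk Ground-truth FA / mean /
#'   axial / radial kurtosis (dimensionless).
#' @param transverse_split Relative secondary-eigenvalue split
#'   `(lambda2 - lambda3) / MD`; a small positive value keeps the sheetlet
#'   (e2) orientation well defined so E2A is recoverable.  The generating E2A
#'   is 0 everywhere (e2 along the cross-myocyte wall tangent, e3 radial-most).
#' @param s0 Non-diffusion-weighted signal level.
#' @param snr_b100 Target SNR (mean in-mask signal over sigma) at b = 100.
#' @param n_noise_frames Number of appended pure-noise frames.
#' @param phase_scale Multiplier on the random per-frame polynomial phase
#'   (0 disables phase).
#' @param seed Integer seed driving all randomness of the synthesis.
#' @return A `cdki_phantom_spec` list.
#' @export
phantom_spec <- function(grid_n = 36, voxel_mm = 2.7, n_slices = 3,
                         inner_mm = 10, outer_mm = 22,
                         slice_taper = c(1.05, 1, 0.9),
                         ha_endo = 60, ha_epi = -60,
                         target_md = 1.66e-3, target_fa = 0.31,
                         target_mk = 0.32, target_ak = 0.27,
                         target_rk = 0.35,
                         transverse_split = 0.02,
                         s0 = 1, snr_b100 = 40, n_noise_frames = 256,
                         phase_scale = 1, seed = 1) {
  if (inner_mm <= 0 || outer_mm <= inner_mm) {
    abort("annulus radii must satisfy 0 < inner_mm < outer_mm")
  }
  if (any(c(target_md, target_fa, target_mk, target_ak, target_rk) <= 0)) {
    abort("ground-truth targets must be positive")
  }
  if (snr_b100 <= 0) abort("snr_b100 must be positive")
  spec <- list(grid_n = grid_n, voxel_mm = voxel_mm, n_slices = n_slices,
               inner_mm = inner_mm, outer_mm = outer_mm,
               slice_taper = rep_len(slice_taper, n_slices),
               ha_endo = ha_endo, ha_epi = ha_epi,
               target_md = target_md, target_fa = target_fa,
               target_mk = target_mk, target_ak = target_ak,
               target_rk = target_rk,
               transverse_split = transverse_split,
               s0 = s0, snr_b100 = snr_b100,
               n_noise_frames = n_noise_frames,
               phase_scale = phase_scale, seed = seed)
  class(spec) <- "cdki_phantom_spec"
  spec
}

# eigenvalues (lambda1 >= lambda2 >= lambda3) matching MD and FA with a fixed
# transverse split (lambda2 - lambda3 = split * MD).  split = 0 has the
# closed form lambda_par = MD (1 + 2a), lambda_perp = MD (1 - a) with
# a = FA / sqrt(3 - 2 FA^2).
.solve_eigenvalues <- function(md, fa, split = 0) {
  if (split == 0) {
    a <- fa / sqrt(3 - 2 * fa^2)
    return(md * c(1 + 2 * a, 1 - a, 1 - a))
  }
  d <- split * md
  fa_of <- function(l1) {
    m <- (3 * md - l1) / 2
    lam <- c(l1, m + d / 2, m - d / 2)
    sqrt(1.5 * sum((lam - md)^2) / sum(lam^2))
  }
  l1 <- uniroot(function(l1) fa_of(l1) - fa, c(md * (1 + 1e-9), 2.999 * md),
                tol = 1e-15)$root
  m <- (3 * md - l1) / 2
  c(l1, m + d / 2, m - d / 2)
}

# transversely isotropic kurtosis tensor in the eigenframe (axis = 1):
# w[1] = W1111, w[2] = w[3] = W_perp (with W2233 = W_perp / 3), cross
# elements W1122 = W1133 = wc, all others zero
.w_eigenframe <- function(w_par, w_perp, wc) {
  w <- setNames(numeric(15), .w_names)
  w["w1111"] <- w_par
  w["w2222"] <- w["w3333"] <- w_perp
  w["w2233"] <- w_perp / 3
  w["w1122"] <- w["w1133"] <- wc
  w
}

# solve the eigenframe tensor pair hitting the (md, fa, ak, rk, mk) targets
.solve_truth_tensors <- function(spec) {
  lam <- .solve_eigenvalues(spec$target_md, spec$target_fa,
                            spec$transverse_split)
  md <- mean(lam)
  d_eigen <- c(lam, 0, 0, 0)
  w_par <- spec$target_ak * lam[1]^2 / md^2
  # radial kurtosis is the in-plane fan average MD^2 W_perp mean(1/Dapp^2)
  fan <- .perp_fan(c(1, 0, 0), 256)
  inv_da2 <- mean(1 / dapp(d_eigen, fan)^2)
  w_perp <- spec$target_rk / (md^2 * inv_da2)
  mk_of <- function(wc) {
    mean_kurtosis(d_eigen, .w_eigenframe(w_par, w_perp, wc), n_dirs = 10000)
  }
  lo <- -2; hi <- 3
  if ((mk_of(lo) - spec$target_mk) * (mk_of(hi) - spec$target_mk) > 0) {
    abort(sprintf(
      "target_mk = %.3f is outside the attainable range [%.3f, %.3f] for AK = %.3f, RK = %.3f",
      spec$target_mk, mk_of(lo), mk_of(hi), spec$target_ak, spec$target_rk))
  }
  wc <- uniroot(function(x) mk_of(x) - spec$target_mk, c(lo, hi),
                tol = 1e-12)$root
  list(lambda = lam, d_eigen = d_eigen,
       w_eigen = .w_eigenframe(w_par, w_perp, wc),
       w_par = w_par, w_perp = w_perp, w_cross = wc)
}

#' Build the phantom ground truth
#'
#' Constructs the annular myocardial mask, per-voxel wall frames, the linear
#' transmural helix-angle ramp, and per-voxel diffusion / kurtosis tensors in
#' image coordinates.  In the local myocyte frame the tensors are transversely
#' isotropic around the myocyte axis: the parallel kurtosis element is fixed
#' by the axial-kurtosis target, the perpendicular elements by the
#' radial-kurtosis target, and the parallel-perpendicular cross element is
#' root-found so the orientation-averaged kurtosis hits the mean-kurtosis
#' target.  Recovery of the targets from noiseless fits is then exact by
#' construction.
#'
#' @param spec A [phantom_spec()].
#' @return A `cdki_phantom` list: `spec`, logical `mask` array, wall
#'   `frames`, eigenframe `tensors`, and a `voxels` tibble holding per-voxel
#'   depth, generating `ha`, `s0`, `d11..d23` and `w1111..w1233`.
#' @export
build_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "cdki_phantom_spec"))
  n <- spec$grid_n
  ctr <- (n + 1) / 2
  xs <- (seq_len(n) - ctr) * spec$voxel_mm
  mask <- array(FALSE, c(n, n, spec$n_slices))
  rr <- outer(xs, xs, function(y, x) sqrt(x^2 + y^2))
  for (s in seq_len(spec$n_slices)) {
    tap <- spec$slice_taper[s]
    mask[, , s] <- rr >= spec$inner_mm * tap & rr <= spec$outer_mm * tap
  }
  frames <- build_frames(mask, spec$voxel_mm)
  tens <- .solve_truth_tensors(spec)

  inner <- spec$inner_mm * spec$slice_taper[frames$slice]
  outer_r <- spec$outer_mm * spec$slice_taper[frames$slice]
  depth <- (frames$radius_mm - inner) / (outer_r - inner)
  ha <- spec$ha_endo + depth * (spec$ha_epi - spec$ha_endo)

  nvox <- nrow(frames)
  dmat <- matrix(NA_real_, nvox, 6, dimnames = list(NULL, .d_names))
  wmat <- matrix(NA_real_, nvox, 15, dimnames = list(NULL, .w_names))
  ch <- as.matrix(frames[, c("cx", "cy", "cz")])
  rh <- as.matrix(frames[, c("rx", "ry", "rz")])
  zh <- as.matrix(frames[, c("zx", "zy", "zz")])
  har <- ha * pi / 180
  e1 <- cos(har) * ch + sin(har) * zh
  e2 <- .normalize_rows(.cross_rows(rh, e1))   # cross-myocyte wall tangent
  e3 <- .cross_rows(e1, e2)                    # radial-most (sheet normal)
  for (v in seq_len(nvox)) {
    R <- cbind(e1[v, ], e2[v, ], e3[v, ])
    dmat[v, ] <- .mat_to_d6(R %*% diag(tens$lambda) %*% t(R))
    wmat[v, ] <- .rotate_w15(R, tens$w_eigen)
  }
  voxels <- bind_cols(
    frames[, c("slice", "row", "col", "radius_mm")],
    tibble(depth = depth, ha = ha, e2a = 0, s0 = spec$s0),
    as_tibble(dmat), as_tibble(wmat))
  structure(list(spec = spec, mask = mask, frames = frames,
                 tensors = tens, voxels = voxels),
            class = "cdki_phantom")
}

# evaluate noiseless signals for truth voxels: ln S = X theta, exactly the
# DKI linear model
.truth_signals <- function(truth, scheme) {
  X <- dki_design_matrix(scheme, check_shells = FALSE)
  vx <- truth$voxels
  md <- rowMeans(as.matrix(vx[, c("d11", "d22", "d33")]))
  theta <- cbind(log(vx$s0), as.matrix(vx[, .d_names]),
                 as.matrix(vx[, .w_names]) * md^2)
  exp(theta %*% t(X))   # nvox x nmeas
}

# random low-order 2-D polynomial phase field on normalized [-1,1] coords
.random_phase <- function(n, scale) {
  u <- seq(-1, 1, length.out = n)
  cf <- c(runif(1, -pi, pi), rnorm(2, 0, pi / 2), rnorm(3, 0, pi / 4)) *
    c(1, rep(scale, 5))
  outer(u, u, function(y, x) {
    cf[1] + cf[2] * x + cf[3] * y + cf[4] * x^2 + cf[5] * x * y + cf[6] * y^2
  })
}

#' Synthesize a complex-valued DWI series from the phantom
#'
#' Per measurement, the complex image is
#' `S_true * exp(i phi) + (eps_r + i eps_i)` with a smooth random per-frame
#' polynomial phase `phi` (simulating motion-induced phase) and independent
#' zero-mean Gaussian noise of standard deviation sigma on both channels.
#' Sigma is chosen so that the mean in-mask true signal at the lowest shell
#' divided by sigma equals `spec$snr_b100` (`snr = Inf` gives a noiseless
#' series; the phase is still applied unless `spec$phase_scale = 0`).
#' `spec$n_noise_frames` pure-noise complex frames are appended for noise
#' estimation.  All randomness derives from `seed`.
#'
#' @param truth A [build_ground_truth()] result.
#' @param scheme A `cdki_scheme`.
#' @param snr Target SNR at the lowest shell; defaults to the spec value.
#' @param seed Seed; defaults to the spec seed.
#' @return A complex `cdki_series` list: `data` (ny x nx x n_slices x
#'   n_measurements), `noise_frames`, `mask`, `scheme`, `sigma` (true value
#'   used), `spec`.
#' @export
synthesize_series <- function(truth, scheme, snr = NULL, seed = NULL) {
  stopifnot(inherits(truth, "cdki_phantom"))
  spec <- truth$spec
  snr <- snr %||% spec$snr_b100
  seed <- seed %||% spec$seed
  n <- spec$grid_n; ns <- spec$n_slices; nmeas <- nrow(scheme)
  S <- .truth_signals(truth, scheme)
  blo <- min(scheme$bval)
  sigma <- if (is.finite(snr)) {
    mean(S[, scheme$bval == blo]) / snr
  } else 0
  vx <- truth$voxels
  lin <- cbind(vx$row, vx$col, vx$slice)
  data <- array(complex(real = 0), c(n, n, ns, nmeas))
  withr::with_seed(seed, {
    for (m in seq_len(nmeas)) {
      for (s in seq_len(ns)) {
        ph <- if (spec$phase_scale > 0) .random_phase(n, spec$phase_scale) else
          matrix(0, n, n)
        frame <- matrix(complex(real = 0), n, n)
        sel <- lin[, 3] == s
        frame[lin[sel, 1:2, drop = FALSE]] <- S[sel, m]
        frame <- frame * exp(1i * ph)
        if (sigma > 0) {
          frame <- frame + complex(real = rnorm(n * n, 0, sigma),
                                   imaginary = rnorm(n * n, 0, sigma))
        }
        data[, , s, m] <- frame
      }
    }
    noise <- array(complex(real = 0), c(n, n, ns, spec$n_noise_frames))
    if (sigma > 0) {
      nn <- length(noise)
      noise[] <- complex(real = rnorm(nn, 0, sigma),
                         imaginary = rnorm(nn, 0, sigma))
    }
    out <- list(data = data, noise_frames = noise, mask = truth$mask,
                scheme = scheme, sigma = sigma, spec = spec, seed = seed)
  })
  class(out) <- "cdki_series"
  out
}

#' Inject whole-frame signal-dropout outliers
#'
#' Multiplies randomly chosen whole measurement frames by `dropout_factor`
#' inside the mask, emulating motion-corrupted images.  The corrupted frame
#' indices are recorded in the returned series (`$corrupted`) so rejection
#' sensitivity and specificity can be scored.
#'
#' @param series A `cdki_series`.
#' @param fraction Fraction of frames to corrupt, `0 <= fraction < 0.2`
#'   (`floor(fraction * n_measurements)` frames).
#' @param dropout_factor Multiplicative dropout applied within the mask.
#' @param seed Integer seed for the frame choice.
#' @return The corrupted series with a `corrupted` integer vector.
#' @export
inject_outliers <- function(series, fraction, dropout_factor = 0.5, seed = 1) {
  stopifnot(inherits(series, "cdki_series"))
  if (fraction < 0 || fraction >= 0.2) abort("fraction must be in [0, 0.2)")
  nmeas <- dim(series$data)[4]
  k <- floor(fraction * nmeas)
  idx <- if (k > 0) withr::with_seed(seed, sort(sample.int(nmeas, k))) else
    integer(0)
  msk <- series$mask
  for (m in idx) {
    frame <- series$data[, , , m, drop = FALSE]
    dim(frame) <- dim(msk)
    frame[msk] <- frame[msk] * dropout_factor
    series$data[, , , m] <- frame
  }
  series$corrupted <- idx
  series
}

#' Extract the in-mask voxel x measurement signal matrix
#'
#' @param series A `cdki_series`.
#' @return Matrix of signals, voxels (rows, in [series_voxels()] order) by
#'   measurements.
#' @export
series_signal_matrix <- function(series) {
  idx <- which(series$mask, arr.ind = TRUE)
  nmeas <- dim(series$data)[4]
  out <- matrix(if (is.complex(series$data)) complex(real = NA) else NA_real_,
                nrow(idx), nmeas)
  for (m in seq_len(nmeas)) {
    frame <- series$data[, , , m, drop = FALSE]
    dim(frame) <- dim(series$mask)
    out[, m] <- frame[idx]
  }
  out
}

#' @rdname series_signal_matrix
#' @return `series_voxels()`: tibble of in-mask voxel coordinates
#'   (`slice`, `row`, `col`) matching the matrix rows.
#' @export
series_voxels <- function(series) {
  idx <- which(series$mask, arr.ind = TRUE)
  tibble(slice = idx[, 3], row = idx[, 1], col = idx[, 2])
}
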