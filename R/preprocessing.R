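# Preprocessing: phase removal to real-valued images, noise / SNR
# estimation, and robust outlier rejection.

# order-2 polynomial basis on normalized slice coordinates
.poly_basis <- function(n) {
  u <- seq(-1, 1, length.out = n)
  U <- matrix(rep(u, each = n), n, n)    # x varies over columns
  V <- matrix(rep(u, times = n), n, n)   # y varies over rows
  cbind(1, as.vector(U), as.vector(V),
        as.vector(U)^2, as.vector(U) * as.vector(V), as.vector(V)^2)
}

# Polynomial phase estimate fitted through wrapped finite differences.
#
# The non-constant coefficients are estimated by weighted least squares on
# the wrapped phase differences between horizontally and vertically adjacent
# pixels (valid while the true phase changes by < pi per pixel, which any
# smooth motion-induced field satisfies); differencing removes the 2*pi
# wrapping ambiguity that defeats a direct fit of Arg(I).  The constant term
# follows from the magnitude-weighted circular mean of the de-trended image,
# and one joint re-fit of the (now small) residual phase polishes all
# coefficients.  Exact for noiseless polynomial phase of the fitted order.
.phase_fit_context <- function(n) {
  B <- .poly_basis(n)
  i1 <- as.vector(outer(seq_len(n), seq_len(n - 1), function(r, c) (c - 1) * n + r))
  pairs_x <- cbind(i1, i1 + n)            # horizontal neighbours
  i2 <- as.vector(outer(seq_len(n - 1), seq_len(n), function(r, c) (c - 1) * n + r))
  pairs_y <- cbind(i2, i2 + 1)            # vertical neighbours
  pairs <- rbind(pairs_x, pairs_y)
  DB <- B[pairs[, 2], -1, drop = FALSE] - B[pairs[, 1], -1, drop = FALSE]
  list(B = B, pairs = pairs, DB = DB, n = n)
}

.poly_phase_fit <- function(img, ctx) {
  n <- ctx$n; B <- ctx$B; pairs <- ctx$pairs
  w <- as.vector(Mod(img))^2
  if (!any(w > 0)) return(matrix(0, n, n))
  v <- as.vector(img)
  dphi <- Arg(v[pairs[, 2]] * Conj(v[pairs[, 1]]))
  wp <- w[pairs[, 1]] * w[pairs[, 2]]
  beta <- .wls_solve(ctx$DB, dphi, wp)
  if (is.null(beta)) beta <- numeric(ncol(B) - 1)
  phi <- as.vector(B[, -1, drop = FALSE] %*% beta)
  phi <- phi + Arg(sum(w * v * exp(-1i * phi)))
  # joint polish: residuals are now far from the wrap, a plain WLS applies
  for (it in 1:2) {
    r <- Arg(v * exp(-1i * phi))
    upd <- .wls_solve(B, r, w)
    if (is.null(upd)) break
    phi <- phi + as.vector(B %*% upd)
  }
  matrix(phi, n, n)
}

#' Phase-correct a complex series to real-valued images
#'
#' Per measurement and slice, the smooth background phase is estimated and
#' removed: the image is multiplied by the conjugate unit phase and the real
#' part kept.  With `poly_order = 2` (default) the phase model is a
#' second-order 2-D polynomial fitted by magnitude-weighted least squares on
#' the wrapped phase differences of adjacent pixels (immune to 2*pi wrapping
#' and exact for smooth low-order phase where the magnitude is non-zero);
#' with `poly_order = 0` the phase is the argument of the Gaussian low-pass
#' filtered complex image (kernel FWHM `kernel_fwhm` mm), the classical
#' smoothing estimator, which carries a small bias where the magnitude
#' varies across the kernel (tissue borders).  The noise statistics of the
#' output remain zero-mean Gaussian with the input sigma (a phase rotation
#' of circular complex noise).
#'
#' @param series A complex `cdki_series`.
#' @param kernel_fwhm Gaussian kernel full width at half maximum, mm.
#' @param poly_order 0 (no refinement) or 2.
#' @return The series with `data` replaced by the real-valued images.
#' @export
phase_correct_real <- function(series, kernel_fwhm = 12, poly_order = 2) {
  stopifnot(inherits(series, "cdki_series"))
  if (!is.complex(series$data)) abort("series is already real-valued")
  n <- dim(series$data)[1]
  fov <- n * series$spec$voxel_mm
  if (kernel_fwhm > fov) {
    abort(sprintf("kernel_fwhm (%g mm) exceeds the field of view (%g mm)",
                  kernel_fwhm, fov))
  }
  sigma_vox <- kernel_fwhm / (2 * sqrt(2 * log(2))) / series$spec$voxel_mm
  ctx <- if (poly_order > 0) .phase_fit_context(n) else NULL
  ns <- dim(series$data)[3]; nmeas <- dim(series$data)[4]
  real_data <- array(NA_real_, dim(series$data))
  for (m in seq_len(nmeas)) {
    for (s in seq_len(ns)) {
      img <- series$data[, , s, m]
      phi <- if (is.null(ctx)) Arg(.smooth2d(img, sigma_vox)) else
        .poly_phase_fit(img, ctx)
      real_data[, , s, m] <- Re(img * exp(-1i * phi))
    }
  }
  series$data <- real_data
  series
}

#' Estimate the noise standard deviation from noise-only frames
#'
#' Per-voxel standard deviation (unbiased, n - 1 normalization) of the real
#' part over frames, summarized as the mean over the mask (or over all voxels
#' when no mask is available).
#'
#' @param x A `cdki_series` (uses its `noise_frames` and mask) or a 4-D array
#'   of noise frames (last dimension = frames).
#' @param mask Optional logical array overriding the series mask.
#' @return Estimated sigma (scalar).
#' @export
estimate_sigma <- function(x, mask = NULL) {
  frames <- if (inherits(x, "cdki_series")) x$noise_frames else x
  if (inherits(x, "cdki_series") && is.null(mask)) mask <- x$mask
  nf <- dim(frames)[4]
  if (is.null(nf) || nf < 2) abort("at least 2 noise frames are required")
  re <- Re(frames)
  dim(re) <- c(prod(dim(frames)[1:3]), nf)
  sds <- sqrt(rowSums((re - rowMeans(re))^2) / (nf - 1))
  if (!is.null(mask)) sds <- sds[as.vector(mask)]
  mean(sds)
}

#' Per-shell SNR summary
#'
#' Per voxel and direction the signal is averaged over repeats, divided by
#' sigma, then averaged over the directions of each shell; the summary is the
#' in-mask mean and SD per b-value.  Computed on the phase-corrected
#' real-valued data, before outlier rejection.
#'
#' @param series A real-valued `cdki_series`.
#' @param sigma Noise level; estimated from the series' noise frames when
#'   omitted.
#' @return Tibble with `bval`, `n_directions`, `snr_mean`, `snr_sd`.
#' @export
snr_summary <- function(series, sigma = NULL) {
  stopifnot(inherits(series, "cdki_series"))
  if (is.complex(series$data)) abort("run phase_correct_real() first")
  sigma <- sigma %||% estimate_sigma(series)
  if (sigma <= 0) abort("sigma must be positive")
  S <- series_signal_matrix(series)
  sch <- series$scheme
  shells <- sort(unique(sch$bval))
  out <- vector("list", length(shells))
  for (k in seq_along(shells)) {
    rows <- which(sch$bval == shells[k])
    dirs <- unique(sch$direction_id[rows])
    per_dir <- sapply(dirs, function(d) {
      rep_cols <- rows[sch$direction_id[rows] == d]
      rowMeans(S[, rep_cols, drop = FALSE]) / sigma
    })
    per_vox <- rowMeans(per_dir)
    out[[k]] <- tibble(bval = shells[k], n_directions = length(dirs),
                       snr_mean = mean(per_vox), snr_sd = sd(per_vox))
  }
  bind_rows(out)
}

#' Robust rejection of corrupted measurement frames
#'
#' Per measurement frame, the in-mask mean log-signal residual against the
#' voxelwise median frame of its (shell, direction) group is computed; frames
#' whose residual deviates from the shell median by more than `z_threshold`
#' robust standard deviations (1.4826 MAD of the shell's residuals) are
#' flagged, and the procedure iterates once with flagged frames removed from
#' the reference medians.  Requires repeats (>= 3 per group for a meaningful
#' median).
#'
#' @param series A real-valued `cdki_series`.
#' @param z_threshold Robust z-score threshold (default 3).
#' @return Tibble with one row per measurement: `measurement`, `bval`,
#'   `direction_id`, `repeat_id`, `z`, `included`; the per-shell rejection
#'   count table is attached as attribute `"rejections"`.
#' @export
reject_outliers <- function(series, z_threshold = 3) {
  stopifnot(inherits(series, "cdki_series"))
  if (is.complex(series$data)) abort("run phase_correct_real() first")
  S <- series_signal_matrix(series)
  sch <- series$scheme
  nmeas <- nrow(sch)
  groups <- split(seq_len(nmeas), paste(sch$shell_id, sch$direction_id))
  included <- rep(TRUE, nmeas)
  zsc <- rep(NA_real_, nmeas)
  for (pass in 1:2) {
    resid <- rep(NA_real_, nmeas)
    for (g in groups) {
      use <- g[included[g]]
      # a dropout can drag the small-sample median enough to flag its whole
      # group on the first pass; fall back to the two least-suspicious
      # frames so the residual scale stays comparable across groups
      if (length(use) < 2) {
        use <- g[order(abs(zsc[g]))][seq_len(min(2, length(g)))]
      }
      ref <- apply(S[, use, drop = FALSE], 1, median)
      pos <- ref > 0
      for (m in g) {
        both <- pos & S[, m] > 0
        resid[m] <- mean(log(S[both, m]) - log(ref[both]))
      }
    }
    for (sh in unique(sch$shell_id)) {
      rows <- which(sch$shell_id == sh)
      ctr <- median(resid[rows])
      spread <- mad(resid[rows])   # 1.4826 * MAD
      z <- if (spread > 0) (resid[rows] - ctr) / spread else
        rep(0, length(rows))
      zsc[rows] <- z
      flagged <- abs(z) > z_threshold
      if (all(flagged)) {
        abort(sprintf("all frames of shell b = %g flagged as outliers (degenerate input)",
                      sch$bval[rows[1]]))
      }
      included[rows] <- !flagged
    }
  }
  out <- tibble(measurement = seq_len(nmeas), bval = sch$bval,
                direction_id = sch$direction_id, repeat_id = sch$repeat_id,
                z = zsc, included = included)
  attr(out, "rejections") <- out |>
    group_by(.data$bval) |>
    summarise(n_frames = n(), n_rejected = sum(!.data$included),
              .groups = "drop")
  out
}
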