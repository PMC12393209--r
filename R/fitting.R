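# Weighted linear least-squares estimation of DTI and DKI parameters.
#
# Estimator (both models): ordinary least squares on ln S gives an initial
# prediction; a second pass solves the weighted normal equations with weights
# equal to the squared *predicted* signals from the first pass.  This is the
# standard variance-stabilizing weighting for log-linearized diffusion fits
# and is robust to noisy observations (weighting by squared observed signals
# would couple the weights to the noise).  Non-positive signals - possible in
# phase-corrected real-valued data at low SNR - are excluded per measurement
# rather than floored, preserving the symmetry of the noise.

# column-equilibrated weighted least squares solve; returns NULL on rank
# deficiency
.wls_solve <- function(X, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  sc <- sqrt(colSums(X^2))
  sc[sc == 0] <- 1
  Xs <- sweep(X, 2, sc, "/")
  A <- crossprod(Xs, w * Xs)
  qa <- qr(A)
  if (qa$rank < ncol(X)) return(NULL)
  as.vector(qr.coef(qa, crossprod(Xs, w * y))) / sc
}

# two-pass WLS over a voxel x measurement signal matrix.
# Returns list(coef = nvox x p, ok, n_included, residuals, included).
.fit_wls_matrix <- function(S, X, included = NULL) {
  S <- as.matrix(S)
  nvox <- nrow(S); nmeas <- ncol(S); p <- ncol(X)
  if (nmeas != nrow(X)) {
    abort(sprintf("signal matrix has %d measurements but design has %d rows",
                  nmeas, nrow(X)))
  }
  if (is.null(included)) included <- rep(TRUE, nmeas)
  coefs <- matrix(NA_real_, nvox, p, dimnames = list(NULL, colnames(X)))
  ok <- rep(FALSE, nvox)
  n_inc <- integer(nvox)
  resid <- matrix(NA_real_, nvox, nmeas)
  inc_out <- matrix(FALSE, nvox, nmeas)
  for (v in seq_len(nvox)) {
    s <- S[v, ]
    use <- included & is.finite(s) & s > 0
    n_inc[v] <- sum(use)
    inc_out[v, ] <- use
    if (sum(use) < p) next
    Xi <- X[use, , drop = FALSE]
    y <- log(s[use])
    b0 <- .wls_solve(Xi, y)
    if (is.null(b0)) next
    w <- exp(2 * as.vector(Xi %*% b0))
    b1 <- .wls_solve(Xi, y, w)
    if (is.null(b1)) next
    coefs[v, ] <- b1
    resid[v, use] <- y - as.vector(Xi %*% b1)
    ok[v] <- is.finite(b1[1])   # ln S0 finite => S0 > 0
  }
  list(coef = coefs, ok = ok, n_included = n_inc,
       residuals = resid, included = inc_out)
}

# normalize the signal input: dwi_series (real), matrix, or vector.
# Returns list(S = nvox x nmeas matrix, voxels = coordinate tibble or NULL).
.signal_input <- function(signals) {
  if (inherits(signals, "cdki_series")) {
    if (is.complex(signals$data)) {
      abort("series is complex-valued; run phase_correct_real() first")
    }
    return(list(S = series_signal_matrix(signals),
                voxels = series_voxels(signals)))
  }
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  list(S = as.matrix(signals), voxels = NULL)
}

.subset_scheme <- function(scheme, subset_bvals, tol = 0.5) {
  if (is.null(subset_bvals)) return(rep(TRUE, nrow(scheme)))
  keep <- rep(FALSE, nrow(scheme))
  for (b in subset_bvals) {
    hit <- abs(scheme$bval - b) <= tol
    if (!any(hit)) abort(sprintf("scheme has no shell at b = %g s/mm^2", b))
    keep <- keep | hit
  }
  keep
}

.fit_result_tibble <- function(fit, voxels, extra = NULL) {
  out <- if (is.null(voxels)) tibble(voxel = seq_along(fit$ok)) else voxels
  out <- bind_cols(out, as_tibble(fit$coef))
  if (!is.null(extra)) out <- bind_cols(out, as_tibble(extra))
  out$ok <- fit$ok
  out$n_included <- fit$n_included
  out
}

#' Weighted least-squares DTI fit
#'
#' Fits `ln S = ln S0 - b n' D n` by two-pass WLS, optionally restricted to a
#' subset of shells (e.g. `subset_bvals = c(100, 450)`).  One row per voxel is
#' returned with the fitted `s0`, tensor elements, an `ok` validity flag
#' (FALSE for rank-deficient designs or non-positive S0) and the number of
#' included measurements.  Per-measurement log-residuals and inclusion masks
#' are attached as attributes `"residuals"` and `"included"` (columns indexed
#' by the retained measurements, attribute `"measurements"`).
#'
#' @param signals A real-valued `cdki_series`, a voxel x measurement matrix,
#'   or a single voxel's signal vector.
#' @param scheme The matching `cdki_scheme`.
#' @param subset_bvals Optional b-values to restrict the fit to (requires at
#'   least two distinct values and six directions at the highest one).
#' @param included Optional logical per-measurement inclusion mask (length of
#'   the full scheme), e.g. from [reject_outliers()].
#' @return A `cdki_dti_fit` tibble.
#' @export
fit_dti_wls <- function(signals, scheme, subset_bvals = NULL, included = NULL) {
  inp <- .signal_input(signals)
  keep <- .subset_scheme(scheme, subset_bvals)
  if (!is.null(included)) keep <- keep & included
  sub <- scheme[keep, , drop = FALSE]
  if (length(unique(sub$bval)) < 2) {
    abort("DTI subset must span at least 2 distinct b-values")
  }
  bmax <- max(sub$bval)
  ndir <- length(unique(sub$direction_id[sub$bval == bmax]))
  if (ndir < 6) {
    abort(sprintf("DTI subset has only %d directions at b = %g; at least 6 are required", ndir, bmax))
  }
  X <- dti_design_matrix(sub)
  fit <- .fit_wls_matrix(inp$S[, keep, drop = FALSE], X)
  coefs <- fit$coef
  out <- .fit_result_tibble(
    list(coef = cbind(s0 = exp(coefs[, 1]),
                      coefs[, .d_names, drop = FALSE]),
         ok = fit$ok, n_included = fit$n_included),
    inp$voxels)
  attr(out, "scheme") <- sub
  attr(out, "measurements") <- which(keep)
  attr(out, "residuals") <- fit$residuals
  attr(out, "included") <- fit$included
  attr(out, "subset_bvals") <- subset_bvals %||% sort(unique(sub$bval))
  class(out) <- c("cdki_dti_fit", "cdki_fit", class(out))
  out
}

#' Weighted least-squares DKI fit
#'
#' Fits the 22-parameter kurtosis signal model by two-pass WLS.  The linear
#' coefficients are `(ln S0, D, MD^2 W)`; the kurtosis tensor is recovered by
#' dividing the quartic coefficients by the fitted MD squared.  Voxels with a
#' rank-deficient design, non-finite signals or non-positive fitted MD are
#' flagged `ok = FALSE` and the fit continues over the remaining voxels.
#'
#' @inheritParams fit_dti_wls
#' @return A `cdki_dki_fit` tibble with columns `s0`, the six tensor
#'   elements, the 15 kurtosis-tensor elements and validity bookkeeping.
#' @export
fit_dki_wls <- function(signals, scheme, subset_bvals = NULL, included = NULL) {
  inp <- .signal_input(signals)
  keep <- .subset_scheme(scheme, subset_bvals)
  if (!is.null(included)) keep <- keep & included
  sub <- scheme[keep, , drop = FALSE]
  if (length(unique(sub$bval[sub$bval > 0])) < 2) {
    abort("DKI requires at least 2 distinct non-zero b-values")
  }
  if (nrow(sub) < 22) abort("DKI requires at least 22 usable measurements")
  X <- dki_design_matrix(sub)
  if (qr(X)$rank < 22) {
    abort("direction set does not span the 15 independent quartic forms (design matrix rank-deficient)")
  }
  fit <- .fit_wls_matrix(inp$S[, keep, drop = FALSE], X)
  coefs <- fit$coef
  dmat <- coefs[, .d_names, drop = FALSE]
  md <- rowMeans(dmat[, 1:3, drop = FALSE])
  wmat <- coefs[, .w_names, drop = FALSE] / md^2
  bad_md <- !is.na(md) & md <= 0
  wmat[bad_md, ] <- NA_real_
  fit$ok <- fit$ok & !bad_md
  out <- .fit_result_tibble(
    list(coef = cbind(s0 = exp(coefs[, 1]), dmat, wmat),
         ok = fit$ok, n_included = fit$n_included),
    inp$voxels)
  attr(out, "scheme") <- sub
  attr(out, "measurements") <- which(keep)
  attr(out, "residuals") <- fit$residuals
  attr(out, "included") <- fit$included
  attr(out, "subset_bvals") <- subset_bvals %||% sort(unique(sub$bval))
  class(out) <- c("cdki_dki_fit", "cdki_fit", class(out))
  out
}

#' One-dimensional ADC / kurtosis fits along a single direction
#'
#' `fit_adc_1d()` fits `ln S = ln S0 - b Dapp` (two-pass WLS); with
#' `kurtosis = TRUE` it fits the 1-D quadratic cumulant form
#' `ln S = ln S0 - b Dapp + (1/6) b^2 Dapp^2 Kapp`.
#'
#' @param signals Signal vector.
#' @param bvals Matching b-values, s/mm^2.
#' @param kurtosis Include the quadratic kurtosis term?
#' @return A one-row tibble with `s0`, `dapp` and (if requested) `kapp`.
#' @export
fit_adc_1d <- function(signals, bvals, kurtosis = FALSE) {
  stopifnot(length(signals) == length(bvals))
  use <- is.finite(signals) & signals > 0
  X <- if (kurtosis) cbind(1, -bvals[use], bvals[use]^2 / 6) else
    cbind(1, -bvals[use])
  if (sum(use) < ncol(X)) abort("not enough positive signals for the 1-D fit")
  y <- log(signals[use])
  b0 <- .wls_solve(X, y)
  if (is.null(b0)) abort("1-D design is rank-deficient (repeated b-values?)")
  w <- exp(2 * as.vector(X %*% b0))
  b1 <- .wls_solve(X, y, w)
  out <- tibble(s0 = exp(b1[1]), dapp = b1[2])
  if (kurtosis) out$kapp <- b1[3] / b1[2]^2
  out
}
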