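# Forward DKI signal model and per-direction apparent quantities.
#
# The cumulant expansion truncated at the kurtosis term reads, per direction n
# and b-value b,
#
#   ln S(n, b) = ln S0 - b * Dapp(n) + (1/6) b^2 MD^2 * W(n)
#              = ln S0 - b * Dapp(n) + (1/6) b^2 Dapp(n)^2 * Kapp(n)
#
# with Dapp(n) = n' D n, W(n) = sum_ijkl ni nj nk nl W_ijkl and
# Kapp(n) = MD^2 / Dapp(n)^2 * W(n).  The two quadratic-term forms are
# algebraically identical; both are implemented and tested against each other.

#' Voxel signal model
#'
#' Bundles the non-diffusion-weighted signal S0 (> 0), a diffusion tensor and
#' an optional kurtosis tensor.
#'
#' @param s0 Signal at b = 0, arbitrary units, positive.
#' @param d Diffusion tensor: symmetric 3x3 matrix or length-6 vector
#'   (d11, d22, d33, d12, d13, d23), mm^2/s.
#' @param w Kurtosis tensor: length-15 vector of unique elements in canonical
#'   order, or `NULL` for a Gaussian (DTI) model.
#' @return A `cdki_model` list.
#' @export
voxel_model <- function(s0, d, w = NULL) {
  if (s0 <= 0) abort("s0 must be positive")
  d <- .as_d6(d)
  if (!is.null(w)) {
    stopifnot(length(w) == 15)
    w <- setNames(as.numeric(w), .w_names)
  }
  structure(list(s0 = s0, d = setNames(d, .d_names), w = w),
            class = "cdki_model")
}

#' Apparent diffusion coefficient along a direction
#'
#' @param d Diffusion tensor (3x3 matrix or length-6 vector), mm^2/s.
#' @param n Unit direction(s): length-3 vector or matrix with one per row.
#' @return Numeric vector of `n' D n`, mm^2/s.
#' @export
dapp <- function(d, n) {
  n <- .check_unit(n)
  as.vector(.quad_design(n) %*% .as_d6(d))
}

#' Apparent kurtosis along a direction
#'
#' `Kapp(n) = MD^2 / Dapp(n)^2 * sum_ijkl ni nj nk nl W_ijkl`, with
#' `MD = tr(D) / 3`.  Where `Dapp <= 0` (possible for non-physical fitted
#' tensors) the kurtosis is undefined and `NA` is returned rather than
#' raising an error.
#'
#' @inheritParams dapp
#' @param w Kurtosis tensor (15 unique elements, canonical order).
#' @return Numeric vector, dimensionless; `NA` where undefined.
#' @export
kapp <- function(d, w, n) {
  n <- .check_unit(n)
  d <- .as_d6(d)
  md <- sum(d[1:3]) / 3
  da <- as.vector(.quad_design(n) %*% d)
  wn <- as.vector(.quartic_design(n) %*% as.numeric(w))
  out <- md^2 / da^2 * wn
  out[da <= 0] <- NA_real_
  out
}

#' Predict DKI signals for a scheme
#'
#' @param model A [voxel_model()].
#' @param scheme A `cdki_scheme`.
#' @param method `"tensor"` evaluates the MD^2-scaled tensor form through the
#'   design matrix; `"apparent"` evaluates `S0 exp(-b Dapp + b^2 Dapp^2 Kapp / 6)`
#'   per measurement.  The two are algebraically identical.
#' @return Numeric vector of predicted signals, one per measurement.
#' @export
predict_signal <- function(model, scheme, method = c("tensor", "apparent")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "cdki_model"), nrow(scheme) > 0)
  w <- model$w %||% rep(0, 15)
  if (method == "tensor") {
    X <- dki_design_matrix(scheme, check_shells = FALSE)
    md <- sum(model$d[1:3]) / 3
    theta <- c(log(model$s0), model$d, md^2 * w)
    return(as.vector(exp(X %*% theta)))
  }
  nvec <- .scheme_bvecs(scheme)
  b <- scheme$bval
  da <- dapp(model$d, nvec)
  ka <- kapp(model$d, w, nvec)
  model$s0 * exp(-b * da + (1 / 6) * b^2 * da^2 * ka)
}

#' DKI design matrix (22 columns)
#'
#' Rows are measurements; the coefficient vector solving
#' `X theta = ln S` is `theta = (ln S0, D11, D22, D33, D12, D13, D23,
#' MD^2 W1111, ..., MD^2 W1233)`:
#'
#' * column 1: intercept (ln S0);
#' * columns 2-7: `-b` times the quadratic direction monomials
#'   `(n1^2, n2^2, n3^2, 2 n1 n2, 2 n1 n3, 2 n2 n3)`;
#' * columns 8-22: `b^2 / 6` times the multiplicity-weighted quartic monomials
#'   for the 15 unique kurtosis-tensor elements in canonical order, so the
#'   corresponding coefficients are `MD^2 W_ijkl` (the kurtosis tensor is
#'   recovered by dividing by the fitted MD squared).
#'
#' Estimating all 22 parameters requires at least 22 measurements spanning at
#' least two distinct non-zero b-values.
#'
#' @param scheme A `cdki_scheme`.
#' @param check_shells Require two distinct non-zero shells (default `TRUE`).
#' @return A numeric matrix, measurements x 22.
#' @export
dki_design_matrix <- function(scheme, check_shells = TRUE) {
  if (check_shells && length(unique(scheme$bval[scheme$bval > 0])) < 2) {
    abort("DKI requires at least 2 distinct non-zero b-values; the kurtosis columns are rank-deficient otherwise")
  }
  nvec <- .scheme_bvecs(scheme)
  b <- scheme$bval
  X <- cbind(1, -b * .quad_design(nvec), (b^2 / 6) * .quartic_design(nvec))
  colnames(X) <- c("ln_s0", .d_names, .w_names)
  X
}

#' DTI design matrix (7 columns)
#'
#' Columns: intercept, then `-b` times the quadratic direction monomials; the
#' coefficient vector is `(ln S0, D11, D22, D33, D12, D13, D23)`.
#'
#' @param scheme A `cdki_scheme`.
#' @return A numeric matrix, measurements x 7.
#' @export
dti_design_matrix <- function(scheme) {
  nvec <- .scheme_bvecs(scheme)
  X <- cbind(1, -scheme$bval * .quad_design(nvec))
  colnames(X) <- c("ln_s0", .d_names)
  X
}
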