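# Left-ventricular wall coordinate frames and the helix / secondary
# eigenvector angle maps.
#
# Conventions (short-axis acquisition):
#   * the LV long axis is the slice normal z (toward base);
#   * per voxel, r-hat is the in-plane unit vector pointing outward from the
#     slice's mask centroid, c-hat = z-hat x r-hat is circumferential, so
#     (r-hat, c-hat, z-hat) is right-handed;
#   * helix angle (HA): signed angle, in the tangential (c-z) plane, between
#     the projection of the primary eigenvector and the circumferential
#     direction, positive toward +z; the eigenvector sign is first flipped so
#     its circumferential component is non-negative (antipodal ambiguity);
#   * E2A: signed angle, in the cross-myocyte plane (orthogonal to e1),
#     between e2 and the wall-tangent direction of that plane, i.e. the unit
#     vector orthogonal to both e1 and r-hat; positive toward the radial-most
#     (sheet-normal) direction, with e2 first flipped so its wall-tangent
#     component is non-negative.  Range (-90, 90] degrees.

#' Build per-voxel LV wall frames from an annular mask
#'
#' The LV center of each slice is the mask centroid; each in-mask voxel gets
#' an orthonormal right-handed triad (radial, circumferential, longitudinal).
#' A slice whose mask is empty, or whose centroid does not fall in the cavity
#' (i.e. the mask is not an annulus around its centroid), is an error naming
#' the slice.
#'
#' @param mask Logical array `ny x nx x n_slices` (or `ny x nx` for one slice).
#' @param voxel_mm In-plane voxel spacing, mm.
#' @return A `cdki_frames` tibble with one row per in-mask voxel: `slice`,
#'   `row`, `col`, transmural radius `radius_mm`, and the triad components
#'   `rx, ry, rz, cx, cy, cz, zx, zy, zz`.
#' @export
build_frames <- function(mask, voxel_mm = 1) {
  if (length(dim(mask)) == 2) dim(mask) <- c(dim(mask), 1)
  ns <- dim(mask)[3]
  out <- vector("list", ns)
  for (s in seq_len(ns)) {
    msk <- mask[, , s]
    idx <- which(msk, arr.ind = TRUE)
    if (nrow(idx) == 0) abort(sprintf("slice %d: mask is empty", s))
    ctr <- colMeans(idx)
    if (isTRUE(msk[round(ctr[1]), round(ctr[2])])) {
      abort(sprintf("slice %d: mask centroid lies inside the mask; expected an annulus around a cavity", s))
    }
    dy <- (idx[, 1] - ctr[1]) * voxel_mm
    dx <- (idx[, 2] - ctr[2]) * voxel_mm
    r <- sqrt(dx^2 + dy^2)
    if (any(r < 1e-9)) abort(sprintf("slice %d: voxel coincides with the LV center", s))
    out[[s]] <- tibble(
      slice = s, row = idx[, 1], col = idx[, 2],
      radius_mm = r,
      rx = dx / r, ry = dy / r, rz = 0,
      cx = -dy / r, cy = dx / r, cz = 0,   # c = z x r
      zx = 0, zy = 0, zz = 1
    )
  }
  out <- bind_rows(out)
  class(out) <- c("cdki_frames", class(out))
  out
}

# internal: row-wise cross product
.cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Helix angle of the primary eigenvector
#'
#' @param e1 Primary eigenvector(s): length-3 vector or n x 3 matrix (rows
#'   matched to `frames` rows).
#' @param frames A [build_frames()] tibble (or the rows of one).
#' @return Helix angle in degrees, in `[-90, 90]`; `NA` where the eigenvector
#'   is purely radial (tangential projection below 1e-6).
#' @export
helix_angle <- function(e1, frames) {
  e1 <- .as_dir_matrix(e1)
  ch <- as.matrix(frames[, c("cx", "cy", "cz")])
  zh <- as.matrix(frames[, c("zx", "zy", "zz")])
  pc <- rowSums(e1 * ch)
  pz <- rowSums(e1 * zh)
  flip <- pc < 0
  pc[flip] <- -pc[flip]; pz[flip] <- -pz[flip]
  ha <- atan2(pz, pc) * 180 / pi
  ha[sqrt(pc^2 + pz^2) < 1e-6] <- NA_real_
  ha
}

#' Secondary eigenvector (sheetlet) angle
#'
#' @param e2 Secondary eigenvector(s), unit, orthogonal to `e1`.
#' @param e1 Primary eigenvector(s).
#' @param frames A [build_frames()] tibble.
#' @return E2A in degrees, in `(-90, 90]`; `NA` where the cross-myocyte
#'   wall-tangent direction is undefined (`e1` parallel to the radial axis).
#' @export
e2a_angle <- function(e2, e1, frames) {
  e1 <- .as_dir_matrix(e1)
  e2 <- .as_dir_matrix(e2)
  rh <- as.matrix(frames[, c("rx", "ry", "rz")])
  tang <- .cross_rows(rh, e1)            # orthogonal to both r-hat and e1
  tn <- sqrt(rowSums(tang^2))
  bad <- tn < 1e-6
  tn[bad] <- 1
  tang <- tang / tn
  snorm <- .cross_rows(e1, tang)         # radial-most direction in the plane
  pt <- rowSums(e2 * tang)
  ps <- rowSums(e2 * snorm)
  flip <- pt < 0 | (abs(pt) < 1e-12 & ps < 0)
  pt[flip] <- -pt[flip]; ps[flip] <- -ps[flip]
  e2a <- atan2(ps, pt) * 180 / pi
  e2a[bad] <- NA_real_
  e2a
}

#' Append HA and E2A maps to a fitted scalar table
#'
#' Joins wall frames onto a fitted tibble carrying eigenvector columns (from
#' [dti_scalars()] / [dki_scalar_maps()]) and computes helix and secondary
#' eigenvector angles per voxel.
#'
#' @param maps Fitted tibble with `slice`, `row`, `col` and eigenvector
#'   columns.
#' @param frames A [build_frames()] tibble over the same mask.
#' @return `maps` with `ha` and `e2a` columns appended.
#' @export
add_angle_maps <- function(maps, frames) {
  key <- c("slice", "row", "col")
  fr <- frames[match(interaction(maps$slice, maps$row, maps$col),
                     interaction(frames$slice, frames$row, frames$col)), ]
  if (anyNA(fr$rx)) abort("maps contain voxels without a wall frame")
  e1 <- as.matrix(maps[, c("e1x", "e1y", "e1z")])
  e2 <- as.matrix(maps[, c("e2x", "e2y", "e2z")])
  maps$ha <- helix_angle(e1, fr)
  maps$e2a <- e2a_angle(e2, e1, fr)
  maps
}
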