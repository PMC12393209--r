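# NIfTI and sidecar I/O for synthetic studies and scalar maps.

#' Write a DWI series to NIfTI with gradient tables and a JSON sidecar
#'
#' Complex data are stored as paired `_real` / `_imag` volumes; real-valued
#' data as a single volume.  The mask, the FSL-style bval/bvec pair and a
#' JSON sidecar (sigma, seed, phantom spec) are written next to them.
#'
#' @param series A `cdki_series`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return The directory, invisibly.
#' @export
write_dwi_series <- function(series, dir, prefix = "dwi") {
  stopifnot(inherits(series, "cdki_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vdim <- rep(series$spec$voxel_mm, 3)
  p <- function(...) file.path(dir, paste0(prefix, ...))
  if (is.complex(series$data)) {
    RNifti::writeNifti(RNifti::asNifti(Re(series$data), pixdim = vdim),
                       p("_real.nii"))
    RNifti::writeNifti(RNifti::asNifti(Im(series$data), pixdim = vdim),
                       p("_imag.nii"))
  } else {
    RNifti::writeNifti(RNifti::asNifti(series$data, pixdim = vdim),
                       p(".nii"))
  }
  RNifti::writeNifti(RNifti::asNifti(series$mask * 1, pixdim = vdim),
                     p("_mask.nii"))
  write_gradient_table(series$scheme, file.path(dir, prefix))
  side <- list(sigma = series$sigma, seed = series$seed,
               spec = unclass(series$spec))
  jsonlite::write_json(side, p("_sidecar.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Write scalar metric maps as NIfTI volumes
#'
#' One volume per metric column, with `NaN` outside the mask.
#'
#' @param maps Fitted tibble with `slice`, `row`, `col` and metric columns.
#' @param mask Logical array `ny x nx x n_slices` the maps live on.
#' @param dir Output directory.
#' @param metrics Columns to write.
#' @param voxel_mm Voxel spacing, mm.
#' @return The directory, invisibly.
#' @export
write_scalar_maps <- function(maps, mask, dir,
                              metrics = intersect(
                                c("md", "fa", "mk", "ak", "rk", "ha", "e2a"),
                                names(maps)),
                              voxel_mm = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lin <- cbind(maps$row, maps$col, maps$slice)
  for (met in metrics) {
    vol <- array(NaN, dim(mask))
    vol[lin] <- maps[[met]]
    RNifti::writeNifti(RNifti::asNifti(vol, pixdim = rep(voxel_mm, 3)),
                       file.path(dir, paste0(met, ".nii")))
  }
  invisible(dir)
}
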