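# broom-style tidiers for fitted objects.

#' Tidy a tensor fit
#'
#' Returns one row per voxel and parameter with columns `term` and
#' `estimate` (plus the voxel coordinates).
#'
#' @param x A `cdki_fit` tibble.
#' @param ... Unused.
#' @return A long tibble.
#' @export
tidy.cdki_fit <- function(x, ...) {
  keys <- intersect(c("voxel", "slice", "row", "col"), names(x))
  params <- intersect(c("s0", .d_names, .w_names), names(x))
  tidyr::pivot_longer(as_tibble(x)[, c(keys, params)], dplyr::all_of(params),
                      names_to = "term", values_to = "estimate")
}

#' Summarise a tensor fit in one row
#'
#' @param x A `cdki_fit` tibble.
#' @param ... Unused.
#' @return A one-row tibble: number of voxels, fraction valid, mean MD and FA
#'   over valid voxels, and the model order.
#' @export
glance.cdki_fit <- function(x, ...) {
  sc <- dti_scalars(as_tibble(x[x$ok, ]))
  tibble(
    n_voxels = nrow(x),
    frac_ok = mean(x$ok),
    md_mean = mean(sc$md, na.rm = TRUE),
    fa_mean = mean(sc$fa, na.rm = TRUE),
    model = if (inherits(x, "cdki_dki_fit")) "dki" else "dti"
  )
}

#' Tidy a study report
#'
#' @param x A `cdki_study` from [run_full_study()].
#' @param ... Unused.
#' @return The per-subject global DKI metric table (one row per subject), or
#'   the per-subject bmax table when kurtosis maps were not computed.
#' @export
tidy.cdki_study <- function(x, ...) {
  x$per_subject_dki %||% x$per_subject_bmax %||% x$per_subject_subsets
}

#' One-row summary of a study report
#'
#' @param x A `cdki_study`.
#' @param ... Unused.
#' @return A one-row tibble with group means of the DKI metrics and the
#'   radial-minus-axial kurtosis contrast.
#' @export
glance.cdki_study <- function(x, ...) {
  out <- tibble(n_subjects = x$config$n_subjects)
  if (!is.null(x$table_dki)) {
    out <- bind_cols(out, x$table_dki[, c("md_mean_grp", "fa_mean_grp",
                                          "mk_mean_grp", "ak_mean_grp",
                                          "rk_mean_grp")])
    out$rk_minus_ak <- x$rk_minus_ak$mean
    out$rk_minus_ak_p <- x$rk_minus_ak$p_value
  }
  out
}

#' @export
print.cdki_study <- function(x, ...) {
  cat("Synthetic cardiac DKI study:", x$config$n_subjects, "subjects",
      if (x$config$noisy) "(noisy)" else "(noiseless)", "\n")
  if (!is.null(x$table_bmax)) {
    cat("\nDTI by maximum b-value (MD in 1e-3 mm^2/s):\n")
    print(x$table_bmax)
  }
  if (!is.null(x$table_dki)) {
    cat("\nGlobal DKI metrics (group mean):\n")
    print(x$table_dki)
    cat("\nRK - AK:\n")
    print(x$rk_minus_ak)
  }
  invisible(x)
}
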