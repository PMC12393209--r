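# Diffusion-encoding schemes: construction, validation and FSL-style I/O.

#' Build an acquisition scheme from b-values and directions
#'
#' An acquisition scheme is a tibble with one row per measurement and columns
#' `bval` (s/mm^2), `bx`, `by`, `bz` (unit encoding direction, expressed in
#' image coordinates), `shell_id`, `direction_id` and `repeat_id`.  Directions
#' must be unit vectors; an all-zero direction is only admitted for `bval = 0`.
#'
#' @param bvals Numeric vector of b-values, s/mm^2, all `>= 0`.
#' @param bvecs Matrix of encoding directions, one row per measurement.
#' @param shell_id Optional integer shell labels; derived from unique b-values
#'   when omitted.
#' @param seed Optional integer recorded as the scheme's direction seed.
#' @return A `cdki_scheme` tibble.
#' @export
acquisition_scheme <- function(bvals, bvecs, shell_id = NULL, seed = NULL) {
  bvecs <- .as_dir_matrix(bvecs)
  if (length(bvals) != nrow(bvecs)) {
    abort(sprintf(
      "b-value/direction count mismatch: %d b-values but %d directions",
      length(bvals), nrow(bvecs)))
  }
  if (any(bvals < 0)) abort("b-values must be non-negative")
  nrm <- sqrt(rowSums(bvecs^2))
  zero_ok <- nrm < 1e-12 & bvals == 0
  bad <- !zero_ok & abs(nrm - 1) > 1e-8
  if (any(bad)) {
    abort(sprintf("direction %d is not unit norm (|n| = %.8f)",
                  which(bad)[1], nrm[which(bad)[1]]))
  }
  if (is.null(shell_id)) {
    shell_id <- match(bvals, sort(unique(bvals)))
  }
  sch <- tibble(
    bval = as.numeric(bvals),
    bx = bvecs[, 1], by = bvecs[, 2], bz = bvecs[, 3],
    shell_id = as.integer(shell_id)
  )
  # direction/repeat bookkeeping: identical (shell, direction) rows are repeats
  key <- paste(sch$shell_id,
               signif(sch$bx, 9), signif(sch$by, 9), signif(sch$bz, 9))
  sch$direction_id <- as.integer(stats::ave(seq_along(key), sch$shell_id,
    FUN = function(ix) match(key[ix], unique(key[ix]))))
  sch$repeat_id <- as.integer(stats::ave(seq_along(key), key, FUN = seq_along))
  attr(sch, "seed") <- seed
  class(sch) <- c("cdki_scheme", class(sch))
  sch
}

#' Generate diffusion directions by electrostatic repulsion
#'
#' Minimizes the Coulomb energy of `n` antipodally symmetric point pairs on
#' the unit sphere, starting from a seeded random configuration.  The result
#' is deterministic for a fixed seed and well spread (for `n = 30` the minimum
#' pairwise axis angle exceeds 15 degrees).
#'
#' @param n Number of directions.
#' @param seed Integer seed for the random initialization.
#' @param maxit Maximum BFGS iterations.
#' @return An `n` x 3 matrix of unit vectors.
#' @export
generate_directions <- function(n, seed = 1, maxit = 300) {
  stopifnot(n >= 1)
  key <- paste(n, seed, maxit, sep = "_")
  cached <- .dir_cache[[key]]
  if (!is.null(cached)) return(cached)
  init <- withr::with_seed(seed, matrix(rnorm(3 * n), n, 3))
  init <- .normalize_rows(init)
  if (n == 1) return(init)
  energy <- function(v) {
    m <- .normalize_rows(matrix(v, ncol = 3))
    e <- 0
    for (a in seq_len(n - 1)) {
      db <- t(m[(a + 1):n, , drop = FALSE])
      d1 <- sqrt(colSums((m[a, ] - db)^2))
      d2 <- sqrt(colSums((m[a, ] + db)^2))
      e <- e + sum(1 / pmax(d1, 1e-9) + 1 / pmax(d2, 1e-9))
    }
    e
  }
  fit <- optim(as.vector(init), energy, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-12))
  out <- .normalize_rows(matrix(fit$par, ncol = 3))
  .dir_cache[[key]] <- out
  out
}

# memoized direction sets: the optimization is deterministic per
# (n, seed, maxit), so repeated protocol constructions reuse the result
.dir_cache <- new.env(parent = emptyenv())

#' The five-shell cardiac DKI protocol
#'
#' Shells at b = 100, 450, 900, 1200 and 1350 s/mm^2.  The lowest shell uses 3
#' directions with 12 repeats; each higher shell uses `directions_per_shell`
#' directions with `repeats` repeats (defaults 30 and 6, i.e. 36 + 720 = 756
#' measurements).  Direction sets are produced by seeded electrostatic
#' repulsion, the same set being reused across the four high shells.  There is
#' no b = 0 measurement: S0 is always a fitted parameter.
#'
#' @param directions_per_shell Directions per high-b shell (`>= 6`).
#' @param repeats Repeats per direction on the high-b shells.
#' @param seed Integer seed for direction generation.
#' @param bvals Shell b-values, lowest first.
#' @param low_b_directions,low_b_repeats Layout of the lowest shell.
#' @return A `cdki_scheme` tibble.
#' @export
cardiac_dki_protocol <- function(directions_per_shell = 30, repeats = 6,
                                 seed = 1,
                                 bvals = c(100, 450, 900, 1200, 1350),
                                 low_b_directions = 3, low_b_repeats = 12) {
  if (directions_per_shell < 6) {
    abort("directions_per_shell must be >= 6: the diffusion tensor is not identifiable from fewer directions")
  }
  dirs_hi <- generate_directions(directions_per_shell, seed = seed)
  dirs_lo <- generate_directions(low_b_directions, seed = seed + 1L)
  blo <- bvals[1]
  bhi <- bvals[-1]
  b <- c(rep(blo, low_b_directions * low_b_repeats),
         rep(bhi, each = directions_per_shell * repeats))
  v <- rbind(dirs_lo[rep(seq_len(low_b_directions), each = low_b_repeats), ],
             do.call(rbind, rep(list(
               dirs_hi[rep(seq_len(directions_per_shell), each = repeats), ]
             ), length(bhi))))
  acquisition_scheme(b, v, seed = seed)
}

.scheme_bvecs <- function(scheme) {
  cbind(scheme$bx, scheme$by, scheme$bz)
}

#' Write / read FSL-style gradient tables
#'
#' `write_gradient_table()` writes `<prefix>.bval` and `<prefix>.bvec`
#' (whitespace-separated text; the bvec file holds three rows x, y, z) plus a
#' JSON descriptor `<prefix>.json` with the seed and shell table.
#' `read_gradient_table()` reads the pair back into a scheme; a mismatch
#' between the number of b-values and directions is a format error naming both
#' counts.
#'
#' @param scheme A `cdki_scheme`.
#' @param prefix Path prefix for the output files.
#' @return `write_gradient_table()` returns the prefix invisibly;
#'   `read_gradient_table()` returns a `cdki_scheme`.
#' @export
write_gradient_table <- function(scheme, prefix) {
  bv <- sprintf("%.0f", scheme$bval)
  writeLines(paste(bv, collapse = " "), paste0(prefix, ".bval"))
  vec <- .scheme_bvecs(scheme)
  lines <- apply(t(vec), 1, function(r) paste(sprintf("%.10f", r), collapse = " "))
  writeLines(lines, paste0(prefix, ".bvec"))
  shells <- scheme |>
    group_by(.data$shell_id) |>
    summarise(bval = .data$bval[1],
              n_directions = length(unique(.data$direction_id)),
              n_measurements = n(), .groups = "drop")
  jsonlite::write_json(
    list(seed = attr(scheme, "seed"), shells = shells),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_gradient_table
#' @export
read_gradient_table <- function(prefix) {
  bvals <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  rows <- lapply(readLines(paste0(prefix, ".bvec")), function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  rows <- rows[lengths(rows) > 0]
  if (length(rows) != 3) abort("bvec file must contain exactly 3 rows (x, y, z)")
  nvec <- unique(lengths(rows))
  if (length(nvec) != 1 || nvec != length(bvals)) {
    abort(sprintf(
      "gradient table mismatch: %d b-values but %d directions",
      length(bvals), min(lengths(rows))))
  }
  seed <- NULL
  jpath <- paste0(prefix, ".json")
  if (file.exists(jpath)) {
    seed <- jsonlite::read_json(jpath)$seed
  }
  acquisition_scheme(bvals, cbind(rows[[1]], rows[[2]], rows[[3]]), seed = seed)
}
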