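#' Solve the assembled Helmholtz system
#'
#' Factorizes the banded complex-symmetric matrix (in place, direct
#' LDL^T -- no iterative randomness; results are deterministic for a fixed
#' input) and returns the complex pressure amplitude on the grid. A system
#' can be solved repeatedly with different right-hand sides without
#' refactorizing.
#'
#' @param system A `tfus_system` from [assemble_system()].
#' @param rhs Optional alternative right-hand side (complex vector of
#'   length `Nr * Nz`); defaults to the system's source vector.
#' @return A `pressure_field`: complex pressure `p` (Nr x Nz matrix),
#'   grid coordinate vectors `r_m`, `z_m`, the operating frequency and
#'   the originating domain.
#' @export
solve_field <- function(system, rhs = NULL) {
  stopifnot(inherits(system, "tfus_system"))
  if (!system$factored) {
    .band_ldlt_factor(system$band)
    system$factored <- TRUE
  }
  b <- rhs %||% system$rhs
  x <- .band_ldlt_solve(system$band, b)
  if (any(!is.finite(Re(x)))) {
    abort("solver produced non-finite values; check grid resolution and PML settings")
  }
  dom <- system$domain
  structure(
    list(
      p = matrix(x, nrow = dom$Nr, ncol = dom$Nz),
      r_m = dom$rc,
      z_m = dom$zc,
      frequency_hz = system$transducer$center_frequency,
      domain = dom
    ),
    class = "pressure_field"
  )
}

#' Simulate a pressure field from a configuration
#'
#' Convenience wrapper: build the domain, assemble and solve.
#'
#' @param config A [sim_config()].
#' @return A `pressure_field`.
#' @examples
#' \donttest{
#' field <- simulate_field(sim_config())
#' }
#' @export
simulate_field <- function(config) {
  solve_field(assemble_system(build_domain(config)))
}

#' @export
print.pressure_field <- function(x, ...) {
  cat(sprintf(
    "Pressure field: %d x %d (r x z) at %.3g MHz, max |p| = %.4g\n",
    nrow(x$p), ncol(x$p), x$frequency_hz / 1e6, max(Mod(x$p))
  ))
  invisible(x)
}

#' @method as_tibble pressure_field
#' @export
as_tibble.pressure_field <- function(x, ..., include_pml = FALSE) {
  keep_r <- if (!include_pml && x$domain$r_pml) {
    x$r_m <= x$domain$config$radial_extent_m
  } else {
    rep(TRUE, length(x$r_m))
  }
  keep_z <- if (!include_pml) {
    x$z_m >= 0 & x$z_m <= x$domain$config$axial_extent_m
  } else {
    rep(TRUE, length(x$z_m))
  }
  p <- x$p[keep_r, keep_z, drop = FALSE]
  tibble(
    r = rep(x$r_m[keep_r], times = sum(keep_z)),
    z = rep(x$z_m[keep_z], each = sum(keep_r)),
    re = as.vector(Re(p)),
    im = as.vector(Im(p)),
    amplitude = as.vector(Mod(p))
  )
}

#' Write a solved field to disk
#'
#' Writes the complex field as a long-form CSV (`r, z, re, im`) plus a
#' JSON sidecar with the scalar focal metrics.
#'
#' @param field A `pressure_field`.
#' @param dir Output directory (created if missing).
#' @param stem File stem; produces `<stem>.csv` and `<stem>_metrics.json`.
#' @param z_min_m Passed to [focal_metrics()] for the sidecar.
#' @return Invisibly, the paths written.
#' @export
write_field <- function(field, dir, stem = "field", z_min_m = 0) {
  stopifnot(inherits(field, "pressure_field"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv_path <- file.path(dir, paste0(stem, ".csv"))
  json_path <- file.path(dir, paste0(stem, "_metrics.json"))
  tb <- as_tibble(field)
  utils::write.csv(tb[, c("r", "z", "re", "im")], csv_path, row.names = FALSE)
  fm <- focal_metrics(field, z_min_m = z_min_m)
  jsonlite::write_json(as.list(fm), json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}
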