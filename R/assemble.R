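# Discretization of div((1/rho_c) grad p) + omega^2 p / (rho_c c_c^2) = 0
# in cylindrical (r, z) coordinates on a cell-centered grid, unknowns
# ordered radius-fastest. Finite-volume face links are blended with a
# rotated-diagonal stencil (weight 1/3) and the mass term uses the
# sin-corrected wavenumber, which makes the numerical dispersion isotropic
# and fourth-order accurate. Complex coordinate stretching implements the
# absorbing layer; the axis r = 0 is a natural zero-flux face of the
# finite-volume scheme. The matrix is complex symmetric with lower
# bandwidth Nr + 1 and is stored as a band.

.GAMMA_ROT <- 1 / 3

#' Assemble the discrete Helmholtz system
#'
#' Builds the banded complex-symmetric matrix and the source vector for a
#' domain. The bowl source is a transparent monopole sheet on the
#' staircase approximation of the spherical cap: each cell's strength is
#' weighted by the ring area and the surface obliquity, phase-compensated
#' for the sub-cell offset between the cap surface and the cell center,
#' and scaled by the discrete-delta factor `sin(k h)/(k h)` so that the
#' radiated amplitude is grid-independent.
#'
#' @param domain A `tfus_domain` from [build_domain()].
#' @param transducer Optional [transducer_spec()] overriding the one in
#'   the domain's config.
#' @return A `tfus_system` environment with elements `band`, `rhs`,
#'   `domain`, `factored`.
#' @export
assemble_system <- function(domain, transducer = NULL) {
  stopifnot(inherits(domain, "tfus_domain"))
  cfg <- domain$config
  tr <- transducer %||% cfg$transducer
  Nr <- domain$Nr
  Nz <- domain$Nz
  h <- domain$h
  g <- .GAMMA_ROT
  N <- Nr * Nz

  rho <- domain$rho_z          # per z-cell (uniform in r)
  kz <- domain$k_z
  s_z_c <- domain$s_z_c
  s_z_f <- domain$s_z_f
  s_r_c <- domain$s_r_c
  s_r_f <- domain$s_r_f
  rt_c <- domain$rt_c
  rt_f <- domain$rt_f

  # --- link conductances (Nr x Nz matrices, (j, i) layout = band column order)
  # radial faces j <-> j+1 within axial cell i
  gr_j <- (1 - g) * rt_f[2:Nr] / s_r_f[2:Nr]            # length Nr-1
  GR <- outer(gr_j, s_z_c / rho)                        # (Nr-1) x Nz
  # axial faces i <-> i+1 at radius j
  rho_f <- (rho[-Nz] + rho[-1]) / 2
  GZ <- outer((1 - g) * rt_c * s_r_c, 1 / (rho_f * s_z_f[2:Nz]))  # Nr x (Nz-1)
  # rotated-diagonal links across face (i + 1/2, j + 1/2); both families
  rt_m <- (rt_c[-Nr] + rt_c[-1]) / 2                    # length Nr-1
  anis <- 0.5 * (outer(1 / s_r_f[2:Nr], s_z_f[2:Nz]) +
                   outer(s_r_f[2:Nr], 1 / s_z_f[2:Nz]))  # (Nr-1) x (Nz-1)
  GD <- (g / 2) * (rt_m * anis) * matrix(1 / rho_f, Nr - 1, Nz - 1, byrow = TRUE)
  # mirrored diagonal at the outer zero-flux wall -> extra axial link at j = Nr
  anis_w <- 0.5 * (s_z_f[2:Nz] / s_r_f[Nr + 1] + s_r_f[Nr + 1] / s_z_f[2:Nz])
  GW <- (g / 2) * rt_f[Nr + 1] * anis_w / rho_f         # length Nz-1

  # mass term with the stretch-aware sin-corrected wavenumber
  SE <- outer(s_r_c, s_z_c)                             # Nr x Nz
  KH <- matrix(kz, Nr, Nz, byrow = TRUE) * SE * h
  KS <- (2 / h * sin(KH / 2) / SE)^2
  MASS <- (rt_c * s_r_c) * KS * matrix(s_z_c * h * h / rho, Nr, Nz, byrow = TRUE)

  # --- accumulate the diagonal (negative sum of incident link conductances)
  diag_acc <- matrix(0+0i, Nr, Nz)
  diag_acc[seq_len(Nr - 1L), ] <- diag_acc[seq_len(Nr - 1L), ] - GR
  diag_acc[2:Nr, ] <- diag_acc[2:Nr, ] - GR
  diag_acc[, seq_len(Nz - 1L)] <- diag_acc[, seq_len(Nz - 1L)] - GZ
  diag_acc[, 2:Nz] <- diag_acc[, 2:Nz] - GZ
  diag_acc[seq_len(Nr - 1L), seq_len(Nz - 1L)] <-
    diag_acc[seq_len(Nr - 1L), seq_len(Nz - 1L)] - GD
  diag_acc[2:Nr, 2:Nz] <- diag_acc[2:Nr, 2:Nz] - GD
  diag_acc[2:Nr, seq_len(Nz - 1L)] <- diag_acc[2:Nr, seq_len(Nz - 1L)] - GD
  diag_acc[seq_len(Nr - 1L), 2:Nz] <- diag_acc[seq_len(Nr - 1L), 2:Nz] - GD
  diag_acc[Nr, seq_len(Nz - 1L)] <- diag_acc[Nr, seq_len(Nz - 1L)] - GW
  diag_acc[Nr, 2:Nz] <- diag_acc[Nr, 2:Nz] - GW

  # --- band storage: rows 1..Nr+2 = offsets 0, 1, Nr-1, Nr, Nr+1; the
  # remaining rows are structural zeros filled in by the factorization.
  # Each populated row is laid out as an (Nr x Nz) matrix so that its
  # vectorization matches the radius-fastest column order.
  zero_col <- rep(0+0i, Nr)
  zero_row <- rep(0+0i, Nz)
  GZW <- GZ
  GZW[Nr, ] <- GZW[Nr, ] + GW
  band <- .band_build(
    as.vector(diag_acc + MASS),
    as.vector(rbind(GR, zero_row)),                                          # offset 1
    as.vector(rbind(zero_row, cbind(GD, zero_col[seq_len(Nr - 1L)]))),       # offset Nr-1
    as.vector(cbind(GZW, zero_col)),                                         # offset Nr
    as.vector(rbind(cbind(GD, zero_col[seq_len(Nr - 1L)]), zero_row)),       # offset Nr+1
    Nr
  )

  rhs <- .source_vector(domain, tr)

  sys <- new.env(parent = emptyenv())
  sys$band <- band
  sys$rhs <- rhs
  sys$domain <- domain
  sys$transducer <- tr
  sys$factored <- FALSE
  class(sys) <- "tfus_system"
  sys
}

.source_vector <- function(domain, tr) {
  cfg <- domain$config
  Nr <- domain$Nr
  Nz <- domain$Nz
  h <- domain$h
  kw <- complex_medium(cfg$water, tr$center_frequency)$wavenumber
  corr <- sin(kw * h) / (kw * h)
  rhs <- complex(Nr * Nz)

  if (identical(cfg$source, "plane")) {
    i <- as.integer(round((cfg$source_plane_z_m - domain$z0) / h + 0.5))
    if (i < 1L || i > Nz) abort("plane source lies outside the domain")
    idx <- (i - 1L) * Nr + seq_len(Nr)
    rhs[idx] <- tr$drive_amplitude * domain$rt_c * h * corr
    return(rhs)
  }

  a <- tr$aperture_diameter / 2
  R <- tr$curvature_radius
  jset <- which(domain$rc <= a)
  if (length(jset) == 0L) abort("aperture smaller than one radial cell")
  r <- domain$rc[jset]
  zs <- tr$vertex_offset + R - sqrt(R^2 - r^2)
  i <- as.integer(round((zs - domain$z0) / h + 0.5))
  if (any(i < 1L | i > Nz)) abort("bowl cap lies outside the domain")
  zcell <- domain$zc[i]
  phase <- exp(-1i * kw * (zcell - zs))
  obliquity <- R / sqrt(R^2 - r^2)
  idx <- (i - 1L) * Nr + jset
  rhs[idx] <- rhs[idx] +
    tr$drive_amplitude * phase * domain$rt_c[jset] * h * obliquity * corr
  rhs
}

#' @export
print.tfus_system <- function(x, ...) {
  cat(sprintf(
    "Discrete Helmholtz system: %d unknowns, lower bandwidth %d, %s\n",
    ncol(x$band), nrow(x$band) - 1L,
    if (x$factored) "factored" else "unfactored"
  ))
  invisible(x)
}
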