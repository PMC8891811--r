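#' Plane-wave transfer-matrix transmission through a layer stack
#'
#' Closed-form lossy-layer transfer-matrix solution for a normally
#' incident plane wave passing through homogeneous layers between two
#' half-spaces. This is an independent verification oracle for the
#' discretized solver (quasi-1-D equivalence tests), not part of the
#' solver itself.
#'
#' @param layers Layer tibble (see [layer_stack()]); may have zero rows.
#' @param frequency Frequency in Hz.
#' @param half_space One-row medium tibble for both half-spaces
#'   (default: packaged water).
#' @return A one-row tibble with complex `transmission` and `reflection`
#'   pressure coefficients and their magnitudes.
#' @examples
#' transfer_matrix_1d(layer_stack(layer("skull", 0.005)), 1e6)
#' @export
transfer_matrix_1d <- function(layers, frequency,
                               half_space = medium("water", 1482, 998, 0)) {
  if (!is.data.frame(layers)) abort("`layers` must be a layer tibble (see layer_stack())")
  if (frequency <= 0) abort("`frequency` must be positive")
  omega <- 2 * pi * frequency
  z_imp <- function(m) {
    k <- complex_medium(m, frequency)$wavenumber
    m$density_kg_per_m3 * omega / k
  }
  z1 <- z_imp(half_space)
  m11 <- 1 + 0i; m12 <- 0 + 0i; m21 <- 0 + 0i; m22 <- 1 + 0i
  if (nrow(layers)) {
    for (li in seq_len(nrow(layers))) {
      row <- layers[li, ]
      k <- complex_medium(row, frequency)$wavenumber
      zi <- row$density_kg_per_m3 * omega / k
      kd <- k * row$thickness_m
      p11 <- cos(kd); p12 <- 1i * zi * sin(kd)
      p21 <- 1i * sin(kd) / zi; p22 <- cos(kd)
      n11 <- m11 * p11 + m12 * p21
      n12 <- m11 * p12 + m12 * p22
      n21 <- m21 * p11 + m22 * p21
      n22 <- m21 * p12 + m22 * p22
      m11 <- n11; m12 <- n12; m21 <- n21; m22 <- n22
    }
  }
  z2 <- z1  # identical half-spaces on both sides
  denom <- m11 * z2 + m12 + z1 * (m21 * z2 + m22)
  transmission <- 2 * z2 / denom
  reflection <- (m11 * z2 + m12 - z1 * (m21 * z2 + m22)) / denom
  tibble(
    transmission = transmission,
    reflection = reflection,
    transmission_abs = Mod(transmission),
    reflection_abs = Mod(reflection)
  )
}

#' Rayleigh-integral on-axis pressure of the bowl source
#'
#' Numerically integrates the free-field monopole-sheet (Rayleigh)
#' integral over the spherical cap to give the on-axis pressure amplitude
#' in water. This is the closed-form-style oracle used to verify the
#' focal position and axial profile of the discretized solver.
#'
#' @param z Axial positions in m (vector).
#' @param transducer A [transducer_spec()].
#' @param water One-row medium tibble.
#' @param n_quad Number of quadrature nodes over the cap polar angle.
#' @return Complex on-axis pressure (arbitrary source scaling), same
#'   length as `z`.
#' @export
rayleigh_axis_pressure <- function(z, transducer = transducer_spec(),
                                   water = medium("water", 1482, 998, 0),
                                   n_quad = 4000) {
  R <- transducer$curvature_radius
  a <- transducer$aperture_diameter / 2
  zv <- transducer$vertex_offset
  kw <- complex_medium(water, transducer$center_frequency)$wavenumber
  psi_max <- asin(a / R)
  psi <- seq(0, psi_max, length.out = n_quad)
  rs <- R * sin(psi)
  zs <- zv + R - R * cos(psi)
  w <- sin(psi)
  dpsi <- psi[2] - psi[1]
  vapply(z, function(zz) {
    d <- sqrt(rs^2 + (zz - zs)^2)
    integrand <- exp(-1i * kw * d) / d * w
    # trapezoid rule
    sum((integrand[-1] + integrand[-length(integrand)]) / 2) * dpsi
  }, complex(1))
}
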