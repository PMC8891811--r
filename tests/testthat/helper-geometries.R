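# Small geometries and shared oracles for the solver tests. The mini bowl
# (12 mm aperture, 30 mm curvature radius) keeps unit-test solves under a
# second while exercising the full scheme (PML, axis, source, layers).

mini_bowl_config <- function(..., h = 0.15e-3) {
  sim_config(
    transducer = transducer_spec(
      aperture_diameter = 0.012, curvature_radius = 0.030,
      vertex_offset = 0.0015
    ),
    grid_spacing_m = h,
    radial_extent_m = 0.009,
    axial_extent_m = 0.040,
    standoff_m = 0.008,
    ...
  )
}

# Quasi-1-D water column: rigid outer wall, transparent plane source,
# absorbing layers only on the axial ends. 8 points per water wavelength.
column_config <- function(layers = layer_stack(), h = 0.185e-3,
                          standoff_m = 0.020, ...) {
  sim_config(
    layers = layers,
    standoff_m = standoff_m,
    grid_spacing_m = h,
    radial_extent_m = 8 * h,
    axial_extent_m = 0.050,
    radial_boundary = "rigid",
    source = "plane",
    source_plane_z_m = 0.005,
    ...
  )
}

# Apply the assembled (unfactored) banded operator to a vector.
band_apply <- function(sys, x) {
  stopifnot(!sys$factored)
  band <- sys$band
  Nr <- sys$domain$Nr
  N <- ncol(band)
  offsets <- c(1L, Nr - 1L, Nr, Nr + 1L)
  y <- band[1L, ] * x
  for (d in offsets) {
    v <- band[d + 1L, ]
    lead <- seq_len(N - d)
    y[lead] <- y[lead] + v[lead] * x[lead + d]
    y[lead + d] <- y[lead + d] + v[lead] * x[lead]
  }
  y
}

# Column helpers: solve a column configuration and return the field.
solve_column <- function(layers = layer_stack(), h = 0.185e-3,
                         standoff_m = 0.020) {
  simulate_field(column_config(layers = layers, h = h, standoff_m = standoff_m))
}

# Mid-column radial index used when reading quasi-1-D profiles.
COLUMN_J <- 4L
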