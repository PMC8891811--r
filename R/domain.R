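#' Focused bowl transducer description
#'
#' @param center_frequency Operating frequency in Hz. Default 1 MHz.
#' @param aperture_diameter Aperture diameter in m. Default 46 mm.
#' @param curvature_radius Radius of curvature of the spherical cap in m.
#'   Default 110 mm, a weakly focused geometry whose rim rays meet a skull
#'   slab at ~12 degrees, comfortably below the water-to-skull critical
#'   angle (21.3 deg); see the methods vignette for why this matters.
#' @param vertex_offset Axial position of the bowl vertex in m.
#' @param drive_amplitude Source strength scale (arbitrary units until
#'   calibrated against a target focal pressure; see [calibrate_source()]).
#' @return A `transducer_spec` list.
#' @examples
#' transducer_spec()
#' @export
transducer_spec <- function(center_frequency = 1e6,
                            aperture_diameter = 0.046,
                            curvature_radius = 0.110,
                            vertex_offset = 0.002,
                            drive_amplitude = 1) {
  if (center_frequency <= 0) abort("`center_frequency` must be positive (Hz)")
  if (aperture_diameter <= 0) abort("`aperture_diameter` must be positive (m)")
  if (curvature_radius <= 0) abort("`curvature_radius` must be positive (m)")
  if (aperture_diameter > 2 * curvature_radius) {
    abort("`aperture_diameter` must be <= 2 * curvature_radius: a spherical cap must be geometrically realizable")
  }
  structure(
    list(
      center_frequency = center_frequency,
      aperture_diameter = aperture_diameter,
      curvature_radius = curvature_radius,
      vertex_offset = vertex_offset,
      drive_amplitude = drive_amplitude
    ),
    class = "transducer_spec"
  )
}

#' @export
print.transducer_spec <- function(x, ...) {
  cat(sprintf(
    "Focused bowl: f0 = %.3g MHz, aperture %.1f mm, curvature radius %.1f mm, drive %.4g\n",
    x$center_frequency / 1e6, x$aperture_diameter * 1e3,
    x$curvature_radius * 1e3, x$drive_amplitude
  ))
  invisible(x)
}

#' Build a layer stack for the propagation axis
#'
#' @param ... One or more layer descriptions, each a list/row created by
#'   [layer()].
#' @return A tibble with one row per layer.
#' @export
layer_stack <- function(...) {
  rows <- list(...)
  if (length(rows) == 0) {
    return(tibble(
      name = character(), speed_of_sound_mps = numeric(),
      density_kg_per_m3 = numeric(), attenuation_db_per_m = numeric(),
      thickness_m = numeric()
    ))
  }
  bind_rows(rows)
}

#' Describe one tissue layer
#'
#' @param material Packaged material name (see [tissue_materials()]) or a
#'   one-row medium tibble from [medium()].
#' @param thickness_m Layer thickness in m (> 0).
#' @return A one-row layer tibble.
#' @examples
#' layer("skull", 0.005)
#' @export
layer <- function(material, thickness_m) {
  m <- .as_medium_row(material)
  if (!is.numeric(thickness_m) || length(thickness_m) != 1L ||
      !is.finite(thickness_m) || thickness_m <= 0) {
    abort(sprintf("layer '%s': `thickness_m` must be a single positive number", m$name))
  }
  mutate(
    m[, c("name", "speed_of_sound_mps", "density_kg_per_m3", "attenuation_db_per_m")],
    thickness_m = thickness_m
  )
}

#' Simulation configuration
#'
#' Collects every knob of the axisymmetric Helmholtz simulation with the
#' packaged defaults. All defaults are also spelled out in the shipped
#' `default_config.yaml` (see [read_sim_config()]).
#'
#' @param transducer A [transducer_spec()].
#' @param layers Layer stack tibble (see [layer_stack()]); empty for a
#'   pure-water free-field run.
#' @param standoff_m Water gap between `z = 0` and the first layer's
#'   proximal face, in m.
#' @param grid_spacing_m Grid spacing in m; must satisfy the
#'   points-per-wavelength floor `h <= lambda_min / 8`. The default
#'   0.125 mm represents 0.5 mm sweep steps and 0.1 mm-precision site
#'   thicknesses exactly on the grid.
#' @param radial_extent_m Physical radial extent (excluding the absorbing
#'   layer), in m.
#' @param axial_extent_m Physical axial extent (excluding the absorbing
#'   layers), in m.
#' @param pml_wavelengths Absorbing-layer thickness in water wavelengths.
#' @param pml_target_reflection Theoretical normal-incidence reflection
#'   target used to scale the absorption profile.
#' @param pml_profile_order Polynomial grading order of the absorption
#'   profile (2 = quadratic).
#' @param radial_boundary `"pml"` (default) or `"rigid"` (zero-flux outer
#'   wall; used for quasi-1-D column tests).
#' @param source `"bowl"` (default) or `"plane"` (transparent uniform
#'   source plane, used for plane-wave column tests).
#' @param source_plane_z_m Axial position of the plane source when
#'   `source = "plane"`.
#' @param water One-row medium tibble for the background water
#'   (default 1482 m/s, 998 kg/m^3, lossless, 295.15 K).
#' @return A `tfus_config` list.
#' @examples
#' cfg <- sim_config(layers = layer_stack(layer("skull", 0.005)))
#' @export
sim_config <- function(transducer = transducer_spec(),
                       layers = layer_stack(),
                       standoff_m = 0.020,
                       grid_spacing_m = 0.125e-3,
                       radial_extent_m = 0.026,
                       axial_extent_m = 0.128,
                       pml_wavelengths = 1,
                       pml_target_reflection = 1e-4,
                       pml_profile_order = 2,
                       radial_boundary = c("pml", "rigid"),
                       source = c("bowl", "plane"),
                       source_plane_z_m = 0.005,
                       water = medium("water", 1482, 998, 0)) {
  radial_boundary <- match.arg(radial_boundary)
  source <- match.arg(source)
  if (!inherits(transducer, "transducer_spec")) abort("`transducer` must be a transducer_spec()")
  structure(
    list(
      transducer = transducer,
      layers = layers,
      standoff_m = standoff_m,
      grid_spacing_m = grid_spacing_m,
      radial_extent_m = radial_extent_m,
      axial_extent_m = axial_extent_m,
      pml_wavelengths = pml_wavelengths,
      pml_target_reflection = pml_target_reflection,
      pml_profile_order = pml_profile_order,
      radial_boundary = radial_boundary,
      source = source,
      source_plane_z_m = source_plane_z_m,
      water = water
    ),
    class = "tfus_config"
  )
}

#' Read a simulation configuration from YAML
#'
#' The file mirrors [sim_config()]: top-level sections `transducer`,
#' `grid`, `pml`, `layers` plus optional `water` and `source`. Layer
#' materials are resolved against the packaged material table, or against
#' a CSV named by `materials_file` with header
#' `name,speed_of_sound_mps,attenuation_db_per_m,density_kg_per_m3`.
#'
#' @param path Path to a YAML file; see the packaged
#'   `system.file("extdata", "default_config.yaml", package = "tfusatt")`.
#' @return A `tfus_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' not found", path))
  y <- yaml::read_yaml(path)
  mats <- if (!is.null(y$materials_file)) {
    as_tibble(read.csv(y$materials_file, stringsAsFactors = FALSE))
  } else {
    tissue_materials()
  }
  lookup <- function(nm) {
    row <- mats[mats$name == nm, ]
    if (nrow(row) != 1L) abort(sprintf("material '%s' not found in material table", nm))
    row[, c("name", "speed_of_sound_mps", "density_kg_per_m3", "attenuation_db_per_m")]
  }
  lay <- layer_stack()
  for (entry in y$layers %||% list()) {
    lay <- bind_rows(lay, layer(lookup(entry$material), entry$thickness_m))
  }
  tr <- y$transducer %||% list()
  gr <- y$grid %||% list()
  pm <- y$pml %||% list()
  wa <- y$water %||% list()
  water <- medium(
    "water",
    wa$speed_of_sound_mps %||% 1482,
    wa$density_kg_per_m3 %||% 998,
    wa$attenuation_db_per_m %||% 0
  )
  sim_config(
    transducer = transducer_spec(
      center_frequency = tr$center_frequency_hz %||% 1e6,
      aperture_diameter = tr$aperture_diameter_m %||% 0.046,
      curvature_radius = tr$curvature_radius_m %||% 0.110,
      vertex_offset = tr$vertex_offset_m %||% 0.002,
      drive_amplitude = tr$drive_amplitude %||% 1
    ),
    layers = lay,
    standoff_m = y$standoff_m %||% 0.020,
    grid_spacing_m = gr$spacing_m %||% 0.125e-3,
    radial_extent_m = gr$radial_extent_m %||% 0.026,
    axial_extent_m = gr$axial_extent_m %||% 0.128,
    pml_wavelengths = pm$wavelengths %||% 1,
    pml_target_reflection = pm$target_reflection %||% 1e-4,
    pml_profile_order = pm$profile_order %||% 2,
    radial_boundary = y$radial_boundary %||% "pml",
    source = y$source %||% "bowl",
    source_plane_z_m = y$source_plane_z_m %||% 0.005,
    water = water
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Discretize the computational domain
#'
#' Lays the tissue layers along the propagation axis (water between the
#' transducer and the first layer, water behind the stack), snaps layer
#' interfaces to grid faces, appends the absorbing layer on all open
#' boundaries and precomputes the complex coordinate-stretching profiles.
#'
#' @param config A [sim_config()].
#' @return A `tfus_domain` list holding the grids, per-cell complex
#'   material arrays, stretch profiles and the realized (snapped) layer
#'   table.
#' @examples
#' dom <- build_domain(sim_config(grid_spacing_m = 0.18e-3))
#' @export
build_domain <- function(config) {
  stopifnot(inherits(config, "tfus_config"))
  h <- config$grid_spacing_m
  if (!is.numeric(h) || h <= 0) abort("`grid_spacing_m` must be positive")
  f <- config$transducer$center_frequency
  cw <- config$water$speed_of_sound_mps
  lambda_w <- cw / f

  # points-per-wavelength floor over every medium present
  all_media <- bind_rows(
    config$water,
    if (nrow(config$layers)) config$layers[, names(config$water)] else NULL
  )
  lambda_min <- min(all_media$speed_of_sound_mps) / f
  if (h > lambda_min / 8) {
    worst <- all_media$name[which.min(all_media$speed_of_sound_mps)]
    abort(sprintf(
      "grid spacing %.4g mm is too coarse: medium '%s' needs h <= %.4g mm (8 points per wavelength)",
      h * 1e3, worst, lambda_min / 8 * 1e3
    ))
  }

  npml <- max(4L, as.integer(round(config$pml_wavelengths * lambda_w / h)))
  r_pml <- identical(config$radial_boundary, "pml")
  Nr <- as.integer(round(config$radial_extent_m / h)) + if (r_pml) npml else 0L
  Nz <- as.integer(round(config$axial_extent_m / h)) + 2L * npml
  if (Nr < 4L) abort("radial extent too small: fewer than 4 radial cells")
  z0 <- -npml * h

  rc <- (seq_len(Nr) - 0.5) * h
  zc <- z0 + (seq_len(Nz) - 0.5) * h
  rf <- (seq_len(Nr + 1L) - 1) * h
  zf <- z0 + (seq_len(Nz + 1L) - 1) * h

  # quadratic-graded absorption, sigma_max set from the target reflection
  Lp <- npml * h
  p_ord <- config$pml_profile_order
  smax <- -(p_ord + 1) * cw * log(config$pml_target_reflection) / (2 * Lp)
  omega <- 2 * pi * f
  sig <- function(d) smax * pmax(d / Lp, 0)^p_ord
  s_of_z <- function(z) 1 - 1i * sig(pmax(pmax(0 - z, z - config$axial_extent_m), 0)) / omega
  s_of_r <- if (r_pml) {
    function(r) 1 - 1i * sig(pmax(r - config$radial_extent_m, 0)) / omega
  } else {
    function(r) rep(1 + 0i, length(r))
  }

  s_z_c <- s_of_z(zc)
  s_z_f <- s_of_z(zf)
  s_r_c <- s_of_r(rc)
  s_r_f <- s_of_r(rf)
  # stretched radial coordinate (complex inside the radial absorber)
  rt_f <- c(0, cumsum(s_of_r((rf[-length(rf)] + rf[-1]) / 2) * h))
  rt_c <- (rt_f[-length(rt_f)] + rt_f[-1]) / 2

  # per-axial-cell media (layers are uniform in r)
  med_idx <- rep(1L, Nz) # 1 = water
  media <- list(config$water)
  realized <- config$layers
  if (nrow(config$layers)) {
    realized$z_start_m <- NA_real_
    realized$z_end_m <- NA_real_
    realized$realized_thickness_m <- NA_real_
    z_cursor <- config$standoff_m
    for (li in seq_len(nrow(config$layers))) {
      row <- config$layers[li, ]
      ia <- as.integer(round(z_cursor / h))            # proximal face index (from z = 0)
      ncell <- as.integer(round(row$thickness_m / h))
      if (ncell < 1L) {
        abort(sprintf(
          "layer '%s' (%.3g mm) is thinner than one grid cell (%.3g mm)",
          row$name, row$thickness_m * 1e3, h * 1e3
        ))
      }
      ib <- ia + ncell
      if (ib * h > config$axial_extent_m - lambda_w) {
        abort(sprintf(
          "layer '%s' ends at %.1f mm, beyond the axial extent minus a one-wavelength margin (%.1f mm)",
          row$name, ib * h * 1e3, (config$axial_extent_m - lambda_w) * 1e3
        ))
      }
      media[[length(media) + 1L]] <- row[, names(config$water)]
      med_idx[(npml + ia + 1L):(npml + ib)] <- length(media)
      realized$z_start_m[li] <- ia * h
      realized$z_end_m[li] <- ib * h
      realized$realized_thickness_m[li] <- ncell * h
      z_cursor <- ib * h
    }
  }

  cm <- purrr::map(media, complex_medium, frequency = f)
  rho_tab <- vapply(cm, function(m) m$complex_density, complex(1))
  k_tab <- vapply(cm, function(m) m$wavenumber, complex(1))

  structure(
    list(
      config = config,
      h = h, Nr = Nr, Nz = Nz, npml = npml, z0 = z0,
      r_pml = r_pml,
      rc = rc, zc = zc,
      s_z_c = s_z_c, s_z_f = s_z_f, s_r_c = s_r_c, s_r_f = s_r_f,
      rt_c = rt_c, rt_f = rt_f,
      med_idx = med_idx,
      rho_z = rho_tab[med_idx],
      k_z = k_tab[med_idx],
      layers = realized
    ),
    class = "tfus_domain"
  )
}

#' @export
print.tfus_domain <- function(x, ...) {
  cat(sprintf(
    "Axisymmetric domain: %d x %d cells (r x z), h = %.4g mm, absorber %d cells\n",
    x$Nr, x$Nz, x$h * 1e3, x$npml
  ))
  if (nrow(x$layers)) {
    for (i in seq_len(nrow(x$layers))) {
      cat(sprintf(
        "  layer %s: %.3f-%.3f mm (realized thickness %.3f mm)\n",
        x$layers$name[i], x$layers$z_start_m[i] * 1e3, x$layers$z_end_m[i] * 1e3,
        x$layers$realized_thickness_m[i] * 1e3
      ))
    }
  } else {
    cat("  pure water (free field)\n")
  }
  invisible(x)
}
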