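.physical_region <- function(field, z_min_m = NULL, z_max_m = NULL) {
  dom <- field$domain
  z_lo <- z_min_m %||% 0
  z_hi <- z_max_m %||% dom$config$axial_extent_m
  keep_z <- which(field$z_m >= z_lo & field$z_m <= z_hi)
  keep_r <- if (dom$r_pml) {
    which(field$r_m <= dom$config$radial_extent_m)
  } else {
    seq_along(field$r_m)
  }
  if (length(keep_z) == 0L || length(keep_r) == 0L) {
    abort("empty search region: no grid cells between `z_min_m` and `z_max_m`")
  }
  list(jr = keep_r, iz = keep_z)
}

#' Peak pressure over a search region
#'
#' Maximum of |p| over the physical domain (absorbing layers excluded),
#' optionally restricted along z. When measuring transcranial peaks the
#' region should start distal to the last strongly reflecting interface;
#' the experiment drivers do this automatically (see
#' [peak_search_start()]).
#'
#' @param field A `pressure_field`.
#' @param z_min_m,z_max_m Optional axial bounds of the search region (m).
#' @return A one-row tibble with `peak`, `z_m`, `r_m`.
#' @export
peak_pressure <- function(field, z_min_m = NULL, z_max_m = NULL) {
  stopifnot(inherits(field, "pressure_field"))
  reg <- .physical_region(field, z_min_m, z_max_m)
  sub <- Mod(field$p[reg$jr, reg$iz, drop = FALSE])
  ij <- arrayInd(which.max(sub), dim(sub))
  tibble(
    peak = sub[ij],
    z_m = field$z_m[reg$iz[ij[2]]],
    r_m = field$r_m[reg$jr[ij[1]]]
  )
}

.half_max_width <- function(coord, profile) {
  # linear-interpolated full width at half maximum around the profile peak
  ipk <- which.max(profile)
  half <- profile[ipk] / 2
  left <- NA_real_
  for (i in seq(ipk, 2L)) {
    if (profile[i - 1L] < half) {
      left <- approx(profile[c(i - 1L, i)], coord[c(i - 1L, i)], xout = half)$y
      break
    }
  }
  right <- NA_real_
  for (i in seq(ipk, length(profile) - 1L)) {
    if (profile[i + 1L] < half) {
      right <- approx(profile[c(i + 1L, i)], coord[c(i + 1L, i)], xout = half)$y
      break
    }
  }
  list(width = right - left, truncated = is.na(left) || is.na(right))
}

#' Focal-spot metrics
#'
#' Locates the field maximum and measures the axial and lateral full
#' widths at half maximum by linear interpolation along the profiles
#' through the peak. The lateral profile is mirrored across the axis
#' (`r -> -r`) before measuring, so an on-axis peak reports the full
#' lateral width. Widths whose half-maximum crossing leaves the grid are
#' flagged as truncated.
#'
#' @inheritParams peak_pressure
#' @return A one-row tibble: `peak`, `z_peak_m`, `r_peak_m`,
#'   `fwhm_axial_m`, `fwhm_lateral_m`, `axial_truncated`,
#'   `lateral_truncated`.
#' @export
focal_metrics <- function(field, z_min_m = NULL, z_max_m = NULL) {
  stopifnot(inherits(field, "pressure_field"))
  reg <- .physical_region(field, z_min_m, z_max_m)
  sub <- Mod(field$p[reg$jr, reg$iz, drop = FALSE])
  ij <- arrayInd(which.max(sub), dim(sub))
  jpk <- reg$jr[ij[1]]
  ipk <- reg$iz[ij[2]]

  axial <- .half_max_width(field$z_m[reg$iz], Mod(field$p[jpk, reg$iz]))
  lat_profile <- Mod(field$p[reg$jr, ipk])
  lat_coord <- field$r_m[reg$jr]
  lat <- .half_max_width(c(-rev(lat_coord), lat_coord), c(rev(lat_profile), lat_profile))

  tibble(
    peak = sub[ij],
    z_peak_m = field$z_m[ipk],
    r_peak_m = field$r_m[jpk],
    fwhm_axial_m = axial$width,
    fwhm_lateral_m = lat$width,
    axial_truncated = axial$truncated,
    lateral_truncated = lat$truncated
  )
}

#' Start of the transcranial peak-search region
#'
#' Returns the axial position distal to the last strongly reflecting
#' layer (characteristic impedance differing from water by more than 25%)
#' plus a two-wavelength margin, so standing-wave maxima inside and just
#' behind the skull are excluded. Soft tissue layers (scalp, brain) whose
#' impedance nearly matches water do not shift the region.
#'
#' @param domain A `tfus_domain`.
#' @return Axial position in m.
#' @export
peak_search_start <- function(domain) {
  stopifnot(inherits(domain, "tfus_domain"))
  cfg <- domain$config
  lambda_w <- cfg$water$speed_of_sound_mps / cfg$transducer$center_frequency
  z_near <- cfg$transducer$vertex_offset +
    cfg$transducer$curvature_radius -
    sqrt(cfg$transducer$curvature_radius^2 - (cfg$transducer$aperture_diameter / 2)^2)
  start <- z_near + 2 * lambda_w
  if (nrow(domain$layers)) {
    zw <- cfg$water$speed_of_sound_mps * cfg$water$density_kg_per_m3
    zl <- domain$layers$speed_of_sound_mps * domain$layers$density_kg_per_m3
    hard <- which(zl / zw > 1.25 | zl / zw < 0.8)
    if (length(hard)) {
      start <- max(start, max(domain$layers$z_end_m[hard]) + 2 * lambda_w)
    }
  }
  start
}

#' Calibrate the source against a free-water focal pressure
#'
#' Solves the pure-water field once and, by linearity, rescales the drive
#' amplitude so that the free-water focal peak equals the target exactly.
#'
#' @param config A [sim_config()]; its layer stack is ignored (replaced by
#'   pure water) for the calibration solve.
#' @param target_focal_pressure Target free-water focal peak in Pa (>= 0).
#' @param water_field Optional already-solved pure-water `pressure_field`
#'   for this configuration, to avoid re-solving.
#' @return The configuration with `transducer$drive_amplitude` rescaled;
#'   the attribute `"water_peak"` records the calibrated peak.
#' @export
calibrate_source <- function(config, target_focal_pressure, water_field = NULL) {
  stopifnot(inherits(config, "tfus_config"))
  if (target_focal_pressure < 0) abort("`target_focal_pressure` must be >= 0")
  if (target_focal_pressure == 0) {
    config$transducer$drive_amplitude <- 0
    attr(config, "water_peak") <- 0
    return(config)
  }
  water_cfg <- config
  water_cfg$layers <- layer_stack()
  field <- water_field %||% simulate_field(water_cfg)
  dom <- field$domain
  pk <- peak_pressure(field, z_min_m = peak_search_start(dom))$peak
  if (pk == 0) abort("computed free-water peak is zero; cannot calibrate")
  config$transducer$drive_amplitude <-
    config$transducer$drive_amplitude * target_focal_pressure / pk
  attr(config, "water_peak") <- target_focal_pressure
  config
}
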