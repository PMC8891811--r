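.config_digest <- function(config) {
  tr <- config$transducer
  paste(
    sprintf("f0=%g", tr$center_frequency),
    sprintf("ap=%g", tr$aperture_diameter),
    sprintf("roc=%g", tr$curvature_radius),
    sprintf("h=%g", config$grid_spacing_m),
    sprintf("rext=%g", config$radial_extent_m),
    sprintf("zext=%g", config$axial_extent_m),
    sprintf("pml=%g/%g/%g", config$pml_wavelengths, config$pml_target_reflection,
            config$pml_profile_order),
    sprintf("standoff=%g", config$standoff_m),
    sep = ";"
  )
}

.water_reference <- function(config) {
  water_cfg <- config
  water_cfg$layers <- layer_stack()
  field <- simulate_field(water_cfg)
  peak <- peak_pressure(field, z_min_m = peak_search_start(field$domain))
  list(field = field, peak = peak$peak, peak_z = peak$z_m)
}

#' Skull-thickness sweep with system identification
#'
#' Runs the identification experiment behind the exponential attenuation
#' model: for each thickness a single skull layer is placed in water, the
#' transcranial field is solved, the distal peak is ratioed against the
#' pure-water baseline (solved once) to give the transmission percentage,
#' and the exponential law is fitted to the resulting samples. Recorded
#' thicknesses are the realized (grid-snapped) ones; with the default
#' spacing the default sweep is represented exactly.
#'
#' @param thicknesses_mm Skull thicknesses in mm (default 2-9 mm in
#'   0.5 mm steps, covering all packaged site thicknesses).
#' @param config Base [sim_config()]; its layer stack is replaced per
#'   solve.
#' @param material Layer material (default `"skull"`).
#' @param target_focal_pressure Optional free-water calibration target in
#'   Pa; peak pressures are reported on that scale (attenuation
#'   percentages are scale-invariant by linearity).
#' @return A `sweep_result`: `samples` (one row per thickness), `fit`
#'   (an `attenuation_fit`, or `NULL` with `degenerate = TRUE` if the
#'   samples carry no decay), `water_peak`, `config_digest`.
#' @export
run_thickness_sweep <- function(thicknesses_mm = seq(2, 9, by = 0.5),
                                config = sim_config(),
                                material = "skull",
                                target_focal_pressure = NULL) {
  if (length(thicknesses_mm) < 3L) abort("need at least 3 thicknesses to identify the model")
  mat <- .as_medium_row(material)
  wr <- .water_reference(config)
  scale <- if (!is.null(target_focal_pressure)) target_focal_pressure / wr$peak else 1

  rows <- purrr::map(thicknesses_mm, function(zmm) {
    cfg <- config
    cfg$layers <- layer_stack(layer(mat, zmm * 1e-3))
    field <- tryCatch(
      simulate_field(cfg),
      error = function(e) abort(sprintf(
        "solve failed at thickness %.3g mm: %s", zmm, conditionMessage(e)
      ))
    )
    pk <- peak_pressure(field, z_min_m = peak_search_start(field$domain))
    tibble(
      thickness_mm = field$domain$layers$realized_thickness_m[1] * 1e3,
      nominal_thickness_mm = zmm,
      peak = pk$peak * scale,
      peak_z_m = pk$z_m,
      tau_percent = 100 * pk$peak / wr$peak,
      attenuation_percent = 100 * (1 - pk$peak / wr$peak),
      provenance = "simulation"
    )
  })
  samples <- arrange(bind_rows(rows), .data$thickness_mm)

  fit <- NULL
  degenerate <- FALSE
  fit_try <- tryCatch(fit_attenuation(samples), error = function(e) e)
  if (inherits(fit_try, "attenuation_fit")) {
    fit <- fit_try
  } else {
    degenerate <- TRUE
    warn(sprintf("sweep fit is degenerate: %s", conditionMessage(fit_try)))
  }

  structure(
    list(
      samples = samples,
      fit = fit,
      degenerate = degenerate,
      water_peak = wr$peak * scale,
      water_peak_z_m = wr$peak_z,
      config_digest = .config_digest(config)
    ),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "Thickness sweep: %d solves, tau %.2f-%.2f%%\n",
    nrow(x$samples), min(x$samples$tau_percent), max(x$samples$tau_percent)
  ))
  if (!is.null(x$fit)) print(x$fit) else cat("  fit: degenerate\n")
  invisible(x)
}

#' Attenuation of a single tissue layer
#'
#' Solves one layer of the given tissue in water and reports the
#' attenuation of the distal peak relative to the pure-water baseline at
#' matched source calibration. A zero thickness returns 0% attenuation by
#' definition.
#'
#' @param material Material name or one-row medium tibble.
#' @param thickness_mm Layer thickness in mm (>= 0).
#' @param config Base [sim_config()].
#' @param water_reference Optional precomputed result of an internal
#'   water baseline (to share one baseline across several calls): a list
#'   with elements `field` and `peak`.
#' @inheritParams run_thickness_sweep
#' @return A one-row tibble: `material`, `thickness_mm` (realized),
#'   `peak`, `water_peak`, `tau_percent`, `attenuation_percent`.
#' @export
run_single_layer <- function(material, thickness_mm,
                             config = sim_config(),
                             target_focal_pressure = NULL,
                             water_reference = NULL) {
  mat <- .as_medium_row(material)
  if (thickness_mm < 0) abort("`thickness_mm` must be >= 0")
  wr <- water_reference %||% .water_reference(config)
  scale <- if (!is.null(target_focal_pressure)) target_focal_pressure / wr$peak else 1
  if (thickness_mm == 0) {
    return(tibble(
      material = mat$name, thickness_mm = 0,
      peak = wr$peak * scale, water_peak = wr$peak * scale,
      tau_percent = 100, attenuation_percent = 0
    ))
  }
  cfg <- config
  cfg$layers <- layer_stack(layer(mat, thickness_mm * 1e-3))
  field <- simulate_field(cfg)
  pk <- peak_pressure(field, z_min_m = peak_search_start(field$domain))
  tibble(
    material = mat$name,
    thickness_mm = field$domain$layers$realized_thickness_m[1] * 1e3,
    peak = pk$peak * scale,
    water_peak = wr$peak * scale,
    tau_percent = 100 * pk$peak / wr$peak,
    attenuation_percent = 100 * (1 - pk$peak / wr$peak)
  )
}

#' Default multilayer head-model configuration
#'
#' Scalp 3.35 mm, skull 5 mm, brain 40 mm stacked in source-to-far-field
#' order with a 15 mm water standoff, matching the packaged head-model
#' geometry.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `tfus_config`.
#' @export
multilayer_config <- function(...) {
  sim_config(
    layers = layer_stack(
      layer("scalp", 0.00335),
      layer("skull", 0.005),
      layer("brain", 0.040)
    ),
    standoff_m = 0.015,
    ...
  )
}

#' Multilayer head model versus pure water
#'
#' Solves the multilayer head model and the pure-water reference at
#' matched calibration and compares peak attenuation, focal-spot size
#' (FWHM) and axial peak position. The transcranial peak is searched
#' distal to the skull layer, i.e. inside and beyond the brain.
#'
#' @param config A multilayer [sim_config()]; default
#'   [multilayer_config()].
#' @inheritParams run_thickness_sweep
#' @return A `multilayer_result` list: `attenuation_percent`,
#'   `tau_percent`, `water_metrics`, `head_metrics`, `axial_profiles`
#'   (tibble of on-axis amplitude for both solves), peaks.
#' @export
run_multilayer <- function(config = multilayer_config(),
                           target_focal_pressure = NULL) {
  if (!nrow(config$layers)) abort("`config` must contain a multilayer stack")
  wr <- .water_reference(config)
  scale <- if (!is.null(target_focal_pressure)) target_focal_pressure / wr$peak else 1

  field <- simulate_field(config)
  z_start <- peak_search_start(field$domain)
  pk <- peak_pressure(field, z_min_m = z_start)
  wm <- focal_metrics(wr$field, z_min_m = peak_search_start(wr$field$domain))
  hm <- focal_metrics(field, z_min_m = z_start)

  keep <- field$z_m >= 0 & field$z_m <= config$axial_extent_m
  profiles <- tibble(
    z_m = field$z_m[keep],
    water = Mod(wr$field$p[1, keep]) * scale,
    head = Mod(field$p[1, keep]) * scale
  )

  structure(
    list(
      tau_percent = 100 * pk$peak / wr$peak,
      attenuation_percent = 100 * (1 - pk$peak / wr$peak),
      head_peak = pk$peak * scale,
      water_peak = wr$peak * scale,
      water_metrics = mutate(wm, peak = .data$peak * scale),
      head_metrics = mutate(hm, peak = .data$peak * scale),
      axial_profiles = profiles,
      config_digest = .config_digest(config)
    ),
    class = "multilayer_result"
  )
}

#' @export
print.multilayer_result <- function(x, ...) {
  cat(sprintf(
    "Multilayer head model: attenuation %.2f%% (peak %.4g vs water %.4g)\n",
    x$attenuation_percent, x$head_peak, x$water_peak
  ))
  cat(sprintf(
    "  axial peak: %.1f mm (water %.1f mm)\n",
    x$head_metrics$z_peak_m * 1e3, x$water_metrics$z_peak_m * 1e3
  ))
  invisible(x)
}

#' Pairwise tissue attenuation ratios
#'
#' How much more the skull attenuates than the other head tissues:
#' `skull / brain` and `skull / scalp` ratios of attenuation percentages
#' from one experiment family.
#'
#' @param attenuations A data frame with columns `tissue` (or `material`)
#'   and `attenuation_percent`, containing rows for `skull`, `brain` and
#'   `scalp`.
#' @return A tibble with `numerator`, `denominator`, `ratio`.
#' @examples
#' tissue_ratio_report(tibble::tibble(
#'   tissue = c("scalp", "skull", "brain"),
#'   attenuation_percent = c(12.10, 85.45, 18.20)
#' ))
#' @export
tissue_ratio_report <- function(attenuations) {
  if (!is.data.frame(attenuations)) abort("`attenuations` must be a data frame")
  tcol <- if ("tissue" %in% names(attenuations)) "tissue" else "material"
  if (!tcol %in% names(attenuations) || !"attenuation_percent" %in% names(attenuations)) {
    abort("`attenuations` needs columns `tissue` (or `material`) and `attenuation_percent`")
  }
  val <- function(nm) {
    v <- attenuations$attenuation_percent[attenuations[[tcol]] == nm]
    if (length(v) != 1L) abort(sprintf("need exactly one '%s' row", nm))
    v
  }
  skull <- val("skull")
  out <- purrr::map(c("brain", "scalp"), function(nm) {
    denom <- val(nm)
    if (denom == 0) abort(sprintf("'%s' attenuation is zero; ratio undefined", nm))
    tibble(numerator = "skull", denominator = nm, ratio = skull / denom)
  })
  bind_rows(out)
}
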