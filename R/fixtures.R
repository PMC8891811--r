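# Registry of packaged measurement tables. Each entry records the file,
# a human-readable description and the md5 of the shipped CSV so that any
# drift in the packaged values fails loudly.
.fixture_registry <- list(
  materials_table1 = list(
    file = "materials_table1.csv",
    md5 = "5a09703b58d53379f8d557521361b08b",
    description = "head-model acoustic constants (speed, attenuation, density) plus the water reference"
  ),
  water_pressures = list(
    file = "water_pressures.csv",
    md5 = "52c0c19299a31ba24a30a5999ce27e3f",
    description = "free-water focal peak pressures at the four excitation voltages (0.862/1.931/2.138/2.276 MPa)"
  ),
  multilayer_peaks = list(
    file = "multilayer_peaks.csv",
    md5 = "be413a1194cf67fcf7db148868786996",
    description = "water vs multilayer head model peak pressures (sim 0.219 MPa, phantom 0.255 MPa, water 2.276 MPa)"
  ),
  single_layer_phantom = list(
    file = "single_layer_phantom.csv",
    md5 = "388dfdd1fabbeac56c242ba0bada0c8a",
    description = "phantom single-layer attenuations: scalp 12.10, skull 85.45, brain 18.20 percent"
  ),
  single_layer_sim_mixed_thickness = list(
    file = "single_layer_sim_mixed_thickness.csv",
    md5 = "7b96a0646c09498f860758c83aa5f65a",
    description = "simulated single-layer attenuations at native thicknesses: scalp 3.21, skull 83.22, brain 34.49 percent"
  ),
  single_layer_sim_5mm = list(
    file = "single_layer_sim_5mm.csv",
    md5 = "e92f390a3ea46cfb2e741b5f1cd41b1a",
    description = "simulated uniform 5 mm single-layer attenuations: scalp 3.78, skull 85.45, brain 5.54 percent"
  ),
  skull14_sim = list(
    file = "skull14_sim.csv",
    md5 = "5c52dd9fde09fbf43b76c87622abd671",
    description = "simulated attenuation at skull No. 14 sites S1-S4 (75.52/79.85/82.96/88 percent)"
  ),
  skull14_phantom = list(
    file = "skull14_phantom.csv",
    md5 = "2a0261765199919c4d23ec6fce9c2348",
    description = "phantom attenuation at skull No. 14 sites S1-S4 (69.60/76.80/82.40/86.40 percent)"
  ),
  skull49_errors = list(
    file = "skull49_errors.csv",
    md5 = "1ee44703415d8eeaa284f564d6d55ada",
    description = "model-vs-phantom relative errors for skull No. 49 sites S5-S6 (1.99/2.44 percent); raw pressures were never published"
  ),
  site_thicknesses = list(
    file = "site_thicknesses.csv",
    md5 = "af2efc992fd69788cfe7af27a85daaea",
    description = "skull thickness at test points S1-S6 (3.5/4.5/5/6.5/7.1/7.1 mm)"
  )
)

#' List the packaged measurement fixtures
#'
#' @return A tibble with columns `name`, `file`, `description`.
#' @examples
#' list_fixtures()
#' @export
list_fixtures <- function() {
  tibble(
    name = names(.fixture_registry),
    file = purrr::map_chr(.fixture_registry, "file"),
    description = purrr::map_chr(.fixture_registry, "description")
  )
}

#' Load a packaged measurement table
#'
#' Fixtures are plain CSV files shipped with the package; each carries the
#' measured site, thickness, quantity, value, units and provenance
#' (`simulation`, `phantom` or `synthetic`) of every published number the
#' package validates against. The file's md5 checksum is verified on every
#' load so silent drift of packaged values is impossible.
#'
#' @param name Registry name; see [list_fixtures()].
#' @return A tibble. The registry description is attached as attribute
#'   `"source_label"`.
#' @examples
#' load_fixture("skull14_phantom")
#' @export
load_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(.fixture_registry)) {
    abort(sprintf(
      "unknown fixture '%s'; packaged fixtures are: %s",
      paste(name, collapse = ", "), paste(names(.fixture_registry), collapse = ", ")
    ))
  }
  entry <- .fixture_registry[[name]]
  path <- system.file("extdata", entry$file, package = "tfusatt")
  if (!nzchar(path)) {
    abort(sprintf("fixture file '%s' is missing from the installed package", entry$file))
  }
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, entry$md5)) {
    abort(sprintf(
      "fixture '%s' failed its checksum (got %s, expected %s): packaged values have drifted",
      name, md5, entry$md5
    ))
  }
  out <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  attr(out, "source_label") <- entry$description
  out
}

#' Generate synthetic thickness/transmission samples
#'
#' Draws noisy observations from a known exponential transmission law
#' `tau(z) = a * exp(-b * z)`, emulating repeated hydrophone amplitude
#' measurements: the noise is multiplicative Gaussian,
#' `tau_i = a * exp(-b * z_i) * (1 + eps_i)` with `eps_i ~ N(0, sigma)`.
#' Values are clipped to the physical range \[0, 100\] percent and clipping
#' events are reported in the `clipped` column.
#'
#' @param a Amplitude coefficient in percent (> 0).
#' @param b Decay coefficient in 1/mm (> 0).
#' @param thicknesses Skull thicknesses in mm.
#' @param noise_sigma Relative noise standard deviation (fraction, >= 0);
#'   default 0.01 emulates ~1% amplitude measurement error.
#' @param seed Integer seed; the draw is reproducible for a fixed seed.
#' @return A tibble of thickness samples with columns `thickness_mm`,
#'   `tau_percent`, `tau_true_percent`, `clipped`, `provenance`.
#' @examples
#' generate_tau_samples(61.85, 0.2537, seq(2, 9, 0.5), noise_sigma = 0.01, seed = 1)
#' @export
generate_tau_samples <- function(a, b, thicknesses, noise_sigma = 0.01, seed = 1L) {
  if (!is.numeric(a) || length(a) != 1L || a <= 0) abort("`a` must be a single positive number (percent)")
  if (!is.numeric(b) || length(b) != 1L || b <= 0) abort("`b` must be a single positive number (1/mm)")
  if (!is.numeric(thicknesses) || length(thicknesses) < 1L || any(thicknesses < 0)) {
    abort("`thicknesses` must be non-negative (mm)")
  }
  if (!is.numeric(noise_sigma) || length(noise_sigma) != 1L || noise_sigma < 0) {
    abort("`noise_sigma` must be a single non-negative fraction")
  }
  tau_true <- a * exp(-b * thicknesses)
  eps <- if (noise_sigma > 0) {
    withr::with_seed(as.integer(seed), stats::rnorm(length(thicknesses), 0, noise_sigma))
  } else {
    rep(0, length(thicknesses))
  }
  tau_raw <- tau_true * (1 + eps)
  tau <- pmin(pmax(tau_raw, 0), 100)
  n_clip <- sum(tau != tau_raw)
  if (n_clip > 0) {
    warn(sprintf("%d of %d samples clipped to [0, 100] percent", n_clip, length(tau)))
  }
  tibble(
    thickness_mm = as.numeric(thicknesses),
    tau_percent = tau,
    tau_true_percent = tau_true,
    clipped = tau != tau_raw,
    provenance = "synthetic"
  )
}
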