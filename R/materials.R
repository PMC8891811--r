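#' Define an acoustic medium
#'
#' A medium is described by the three constants that enter the lossy
#' Helmholtz equation: speed of sound, mass density and the amplitude
#' attenuation coefficient at the operating frequency.
#'
#' @param name Character label, e.g. `"skull"`.
#' @param speed_of_sound Speed of sound in m/s (> 0).
#' @param density Mass density in kg/m^3 (> 0).
#' @param attenuation Amplitude attenuation in dB/m (>= 0). The packaged
#'   head-tissue values are single-frequency constants at 1 MHz.
#' @return A one-row tibble with columns `name`, `speed_of_sound_mps`,
#'   `density_kg_per_m3`, `attenuation_db_per_m`.
#' @examples
#' medium("water", 1482, 998, 0)
#' @export
medium <- function(name, speed_of_sound, density, attenuation = 0) {
  if (!is.character(name) || length(name) != 1L) {
    abort("`name` must be a single character label")
  }
  if (!is.numeric(speed_of_sound) || length(speed_of_sound) != 1L ||
      !is.finite(speed_of_sound) || speed_of_sound <= 0) {
    abort(sprintf("medium '%s': `speed_of_sound` must be a positive finite number (m/s)", name))
  }
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) || density <= 0) {
    abort(sprintf("medium '%s': `density` must be a positive finite number (kg/m^3)", name))
  }
  if (!is.numeric(attenuation) || length(attenuation) != 1L ||
      !is.finite(attenuation) || attenuation < 0) {
    abort(sprintf("medium '%s': `attenuation` must be a non-negative finite number (dB/m)", name))
  }
  tibble(
    name = name,
    speed_of_sound_mps = speed_of_sound,
    density_kg_per_m3 = density,
    attenuation_db_per_m = attenuation
  )
}

#' Packaged head-model material table
#'
#' Returns the acoustic constants used throughout the package: scalp, skull
#' and brain tissue from the published head-model material table, plus the
#' water reference (1482 m/s, 998 kg/m^3, lossless, at 295.15 K). Values are
#' read from the CSV shipped in `inst/extdata` so that every number is
#' traceable to a packaged, checksummed file.
#'
#' @return A tibble with one row per material and columns `name`,
#'   `speed_of_sound_mps`, `attenuation_db_per_m`, `density_kg_per_m3`.
#' @examples
#' tissue_materials()
#' @export
tissue_materials <- function() {
  load_fixture("materials_table1")
}

#' Look up one packaged material
#'
#' @param name One of `"water"`, `"scalp"`, `"skull"`, `"brain"`.
#' @return A one-row material tibble (see [medium()]).
#' @export
get_material <- function(name) {
  mats <- tissue_materials()
  row <- mats[mats$name == name, ]
  if (nrow(row) != 1L) {
    abort(sprintf(
      "unknown material '%s'; packaged materials are: %s",
      name, paste(mats$name, collapse = ", ")
    ))
  }
  row[, c("name", "speed_of_sound_mps", "density_kg_per_m3", "attenuation_db_per_m")]
}

#' Convert an attenuation coefficient from dB/m to Np/m
#'
#' `alpha_np = alpha_db * ln(10) / 20`, i.e. alpha_db / 8.6859.
#'
#' @param alpha_db Attenuation in dB/m.
#' @return Attenuation in Np/m.
#' @examples
#' db_to_np(2000)  # skull at 1 MHz: ~230.26 Np/m
#' @export
db_to_np <- function(alpha_db) {
  alpha_db * .tfus_const$ln10_over_20
}

.as_medium_row <- function(material) {
  if (is.character(material) && length(material) == 1L) {
    return(get_material(material))
  }
  if (is.data.frame(material) && nrow(material) == 1L &&
      all(c("speed_of_sound_mps", "density_kg_per_m3", "attenuation_db_per_m") %in%
            names(material))) {
    return(material)
  }
  abort("`material` must be a packaged material name or a one-row medium tibble")
}

#' Lossy-medium representation at a given frequency
#'
#' Converts a real-valued medium into the complex-valued constants used by
#' the frequency-domain wave operator. With the package's time convention
#' `exp(+i*omega*t)`, the complex wavenumber is
#' `k = omega/c - 1i * alpha_np`, so absorbed waves decay along the
#' propagation direction. The complex speed is `omega / k`; the density is
#' kept real (the absorption is carried entirely by the complex speed), so
#' the pair `(rho_c, c_c)` reproduces `k` when substituted into the lossless
#' Helmholtz operator.
#'
#' @param material Material name or one-row medium tibble.
#' @param frequency Operating frequency in Hz (> 0).
#' @return A one-row tibble with columns `name`, `frequency_hz`,
#'   `complex_density`, `complex_speed`, `wavenumber` (complex, 1/m).
#' @examples
#' complex_medium("skull", 1e6)
#' @export
complex_medium <- function(material, frequency) {
  m <- .as_medium_row(material)
  if (!is.numeric(frequency) || length(frequency) != 1L ||
      !is.finite(frequency) || frequency <= 0) {
    abort("`frequency` must be a single positive number (Hz)")
  }
  omega <- 2 * pi * frequency
  k <- omega / m$speed_of_sound_mps - 1i * db_to_np(m$attenuation_db_per_m)
  tibble(
    name = m$name,
    frequency_hz = frequency,
    complex_density = complex(real = m$density_kg_per_m3, imaginary = 0),
    complex_speed = omega / k,
    wavenumber = k
  )
}
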