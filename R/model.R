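#' Exponential skull-thickness transmission model
#'
#' Evaluates the identified transmission law `tau(z) = a * exp(-b * z)`,
#' the percentage of the free-water focal peak that survives passage
#' through a skull of thickness `z` (mm). The packaged reference
#' coefficients are `a = 61.85` percent and `b = 0.2537` 1/mm; see
#' [reference_attenuation_fit()].
#'
#' @param z Skull thickness in mm (>= 0); vectorized.
#' @param fit An `attenuation_fit` object, or anything with elements `a`
#'   and `b` (e.g. `list(a = 61.85, b = 0.2537)`).
#' @return Transmission in percent, same length as `z`.
#' @examples
#' tau_model(6.5, reference_attenuation_fit())  # ~11.89 percent
#' @export
tau_model <- function(z, fit = reference_attenuation_fit()) {
  ab <- .fit_coefs(fit)
  if (!is.numeric(z) || any(!is.finite(z)) || any(z < 0)) {
    abort("`z` must be non-negative skull thickness in mm")
  }
  ab$a * exp(-ab$b * z)
}

.fit_coefs <- function(fit) {
  if (inherits(fit, "attenuation_fit")) {
    return(list(a = fit$a, b = fit$b))
  }
  if (is.list(fit) && all(c("a", "b") %in% names(fit))) {
    return(list(a = as.numeric(fit$a), b = as.numeric(fit$b)))
  }
  abort("`fit` must be an attenuation_fit or a list with elements `a` and `b`")
}

#' Transmitted and attenuated pressure at a given skull thickness
#'
#' Splits a free-water focal pressure into the part transmitted through a
#' skull of thickness `z` and the attenuated remainder,
#' `A_z = P_water * (1 - tau(z)/100)`.
#'
#' @param p_water Free-water focal peak pressure in Pa (>= 0); vectorized.
#' @param z Skull thickness in mm (>= 0).
#' @inheritParams tau_model
#' @return A tibble with columns `thickness_mm`, `p_water_pa`,
#'   `tau_percent`, `attenuation_percent`, `transmitted_pa`,
#'   `attenuation_pa`.
#' @examples
#' attenuation_pressure(2.276e6, 5)  # transmitted ~0.396 MPa
#' @export
attenuation_pressure <- function(p_water, z, fit = reference_attenuation_fit()) {
  if (!is.numeric(p_water) || any(!is.finite(p_water)) || any(p_water < 0)) {
    abort("`p_water` must be non-negative pressure in Pa")
  }
  tau <- tau_model(z, fit)
  tibble(
    thickness_mm = as.numeric(z),
    p_water_pa = as.numeric(p_water),
    tau_percent = tau,
    attenuation_percent = 100 - tau,
    transmitted_pa = p_water * tau / 100,
    attenuation_pa = p_water * (1 - tau / 100)
  )
}

#' Transmission percentage from a pair of measured peaks
#'
#' `tau = 100 * P_z / P_water`, the definition used for both simulated and
#' phantom measurements, with the companion attenuation percentage
#' `100 - tau`.
#'
#' @param p_z Transcranial peak pressure in Pa (>= 0); vectorized.
#' @param p_water Free-water reference peak in Pa (> 0).
#' @return A tibble with columns `p_z_pa`, `p_water_pa`, `tau_percent`,
#'   `attenuation_percent`.
#' @examples
#' tau_from_measurement(0.255e6, 2.276e6)  # attenuation ~88.8 percent
#' @export
tau_from_measurement <- function(p_z, p_water) {
  if (!is.numeric(p_water) || any(!is.finite(p_water)) || any(p_water <= 0)) {
    abort("`p_water` must be a positive reference pressure in Pa")
  }
  if (!is.numeric(p_z) || any(!is.finite(p_z)) || any(p_z < 0)) {
    abort("`p_z` must be non-negative pressure in Pa")
  }
  tau <- 100 * p_z / p_water
  tibble(
    p_z_pa = as.numeric(p_z),
    p_water_pa = as.numeric(p_water),
    tau_percent = tau,
    attenuation_percent = 100 - tau
  )
}

#' Predict the intracranial peak at another skull thickness
#'
#' Transfers a known intracranial peak pressure from a site with skull
#' thickness `x1` to a site with thickness `x2` using the transmission
#' ratio `P_x2 = P_x1 * tau(x2) / tau(x1)`. Because `tau` is exponential
#' the prediction depends only on the decay coefficient and the thickness
#' difference: `P_x2 / P_x1 = exp(-b * (x2 - x1))`.
#'
#' @param p_x1 Intracranial peak pressure at the known site, Pa (>= 0).
#' @param x1 Known skull thickness in mm (>= 0).
#' @param x2 Target skull thickness in mm (>= 0); vectorized.
#' @inheritParams tau_model
#' @return Predicted pressure(s) in Pa.
#' @examples
#' predict_pressure(0.4e6, 5, 6.5)
#' @export
predict_pressure <- function(p_x1, x1, x2, fit = reference_attenuation_fit()) {
  if (!is.numeric(p_x1) || any(!is.finite(p_x1)) || any(p_x1 < 0)) {
    abort("`p_x1` must be non-negative pressure in Pa")
  }
  tau1 <- tau_model(x1, fit)
  if (any(tau1 == 0)) abort("tau(x1) is zero; cannot form the transmission ratio")
  tau2 <- tau_model(x2, fit)
  p_x1 * tau2 / tau1
}

#' Relative error with the model value as denominator
#'
#' `100 * |model - reference| / model`. The model-value denominator is the
#' package's fixed convention for comparing model attenuations against
#' simulated or phantom references: it reproduces the published per-site
#' error bookkeeping (e.g. 100*|74.55 - 69.60|/74.55 = 6.64).
#'
#' @param model_value Model value(s); must be nonzero.
#' @param reference_value Reference value(s), same length or length 1.
#' @return Relative error(s) in percent.
#' @examples
#' relative_error(74.55, 69.60)  # 6.64
#' @export
relative_error <- function(model_value, reference_value) {
  if (!is.numeric(model_value) || any(!is.finite(model_value)) || any(model_value == 0)) {
    abort("`model_value` must be nonzero (it is the denominator)")
  }
  100 * abs(model_value - reference_value) / abs(model_value)
}

#' Pearson correlation between two measurement series
#'
#' Thin wrapper around [stats::cor()] with the validation and percent
#' reporting used in the package's validation reports.
#'
#' @param series_a,series_b Numeric vectors of equal length >= 2 with
#'   nonzero variance.
#' @param as_percent If `TRUE`, report `100 * r` (the convention used for
#'   the packaged site-by-site comparisons).
#' @return Pearson correlation coefficient (or percentage).
#' @examples
#' correlation(c(1, 2, 3), c(2.1, 3.9, 6.0))
#' @export
correlation <- function(series_a, series_b, as_percent = FALSE) {
  if (length(series_a) != length(series_b)) abort("series must have equal length")
  if (length(series_a) < 2L) abort("series must have length >= 2")
  if (stats::sd(series_a) == 0 || stats::sd(series_b) == 0) {
    abort("series must have nonzero variance")
  }
  r <- stats::cor(series_a, series_b, method = "pearson")
  if (as_percent) 100 * r else r
}
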