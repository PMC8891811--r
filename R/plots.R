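#' Plot a pressure field
#'
#' Raster of |p| over the physical (r, z) region, mirrored across the
#' axis for a familiar beam-plot view.
#'
#' @param object A `pressure_field`.
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_point geom_line
#'   geom_col labs scale_fill_viridis_c theme_minimal position_dodge
#' @method autoplot pressure_field
#' @export
autoplot.pressure_field <- function(object, ...) {
  tb <- as_tibble(object)
  tb2 <- bind_rows(tb, mutate(tb, r = -.data$r))
  ggplot(tb2, aes(x = .data$z * 1e3, y = .data$r * 1e3, fill = .data$amplitude)) +
    geom_raster() +
    scale_fill_viridis_c(name = "|p|") +
    labs(x = "axial position z (mm)", y = "radial position r (mm)") +
    theme_minimal()
}

#' Plot an attenuation fit
#'
#' Samples and fitted exponential transmission curve versus skull
#' thickness.
#'
#' @param object An `attenuation_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot attenuation_fit
#' @export
autoplot.attenuation_fit <- function(object, ...) {
  if (is.null(object$data)) abort("this fit carries no samples to plot")
  zg <- seq(min(object$data$thickness_mm), max(object$data$thickness_mm),
            length.out = 200)
  curve <- tibble(thickness_mm = zg, tau_percent = tau_model(zg, object))
  ggplot(object$data, aes(x = .data$thickness_mm, y = .data$tau_percent)) +
    geom_point() +
    geom_line(data = curve, colour = "red") +
    labs(
      x = "skull thickness z (mm)", y = "transmitted peak pressure (%)",
      title = sprintf("tau(z) = %.2f exp(-%.4f z),  R² = %.4f",
                      object$a, object$b, object$r_squared)
    ) +
    theme_minimal()
}

#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  if (is.null(object$fit)) abort("sweep fit is degenerate; nothing to plot")
  autoplot(object$fit, ...)
}

#' Plot a validation report
#'
#' Model versus reference attenuation per site, as grouped bars.
#'
#' @param object A `validation_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, ...) {
  tb <- object$per_site |>
    filter(!is.na(.data$reference_attenuation_percent)) |>
    tidyr::pivot_longer(
      cols = c("model_attenuation_percent", "reference_attenuation_percent"),
      names_to = "which", values_to = "attenuation_percent"
    ) |>
    mutate(which = ifelse(.data$which == "model_attenuation_percent",
                          "model", "reference"))
  ggplot(tb, aes(x = .data$site, y = .data$attenuation_percent, fill = .data$which)) +
    geom_col(position = position_dodge()) +
    ggplot2::facet_wrap(~series) +
    labs(x = "test point", y = "attenuation (%)", fill = NULL) +
    theme_minimal()
}
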