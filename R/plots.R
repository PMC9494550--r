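#' Plot a neutron spectrum per unit lethargy
#'
#' Step plot of fluence per unit lethargy on a logarithmic energy axis (the
#' conventional presentation: equal areas represent equal fluence).
#'
#' @param object A `neutron_spectrum` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot neutron_spectrum
#' @export
autoplot.neutron_spectrum <- function(object, ...) {
  df <- per_lethargy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$e_low_MeV,
                                   y = .data$fluence_per_lethargy)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "neutron energy (MeV)",
      y = expression(paste("fluence per unit lethargy (", cm^-2, " ", Gy^-1, ")")),
      title = "Neutron fluence energy spectrum"
    )
}

#' Plot observed versus fitted H*(10) for a scaling-law fit
#'
#' @param object A `scaling_fit` from [fit_scaling_model()].
#' @param campaign The campaign tibble the model was fitted to.
#' @param ... Unused.
#' @return A ggplot object (log-log observed vs fitted, one facet per
#'   position).
#' @method autoplot scaling_fit
#' @export
autoplot.scaling_fit <- function(object, campaign, ...) {
  pred <- campaign |>
    dplyr::group_by(.data$position) |>
    dplyr::group_modify(function(d, key) {
      predict_h10(d, object$model, position = key$position, quiet = TRUE) |>
        dplyr::rename(fitted = "h10_uSv_per_Gy") |>
        dplyr::mutate(observed = d$h10_uSv_per_Gy)
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~position, scales = "free") +
    ggplot2::labs(
      x = "fitted H*(10) (uSv/Gy)", y = "observed H*(10) (uSv/Gy)",
      title = "Scaling-law fit: observed vs fitted"
    )
}

#' Plot an uncertainty budget
#'
#' @param object An `uncertainty_budget` from [combine_budget()].
#' @param ... Unused.
#' @return A ggplot bar chart of the components and the combined value.
#' @method autoplot uncertainty_budget
#' @export
autoplot.uncertainty_budget <- function(object, ...) {
  df <- tidy(object)
  df$component <- factor(df$component, levels = df$component)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$percent)) +
    ggplot2::geom_col(fill = c(rep("grey40", nrow(df) - 1), "firebrick")) +
    ggplot2::labs(x = NULL, y = "relative uncertainty (%, k = 1)",
                  title = "Measurement uncertainty budget")
}
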