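#' Posterior density plot of an SRM fit
#'
#' Overlaid per-chain posterior densities for a chosen set of parameters;
#' by default the variance components and reciprocity correlations.
#'
#' @param object An `srm_fit`.
#' @param pars Character vector of parameter columns to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot srm_fit
#' @export
autoplot.srm_fit <- function(object,
                             pars = c(
                               "sigma2_m", "sigma2_a", "sigma2_b",
                               "rho_ab", "rho_ee"
                             ),
                             ...) {
  pars <- intersect(pars, srm_parameter_cols(object$draws))
  long <- object$draws |>
    dplyr::select(dplyr::all_of(c(".chain", pars))) |>
    tidyr::pivot_longer(-".chain", names_to = "parameter", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(.data$value,
    colour = factor(.data$.chain)
  )) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density", colour = "chain") +
    ggplot2::theme_minimal()
}

#' Ribbon plot of a prediction grid
#'
#' @param object An `srm_prediction` from [prediction_grid()].
#' @param x Name of the grid column for the horizontal axis.
#' @param colour Optional grid column distinguishing curves.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot srm_prediction
#' @export
autoplot.srm_prediction <- function(object, x, colour = NULL, ...) {
  aes <- if (is.null(colour)) {
    ggplot2::aes(.data[[x]], .data$estimate)
  } else {
    ggplot2::aes(.data[[x]], .data$estimate,
      colour = factor(.data[[colour]]), fill = factor(.data[[colour]])
    )
  }
  ggplot2::ggplot(object, aes) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      alpha = 0.25, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      y = "predicted tie probability",
      colour = colour, fill = colour
    ) +
    ggplot2::theme_minimal()
}

#' Observed reciprocity diagnostics plot
#'
#' Scatter of per-actor out-degree against in-degree (the empirical face of
#' generalized reciprocity), faceted by nothing, coloured by group density.
#'
#' @param x A `dyad_data` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_degree_reciprocity <- function(x, ...) {
  deg <- actor_degrees(x)
  ggplot2::ggplot(deg, ggplot2::aes(.data$out_degree, .data$in_degree)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "out-degree", y = "in-degree") +
    ggplot2::theme_minimal()
}
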