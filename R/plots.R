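# ggplot2 displays for the main result types.

#' @describeIn fit_gem RMSE trace of the calibration heuristic: candidate
#'   full-data RMSE per QP step with the incumbent overlaid.
#' @param object a fitted object (for `autoplot`).
#' @export
autoplot.gem_fit <- function(object, ...) {
  tr <- object$trace |>
    dplyr::mutate(step_index = dplyr::row_number())
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step_index)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rmse_incumbent), linewidth = 0.6) +
    ggplot2::geom_point(ggplot2::aes(y = .data$rmse_candidate,
                                     shape = .data$accepted, colour = .data$step)) +
    ggplot2::labs(x = "QP step", y = "area-weighted RMSE (bu/ac)",
                  colour = "step", shape = "accepted",
                  title = "Calibration trace",
                  subtitle = "line: incumbent; points: blended candidates") +
    ggplot2::theme_minimal()
}

#' Predicted vs observed yields from a cross-validation run
#'
#' @param object a `gem_cv`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gem_cv <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$yield, y = .data$yhat, size = .data$area)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "observed yield (bu/ac)", y = "predicted yield (bu/ac)",
                  title = sprintf("%s: pooled RMSE %.1f bu/ac, R2 %.2f",
                                  object$mode, object$pooled$rmse, object$pooled$r2)) +
    ggplot2::theme_minimal()
}

#' In-season forecast convergence plot
#'
#' One curve per historical weather scenario; curves converge as the
#' observed portion of the season grows.
#'
#' @param object a `gem_forecast`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gem_forecast <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$day, y = .data$yhat,
                                       group = .data$scenario_year)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "day of year", y = "predicted average yield (bu/ac)",
                  title = sprintf("In-season forecast for %s (%d weather scenarios)",
                                  attr(object, "target_year"),
                                  dplyr::n_distinct(object$scenario_year))) +
    ggplot2::theme_minimal()
}

#' Heat map of the pairwise interaction grid
#'
#' Vegetative-stage cells occupy the upper triangle, reproductive-stage
#' cells the lower triangle.
#'
#' @param params a [gem_params()] (or a `gem_fit`).
#' @return a ggplot.
#' @export
plot_interaction_map <- function(params) {
  if (inherits(params, "gem_fit")) params <- params$params
  vars <- c(attr(params, "weather_vars"), attr(params, "soil_vars"))
  M <- interaction_matrix(params)
  df <- tibble::as_tibble(M, rownames = "row") |>
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "effect") |>
    dplyr::mutate(row = factor(.data$row, levels = rev(vars)),
                  col = factor(.data$col, levels = vars))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$effect)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "forestgreen", na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "effect",
                  title = "Pairwise weather/soil interaction effects",
                  subtitle = "upper triangle: vegetative stage; lower: reproductive") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
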