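#' Plot the transition-probability curves
#'
#' Shows the forward (and optionally stay/backward) probability over the
#' decision grid for a set of reasoning propensities.
#'
#' @param p_r Vector of reasoning propensities to draw.
#' @param shape A [curve_shape()] object.
#' @param grid An [state_grid()] object.
#' @return A ggplot object.
#' @export
plot_transition_curves <- function(p_r = c(0, 0.5, 1), shape = curve_shape(),
                                   grid = state_grid()) {
  df <- transition_curves(p_r, shape, grid) |>
    tidyr::pivot_longer(c("p_up", "p_stay", "p_down"),
                        names_to = "direction", values_to = "probability")
  ggplot2::ggplot(df, ggplot2::aes(.data$u, .data$probability,
                                   colour = factor(.data$p_r))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = "decision u", colour = "p_r",
                  title = "Transition probabilities over the decision grid") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_transition_curves Heatmap of the optimal policy
#'   (decision by state and epoch), the direct analogue of a policy matrix
#'   figure.
#' @param object,x Fitted/simulated object.
#' @param ... Unused.
#' @export
autoplot.aware_sdp <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$epoch, .data$state,
                               fill = .data$decision)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(title = "Self-aware (optimal) policy",
                  x = "epoch", y = "awareness state", fill = "decision u") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_transition_curves One trajectory: state, decision and
#'   cumulative reward over time.
#' @export
autoplot.aware_trajectory <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("state", "decision", "cum_reward"),
                        names_to = "series", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(title = sprintf("Trajectory (%s policy)", object$mode)) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_transition_curves Ensemble mean state and decision with
#'   a 2-standard-error ribbon.
#' @export
autoplot.aware_ensemble <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$mean_state)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_state - 2 * .data$se_state,
      ymax = .data$mean_state + 2 * .data$se_state
    ), alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = sprintf("Ensemble mean state (%s policy, N = %d)",
                                  object$mode, object$N),
                  y = "mean awareness state") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_transition_curves Habitual versus self-aware ensemble
#'   mean states on one axis.
#' @export
autoplot.aware_comparison <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$mean_state,
                                   colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = "Habitual vs self-aware mean awareness state",
                  y = "mean awareness state", colour = NULL) +
    ggplot2::theme_minimal()
}
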