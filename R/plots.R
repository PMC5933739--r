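#' Plot a swim trajectory inside the pool
#'
#' @param object a `swim_trajectory`.
#' @param ... unused.
#' @return a ggplot object: pool wall, wall annulus, platform and path.
#' @export
autoplot.swim_trajectory <- function(object, ...) {
  geometry <- attr(object, "geometry")
  .check_geometry(geometry)
  th <- seq(0, 2 * pi, length.out = 200)
  circle <- function(r, cx = 0, cy = 0) {
    tibble(x = cx + r * cos(th), y = cy + r * sin(th))
  }
  lab <- attr(object, "label") %||% "trajectory"
  ggplot2::ggplot() +
    ggplot2::geom_path(data = circle(geometry$pool_radius),
                       ggplot2::aes(.data$x, .data$y), colour = "grey30") +
    ggplot2::geom_path(data = circle(0.9 * geometry$pool_radius),
                       ggplot2::aes(.data$x, .data$y),
                       colour = "grey70", linetype = 2) +
    ggplot2::geom_path(data = circle(geometry$platform_radius,
                                     geometry$platform_center[1],
                                     geometry$platform_center[2]),
                       ggplot2::aes(.data$x, .data$y), colour = "red3") +
    ggplot2::geom_path(data = as_tibble(object),
                       ggplot2::aes(.data$x_m, .data$y_m),
                       colour = "blue4", linewidth = 0.3) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = lab, x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation's confusion matrix
#'
#' @param object a `swim_eval`.
#' @param ... unused.
#' @return a ggplot tile plot of the accumulated confusion counts.
#' @export
autoplot.swim_eval <- function(object, ...) {
  cm <- object$confusion_counts
  df <- as_tibble(as.data.frame(as.table(cm)))
  names(df) <- c("true", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true",
                  title = sprintf("%d-class confusion (%d repetitions)",
                                  object$n_classes, object$repetitions)) +
    ggplot2::theme_minimal()
}

#' Plot the cognitive-score transition
#'
#' @param transition output of [score_transition()].
#' @return a ggplot line plot of per-day group mean scores with SEM bars.
#' @export
plot_score_transition <- function(transition) {
  ggplot2::ggplot(transition,
                  ggplot2::aes(.data$day, .data$mean_score,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_score - .data$sem_score,
                   ymax = .data$mean_score + .data$sem_score),
      width = 0.1) +
    ggplot2::labs(x = "training day", y = "mean cognitive score") +
    ggplot2::theme_minimal()
}
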