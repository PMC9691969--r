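# ggplot2 views of the result objects. These are quick-look plots for
# analysis notebooks, not publication figures.

#' Plot severity score time courses
#'
#' One line per animal, with the reference ceiling (score = 1) marked.
#'
#' @param object A `relsa_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot relsa_result
#' @export
autoplot.relsa_result <- function(object, ...) {
  ggplot2::ggplot(
    object$scores %>% filter(!is.na(.data$relsa)),
    ggplot2::aes(
      x = .data$time, y = .data$relsa,
      group = .data$animal_id, colour = .data$group
    )
  ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "red") +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "time", y = "RELSA score", colour = "group",
      title = "Relative severity over time",
      subtitle = "dashed line: reference ceiling (score = 1)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot severity levels over the score maxima
#'
#' Strip plot of the clustered per-animal maxima with the level thresholds
#' as dashed lines.
#'
#' @param object A `severity_levels`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot severity_levels
#' @export
autoplot.severity_levels <- function(object, ...) {
  pts <- augment(object)
  ggplot2::ggplot(pts, ggplot2::aes(
    x = .data$level_label, y = .data$value, colour = .data$level_label
  )) +
    ggplot2::geom_hline(
      yintercept = object$thresholds, linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_jitter(width = 0.15, height = 0, show.legend = FALSE) +
    ggplot2::labs(
      x = "severity level", y = "RELSA max",
      title = sprintf("Severity levels (k = %d, %s)", object$k, object$method)
    ) +
    ggplot2::theme_minimal()
}

#' Radar plot of variable contributions
#'
#' Polar view of the per-variable weights at each profiled time point.
#'
#' @param object A `relsa_contribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot relsa_contribution
#' @export
autoplot.relsa_contribution <- function(object, ...) {
  prof <- object$profile %>%
    mutate(weight = ifelse(is.na(.data$weight), 0, .data$weight))
  ggplot2::ggplot(prof, ggplot2::aes(
    x = .data$variable, y = .data$weight,
    group = factor(.data$time), colour = factor(.data$time)
  )) +
    ggplot2::geom_polygon(fill = NA) +
    ggplot2::geom_point() +
    ggplot2::coord_polar() +
    ggplot2::labs(
      x = NULL, y = "severity weight", colour = "time",
      title = "Variable contributions over time"
    ) +
    ggplot2::theme_minimal()
}

#' Scree plot for the level-count choice
#'
#' Within-cluster sum of squares against the candidate number of clusters,
#' with the selected elbow marked.
#'
#' @param object A `relsa_scree` from [scree_select_k()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot relsa_scree
#' @export
autoplot.relsa_scree <- function(object, ...) {
  ggplot2::ggplot(object$wss, ggplot2::aes(x = .data$k, y = .data$wss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed") +
    ggplot2::labs(
      x = "number of clusters k", y = "within-cluster sum of squares",
      title = sprintf("Scree curve (elbow at k = %d)", object$k)
    ) +
    ggplot2::theme_minimal()
}
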