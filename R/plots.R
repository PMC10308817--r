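# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a restrained-DoF time series
#'
#' One panel per restrained coordinate (free y scales), with the restraint
#' energy as its own panel.
#'
#' @param object A [dof_timeseries()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dof_timeseries <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object), -"frame",
    names_to = "dof", values_to = "value"
  )
  long$dof <- factor(long$dof, levels = unique(long$dof))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~dof, scales = "free_y") +
    ggplot2::labs(
      x = "frame",
      y = "value (Å / degrees / kcal mol⁻¹)"
    ) +
    ggplot2::theme_bw()
}

#' Plot ranked pair-distance variability
#'
#' Distance standard deviation against rank for the retained low-variance
#' pairs.
#'
#' @param object A [pair_distance_stats()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajectory_stats <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$sd)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "rank", y = "distance SD (Å)") +
    ggplot2::theme_bw()
}

#' Plot binding-site water occupancy
#'
#' @param object A [water_occupancy()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.water_occupancy <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$frame, y = .data$n_waters)
  ) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(
      yintercept = attr(object, "mean_occupancy"), linetype = 2
    ) +
    ggplot2::labs(x = "frame", y = "waters in site") +
    ggplot2::theme_bw()
}
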