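#' Plot group mean kinetics with SEM ribbons
#'
#' One line per group (mean over plants) with a shaded +/- SEM ribbon,
#' against the common ZT axis; night periods are shaded gray.
#'
#' @param series A synced kinetics tibble (see [sync_by_transition()]).
#' @param metric Metric column to plot.
#' @param group Grouping column.
#' @param lights_on_zt_h,lights_off_zt_h Photoperiod used for night shading.
#' @return A ggplot object.
#' @export
plot_kinetics <- function(series, metric = "petiole_angle_deg",
                          group = "treatment",
                          lights_on_zt_h = 0, lights_off_zt_h = 9) {
  sg <- summarize_groups(series, group = group)
  sg <- sg[sg$metric == metric, ]
  nights <- night_rects(range(sg$zt_h), lights_on_zt_h, lights_off_zt_h)
  ggplot2::ggplot(sg, ggplot2::aes(x = .data$zt_h, y = .data$mean,
                                   color = .data[[group]],
                                   fill = .data[[group]])) +
    ggplot2::geom_rect(
      data = nights, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$from, xmax = .data$to,
                   ymin = -Inf, ymax = Inf),
      fill = "gray85", alpha = 0.6
    ) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, color = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "ZT (h)", y = metric) +
    ggplot2::theme_minimal()
}

# night intervals (ZT) overlapping a continuous zt range
night_rects <- function(zt_range, on_h, off_h) {
  day0 <- floor(zt_range[1] / 24) - 1
  day1 <- ceiling(zt_range[2] / 24) + 1
  from <- to <- numeric(0)
  for (d in day0:day1) {
    from <- c(from, d * 24 + off_h)
    to <- c(to, (d + 1) * 24 + on_h)
  }
  keep <- to > zt_range[1] & from < zt_range[2]
  tibble::tibble(from = pmax(from[keep], zt_range[1]),
                 to = pmin(to[keep], zt_range[2]))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated pose series
#'
#' @param object A `pose_series` from [simulate_pose()].
#' @param ... Unused.
#' @return A ggplot of petiole and lamina angle against time.
#' @export
autoplot.pose_series <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("t_min", "petiole_angle_deg", "lamina_angle_deg")],
    -"t_min", names_to = "metric", values_to = "deg"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$t_min, .data$deg,
                                     color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "angle (deg)") +
    ggplot2::theme_minimal()
}

#' Plot binned group statistics with significance letters
#'
#' @param object A [binned_stats()] object.
#' @param metric Metric to plot (default: first available).
#' @param ... Unused.
#' @return A ggplot of group means +/- SEM per bin, annotated with compact
#'   letter display letters.
#' @export
autoplot.binned_stats <- function(object, metric = NULL, ...) {
  s <- object$summary
  if (is.null(metric)) metric <- s$metric[1]
  s <- s[s$metric == metric, ]
  pos <- ggplot2::position_dodge(width = 0.6)
  ggplot2::ggplot(s, ggplot2::aes(x = factor(.data$bin_start_zt_h),
                                  y = .data$mean, color = .data$group)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.3, position = pos) +
    ggplot2::geom_point(position = pos) +
    ggplot2::geom_text(ggplot2::aes(label = .data$letter,
                                    y = .data$mean + 1.5 * .data$sem),
                       position = pos, vjust = -0.8, show.legend = FALSE,
                       na.rm = TRUE) +
    ggplot2::labs(x = "bin start ZT (h)", y = metric) +
    ggplot2::theme_minimal()
}
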