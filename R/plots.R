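#' Plot susceptibility-noise (or any) line profiles by pipeline
#'
#' @param profiles Named list of [line_profile()] results (names are the
#'   pipeline labels), or a tibble with columns `position`, `value`,
#'   `pipeline`.
#' @param ylab Axis label.
#' @return A ggplot object.
#' @export
plot_line_profiles <- function(profiles, ylab = "sigma(chi) [ppm]") {
  if (!is.data.frame(profiles)) {
    profiles <- do.call(rbind, lapply(names(profiles), function(nm)
      tibble::tibble(position = seq_along(profiles[[nm]]$values),
                     value = profiles[[nm]]$values, pipeline = nm)))
  }
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$position, y = .data$value,
                               colour = .data$pipeline)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position along profile [voxels]", y = ylab,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of regional means with SD error bars
#'
#' @param stats_table Tibble from [regional_stats()] / [pool_subjects()]
#'   (uses `pooled_mean`/`pooled_sd` when present, else `mean`/`sd`).
#' @param truth Optional tibble with columns `roi`, `mean` of ground-truth
#'   values, drawn as crossbars.
#' @return A ggplot object.
#' @export
plot_regional_means <- function(stats_table, truth = NULL) {
  d <- stats_table
  if ("pooled_mean" %in% names(d)) {
    d$mean <- d$pooled_mean
    d$sd <- d$pooled_sd
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$roi, y = .data$mean,
                                       fill = .data$pipeline)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::labs(x = NULL, y = "chi [ppm]", fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(truth))
    p <- p + ggplot2::geom_point(
      data = truth, ggplot2::aes(x = .data$roi, y = .data$mean),
      inherit.aes = FALSE, shape = 4, size = 3, stroke = 1.2)
  p
}

#' Bland-Altman bias plot across ROIs and pipeline pairs
#'
#' @param ba_table Stacked rows from [bland_altman()].
#' @param threshold_ppm Negligibility band half-width (default 0.01 ppm).
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba_table, threshold_ppm = 0.01) {
  d <- ba_table
  d$pair <- paste(d$pipeline_a, "-", d$pipeline_b)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$roi, y = .data$bias,
                                  colour = .data$pair)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = -threshold_ppm, ymax = threshold_ppm,
                      alpha = 0.15, fill = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$loa_lower, ymax = .data$loa_upper),
      position = ggplot2::position_dodge(0.6)) +
    ggplot2::labs(x = NULL, y = "bias [ppm]", colour = NULL) +
    ggplot2::theme_minimal()
}

#' L-curve plot
#'
#' @param lcurve Result of [lcurve_alpha()].
#' @return A ggplot object.
#' @export
plot_lcurve <- function(lcurve) {
  d <- lcurve$curve
  ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$residual_norm),
                                  y = log10(.data$solution_norm))) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = d[d$alpha == lcurve$alpha_star, ],
                        colour = "red", size = 3) +
    ggplot2::labs(x = "log10 ||D chi - field||", y = "log10 ||chi||") +
    ggplot2::theme_minimal()
}
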