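#' Plot a savings curve
#'
#' Mean travel-time savings against theta with the percentile-CI ribbon, and
#' the optimal theta marked.
#'
#' @param object A `savings_curve`.
#' @param per_visit Plot per-visit instead of total savings.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.savings_curve <- function(object, per_visit = FALSE, ...) {
  df <- tidy(object)
  if (per_visit) {
    df <- dplyr::rename(df, y = "per_visit_mean_hours",
                        lo = "per_visit_ci_low", hi = "per_visit_ci_high")
    ylab <- "Per-visit travel-time savings (hours)"
  } else {
    df <- dplyr::rename(df, y = "mean_hours",
                        lo = "ci_low_hours", hi = "ci_high_hours")
    ylab <- "Patient travel-time savings (hours)"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$y)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = attr(object, "optimal_theta"),
                        linetype = 2, colour = "grey40") +
    ggplot2::scale_x_continuous(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(
      x = expression("Proportion of hub visits reallocated, " * theta),
      y = ylab,
      title = sprintf("%s oncology outreach to %s",
                      tools::toTitleCase(attr(object, "specialty")),
                      attr(object, "satellite_id")),
      subtitle = sprintf("Optimal theta = %.0f%%; ribbon = %.0f%% percentile CI",
                         100 * attr(object, "optimal_theta"),
                         100 * attr(object, "level"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a savings distribution
#'
#' Histogram of per-iteration paired differences.
#'
#' @param object A `savings_distribution`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.savings_distribution <- function(object, bins = 40, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$difference_hours)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = mean(object$difference_hours), linetype = 2) +
    ggplot2::labs(x = "Paired savings per iteration (hours)", y = "Iterations") +
    ggplot2::theme_minimal()
}

#' Plot a site screening result
#'
#' Demand/supply ratios by site; candidates highlighted, undefined ratios
#' (zero supply) shown as missing.
#'
#' @param object A `site_screening`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.site_screening <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site_id, y = .data$ratio,
                                   fill = .data$candidate)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60"),
                               name = "Outreach candidate") +
    ggplot2::labs(x = NULL, y = "Demand / supply ratio",
                  title = sprintf("%s oncology supply-demand screening",
                                  tools::toTitleCase(attr(object, "specialty")))) +
    ggplot2::theme_minimal()
}
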