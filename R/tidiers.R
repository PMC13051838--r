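#' Tidy a savings distribution
#'
#' Returns the per-iteration outcomes as a plain tibble.
#'
#' @param x A `savings_distribution`.
#' @param ... Unused.
#' @return A tibble with one row per iteration.
#' @export
tidy.savings_distribution <- function(x, ...) {
  as_tibble(unclass_keep(x))
}

#' Glance at a savings distribution
#'
#' One-row summary via [estimate_savings()].
#'
#' @param x A `savings_distribution`.
#' @param level Confidence level.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.savings_distribution <- function(x, level = 0.95, ...) {
  as_tibble(estimate_savings(x, level = level))
}

#' Tidy a savings curve
#'
#' @param x A `savings_curve` from [theta_grid_search()].
#' @param ... Unused.
#' @return Tibble with one row per theta.
#' @export
tidy.savings_curve <- function(x, ...) {
  as_tibble(unclass_keep(x))
}

#' Glance at a savings curve
#'
#' One-row summary at the optimal theta.
#'
#' @param x A `savings_curve`.
#' @param ... Unused.
#' @return One-row tibble with `optimal_theta` and its estimate.
#' @export
glance.savings_curve <- function(x, ...) {
  best <- attr(x, "optimal_estimate")
  dplyr::bind_cols(tibble(optimal_theta = attr(x, "optimal_theta")),
                   as_tibble(best)[, setdiff(names(best), "theta")])
}

#' Tidy a savings estimate
#'
#' @param x A `savings_estimate`.
#' @param ... Unused.
#' @return One-row tibble of the estimate fields.
#' @export
tidy.savings_estimate <- function(x, ...) {
  as_tibble(unclass_keep(x))
}

#' Tidy a site screening result
#'
#' @param x A `site_screening` from [screen_sites()].
#' @param ... Unused.
#' @return Tibble with one row per site.
#' @export
tidy.site_screening <- function(x, ...) {
  as_tibble(unclass_keep(x))
}

unclass_keep <- function(x) {
  cls <- class(x)
  class(x) <- cls[!cls %in% c("savings_distribution", "savings_curve",
                              "site_screening", "savings_estimate",
                              "patient_generator")]
  x
}

#' @export
print.savings_curve <- function(x, ...) {
  cat(sprintf("<savings_curve> %s oncology -> %s; optimal theta = %.2f (mean %.1f h)\n",
              attr(x, "specialty"), attr(x, "satellite_id"),
              attr(x, "optimal_theta"), attr(x, "optimal_estimate")$mean_hours))
  NextMethod()
}
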