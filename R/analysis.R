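#' Grid search over the reallocation fraction theta
#'
#' Evaluates the policy at every theta on the grid (default 0 to 1 in steps of
#' 0.05) with one full [run_simulation()] per grid point, and reports the
#' savings curve together with the theta maximizing mean savings (ties broken
#' toward the smallest theta).
#'
#' By default the same per-iteration child seeds are reused at every grid
#' point (common random numbers across the grid): each grid point then sees
#' the same cohorts and control capacities, so differences between adjacent
#' thetas reflect the policy lever rather than sampling noise — the standard
#' variance-reduction device when comparing simulated policies. Set
#' `grid_seeds = "independent"` for fully independent runs per grid point.
#'
#' @inheritParams run_simulation
#' @param satellite_id Satellite receiving reallocated effort.
#' @param specialty Oncology specialty.
#' @param grid Increasing vector of theta values in `[0, 1]`.
#' @param level Confidence level for the percentile intervals.
#' @param grid_seeds `"common"` (default) or `"independent"`.
#' @return A `savings_curve`: tibble with one row per theta (columns `theta`
#'   plus the [estimate_savings()] fields), with attributes `optimal_theta`
#'   and `optimal_estimate`.
#' @export
#' @examples
#' inputs <- generate_catchment(synthetic_spec(n_zctas = 10, total_incidence = 40, seed = 3))
#' curve <- theta_grid_search(inputs, inputs$sites$site_id[2], "medical",
#'                            n_iter = 30, seed = 1, grid = c(0, 0.5, 1))
#' glance(curve)
theta_grid_search <- function(inputs, satellite_id, specialty,
                              n_iter = 5000, seed = NULL,
                              grid = seq(0, 1, by = 0.05), level = 0.95,
                              grid_seeds = c("common", "independent"),
                              fixed_n = FALSE, fixed_capacity = FALSE) {
  grid_seeds <- match.arg(grid_seeds)
  if (is.unsorted(grid, strictly = TRUE)) abort("grid must be strictly increasing")
  if (any(grid < 0 | grid > 1)) abort("grid values must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  children <- if (grid_seeds == "common") {
    common <- sample.int(2147483646L, n_iter)
    replicate(length(grid), common, simplify = FALSE)
  } else {
    lapply(seq_along(grid), function(i) sample.int(2147483646L, n_iter))
  }

  rows <- purrr::map2(grid, children, function(th, ch) {
    pol <- outreach_policy(satellite_id, specialty, th)
    est <- estimate_savings(
      run_simulation(inputs, pol, n_iter = n_iter,
                     fixed_n = fixed_n, fixed_capacity = fixed_capacity,
                     .child_seeds = ch),
      level = level
    )
    dplyr::bind_cols(tibble(theta = th), as_tibble(est))
  })
  curve <- purrr::list_rbind(rows)
  best <- which(curve$mean_hours == max(curve$mean_hours))[1]
  structure(curve,
            optimal_theta = curve$theta[best],
            optimal_estimate = curve[best, ],
            satellite_id = satellite_id, specialty = specialty,
            level = level, n_iter = n_iter, seed = seed,
            class = c("savings_curve", class(curve)))
}

#' Parameters for net-savings and follow-up calculations
#'
#' @param patients_per_day Average number of patients with the modelled
#'   (common) cancers an oncologist sees per satellite day; default 4.
#' @param day_granularity If `TRUE` (default), oncologist trips are counted
#'   in whole satellite days (`ceiling(m / patients_per_day)`); if `FALSE`,
#'   fractional days are allowed.
#' @param followup_multiplier Named per-specialty average number of visits per
#'   patient per year used by follow-up scaling; default medical 12,
#'   radiation 9.
#' @return A `net_savings_params` list.
#' @export
net_savings_params <- function(patients_per_day = 4,
                               day_granularity = TRUE,
                               followup_multiplier = c(medical = 12, radiation = 9)) {
  if (patients_per_day <= 0) abort("patients_per_day must be positive")
  if (any(followup_multiplier <= 0)) abort("followup_multiplier must be positive")
  structure(list(patients_per_day = patients_per_day,
                 day_granularity = day_granularity,
                 followup_multiplier = followup_multiplier),
            class = "net_savings_params")
}

#' Hours an outreach oncologist spends travelling hub to satellite
#'
#' The reallocated visits `m` are delivered over
#' `ceiling(m / patients_per_day)` satellite days (or the exact quotient when
#' `day_granularity` is off); each day costs one round trip between hub and
#' satellite.
#'
#' @param m Number of reallocated visits (vectorized, non-negative).
#' @param params A [net_savings_params()].
#' @param hub_satellite_one_way_minutes One-way hub-to-satellite driving
#'   minutes (see [site_travel_minutes()]).
#' @return Hours of oncologist travel (same length as `m`).
#' @export
#' @examples
#' oncologist_travel_hours(8, net_savings_params(), 60)  # 2 days x 2 h = 4 h
oncologist_travel_hours <- function(m, params = net_savings_params(),
                                    hub_satellite_one_way_minutes) {
  if (any(m < 0)) abort("m must be non-negative")
  days <- if (params$day_granularity) ceiling(m / params$patients_per_day)
          else m / params$patients_per_day
  days * 2 * hub_satellite_one_way_minutes / 60
}

#' Net travel-time savings after oncologist travel
#'
#' Subtracts, per iteration, the travelling oncologist's hub-satellite hours
#' (computed from that iteration's reallocated count `m`) from the patient
#' savings, then summarizes with the same mean and percentile CI as
#' [estimate_savings()]. Per-visit net savings divide by the mean `m`.
#'
#' @param dist A `savings_distribution`.
#' @param params A [net_savings_params()].
#' @param hub_satellite_one_way_minutes One-way hub-satellite minutes.
#' @param level Confidence level.
#' @return A `savings_estimate` tibble for the net savings.
#' @export
net_savings <- function(dist, params = net_savings_params(),
                        hub_satellite_one_way_minutes, level = 0.95) {
  if (nrow(dist) == 0) abort("empty savings distribution")
  net <- dist$difference_hours -
    oncologist_travel_hours(dist$m, params, hub_satellite_one_way_minutes)
  summarize_differences(net, dist$m, nrow(dist), level)
}

#' Scale savings to include follow-up visits at the satellite
#'
#' Models the case where every follow-up visit also happens at the satellite:
#' per-iteration patient savings are multiplied by the average visits per
#' patient (`multiplier`). When `params` and `hub_satellite_one_way_minutes`
#' are supplied, the result is the net version: the oncologist now delivers
#' `m * multiplier` visits, and travel days are recomputed from that total —
#' not `multiplier` times the single-visit travel, since whole-day rounding
#' is non-linear.
#'
#' @param dist A `savings_distribution`.
#' @param multiplier Average visits per patient per year (at least 1), e.g.
#'   12 for medical and 9 for radiation oncology.
#' @param params Optional [net_savings_params()] to produce net-of-oncologist
#'   travel estimates.
#' @param hub_satellite_one_way_minutes Required when `params` is given.
#' @param level Confidence level.
#' @return A `savings_estimate` tibble (per-visit fields divide by the
#'   unscaled mean `m`, i.e. per reallocated new-patient visit).
#' @export
followup_scaling <- function(dist, multiplier, params = NULL,
                             hub_satellite_one_way_minutes = NULL,
                             level = 0.95) {
  if (multiplier < 1) abort("multiplier must be at least 1")
  if (nrow(dist) == 0) abort("empty savings distribution")
  d <- dist$difference_hours * multiplier
  if (!is.null(params)) {
    if (is.null(hub_satellite_one_way_minutes)) {
      abort("hub_satellite_one_way_minutes required for net follow-up scaling")
    }
    d <- d - oncologist_travel_hours(dist$m * multiplier, params,
                                     hub_satellite_one_way_minutes)
  }
  summarize_differences(d, dist$m, nrow(dist), level)
}

summarize_differences <- function(d, m, n, level) {
  a <- (1 - level) / 2
  ci <- quantile(d, c(a, 1 - a), names = FALSE)
  mean_m <- mean(m)
  pv <- d[m > 0] / m[m > 0]
  pv_ci <- if (length(pv) > 0) quantile(pv, c(a, 1 - a), names = FALSE) else c(NA_real_, NA_real_)
  out <- tibble(
    mean_hours = mean(d),
    ci_low_hours = ci[1], ci_high_hours = ci[2],
    per_visit_mean_hours = if (mean_m > 0) mean(d) / mean_m else NA_real_,
    per_visit_ci_low = pv_ci[1], per_visit_ci_high = pv_ci[2],
    n_iter = n
  )
  structure(out, level = level, class = c("savings_estimate", class(out)))
}

#' Bootstrap supply/demand screening of satellite sites
#'
#' Identifies satellites whose local demand outstrips their supply. Each
#' bootstrap replicate samples an annual cohort from the patient generator,
#' draws specialty demand, sends every demanding patient to their closest
#' site by one-way travel time (ties toward the first site in site-id order),
#' and tallies counts by site. Over replicates this yields each site's mean
#' and SD of proximal demanding patients; dividing the mean by the site's
#' historical annual volume gives a demand/supply ratio. Sites with zero
#' supply get an undefined (`NA`) ratio rather than an error or infinity. A
#' satellite is flagged as an outreach candidate when its ratio exceeds
#' `candidate_factor` times the hub's ratio.
#'
#' @param inputs An [outreach_inputs()] bundle.
#' @param specialty Specialty to screen.
#' @param n_boot Number of bootstrap replicates (default 5000).
#' @param seed Optional seed.
#' @param candidate_factor Multiple of the hub ratio above which a satellite
#'   is flagged (default 1.5).
#' @param fixed_n Use `round(lambda)` cohort sizes.
#' @return A `site_screening`: tibble with one row per site — `site_id`,
#'   `role`, `demand_mean`, `demand_sd`, `supply`, `ratio` (`NA` when supply
#'   is zero), `candidate`.
#' @export
screen_sites <- function(inputs, specialty, n_boot = 5000, seed = NULL,
                         candidate_factor = 1.5, fixed_n = FALSE) {
  cm <- compile_sim_screen(inputs, specialty)
  if (!is.null(seed)) set.seed(seed)
  n_sites <- length(cm$site_levels)
  counts <- matrix(0L, n_boot, n_sites)
  for (b in seq_len(n_boot)) {
    n <- if (fixed_n) as.integer(round(cm$lambda)) else rpois(1L, cm$lambda)
    if (n == 0L) next
    cells <- sample.int(length(cm$cell_prob), n, replace = TRUE, prob = cm$cell_prob)
    demanding <- cells[runif(n) < cm$p_dem[cells]]
    counts[b, ] <- tabulate(cm$nearest[cm$cell_z[demanding]], nbins = n_sites)
  }
  supply <- vapply(cm$site_levels, function(s) {
    sum(inputs$volumes$mean_annual_volume[
      inputs$volumes$site_id == s & inputs$volumes$specialty == specialty])
  }, numeric(1))
  demand_mean <- colMeans(counts)
  demand_sd <- apply(counts, 2, stats::sd)
  ratio <- ifelse(supply > 0, demand_mean / supply, NA_real_)
  hub_ratio <- ratio[cm$site_levels == hub_site(inputs)]
  role <- inputs$sites$role[match(cm$site_levels, inputs$sites$site_id)]
  candidate <- !is.na(ratio) & role == "satellite" &
    !is.na(hub_ratio) & ratio > candidate_factor * hub_ratio
  out <- tibble(
    site_id = cm$site_levels, role = role,
    demand_mean = demand_mean, demand_sd = demand_sd,
    supply = unname(supply), ratio = unname(ratio), candidate = candidate
  )
  structure(out, specialty = specialty, n_boot = n_boot,
            candidate_factor = candidate_factor,
            class = c("site_screening", class(out)))
}

compile_sim_screen <- function(inputs, specialty) {
  cm <- compile_sim(inputs, specialty)
  # closest site per ZCTA is constant across replicates; ties -> first site id
  ow <- cm$rt / 2
  cm$nearest <- apply(ow, 1, which.min)
  cm
}
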