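## Pre-resolve the input tables into plain vectors/matrices once per
## simulation so the per-iteration loop is cheap.
compile_sim <- function(inputs, specialty) {
  dist <- build_joint_distribution(inputs$incidence, inputs$stages)
  zcta_levels <- sort(unique(inputs$incidence$zcta_id))
  site_levels <- inputs$sites$site_id

  dem <- inputs$demand[inputs$demand$specialty == specialty, ]
  if (nrow(dem) == 0) abort(sprintf("no demand rows for specialty '%s'", specialty))
  p_dem <- dem$prob[match(paste(dist$cancer_type, dist$stage),
                          paste(dem$cancer_type, dem$stage))]
  if (anyNA(p_dem)) abort("demand table does not cover the (type, stage) domain")

  rt <- matrix(NA_real_, length(zcta_levels), length(site_levels),
               dimnames = list(zcta_levels, site_levels))
  rt[cbind(match(inputs$travel$zcta_id, zcta_levels),
           match(inputs$travel$site_id, site_levels))] <-
    2 * inputs$travel$one_way_minutes
  if (anyNA(rt)) abort("travel table incomplete over (zcta, site)")

  pairs <- inputs$volumes[inputs$volumes$specialty == specialty, ] |>
    dplyr::arrange(.data$site_id, .data$oncologist_id)
  if (nrow(pairs) == 0) abort(sprintf("no oncologist/site pairs for specialty '%s'", specialty))

  list(
    lambda = attr(dist, "lambda"),
    cell_prob = dist$prob,
    cell_z = match(dist$zcta_id, zcta_levels),
    p_dem = p_dem,
    rt = rt,
    pair_onc = pairs$oncologist_id,
    pair_site_idx = match(pairs$site_id, site_levels),
    pair_mean = pairs$mean_annual_volume,
    hub_idx = match(hub_site(inputs), site_levels),
    site_levels = site_levels
  )
}

iterate_once <- function(cm, theta, sat_idx, fixed_n = FALSE, fixed_capacity = FALSE) {
  n <- if (fixed_n) as.integer(round(cm$lambda)) else rpois(1L, cm$lambda)
  cells <- if (n > 0) sample.int(length(cm$cell_prob), n, replace = TRUE,
                                 prob = cm$cell_prob) else integer()
  demanding <- cells[runif(n) < cm$p_dem[cells]]
  zidx <- cm$cell_z[demanding]

  k <- length(cm$pair_mean)
  slots <- if (fixed_capacity) as.integer(round(cm$pair_mean)) else rpois(k, cm$pair_mean)
  hub_cols <- which(cm$pair_site_idx == cm$hub_idx)
  hub_total <- sum(slots[hub_cols])
  m <- as.integer(ceiling(theta * hub_total))

  cost_ctl <- cm$rt[zidx, cm$pair_site_idx, drop = FALSE]
  a_ctl <- greedy_assign_cpp(cost_ctl, slots)

  if (m > 0L) {
    units <- rep(hub_cols, slots[hub_cols])
    moved <- units[sample.int(length(units), m)]
    moved_per <- tabulate(match(moved, hub_cols), nbins = length(hub_cols))
    pol_slots <- slots
    pol_slots[hub_cols] <- pol_slots[hub_cols] - moved_per
    new_cols <- which(moved_per > 0L)
    cost_pol <- cbind(cost_ctl,
                      cm$rt[zidx, rep(sat_idx, length(new_cols)), drop = FALSE])
    a_pol <- greedy_assign_cpp(cost_pol, c(pol_slots, moved_per[new_cols]))
    shifted <- sum(a_pol > k, na.rm = TRUE)
    pol_min <- sum(cost_pol[cbind(which(!is.na(a_pol)), a_pol[!is.na(a_pol)])])
  } else {
    a_pol <- a_ctl
    shifted <- 0L
    pol_min <- sum(cost_ctl[cbind(which(!is.na(a_ctl)), a_ctl[!is.na(a_ctl)])])
  }
  ctl_min <- sum(cost_ctl[cbind(which(!is.na(a_ctl)), a_ctl[!is.na(a_ctl)])])

  un_ctl <- sum(is.na(a_ctl))
  un_pol <- sum(is.na(a_pol))
  stopifnot(un_ctl == un_pol)  # equal total slots across arms

  list(control_hours = ctl_min / 60, policy_hours = pol_min / 60,
       difference_hours = (ctl_min - pol_min) / 60,
       m = m, shifted_assigned = shifted, unassigned = un_ctl)
}

#' Run one paired policy/control simulation iteration
#'
#' One iteration samples, under common random numbers shared by both arms:
#' the annual incident cohort (size and composition), each patient's
#' specialty demand, the arrival order, and the control-arm visit capacity
#' across oncologist/site pairs. The policy arm is the control capacity with
#' `theta` of the hub's slots moved to the satellite via [apply_policy()]
#' semantics. Both arms are assigned greedily on their own cost matrices and
#' the paired difference in total round-trip patient travel time (control
#' minus policy, hours) is recorded.
#'
#' @param inputs An [outreach_inputs()] bundle.
#' @param policy An [outreach_policy()].
#' @param seed Optional integer seed for this iteration.
#' @param fixed_n Use `round(lambda)` patients instead of a Poisson cohort
#'   size.
#' @param fixed_capacity Use `round(mean)` slots instead of Poisson capacity.
#' @return One-row tibble: `control_hours`, `policy_hours`,
#'   `difference_hours`, `m` (slots reallocated), `shifted_assigned`
#'   (patients assigned to reallocated columns), `unassigned`.
#' @export
run_iteration <- function(inputs, policy, seed = NULL,
                          fixed_n = FALSE, fixed_capacity = FALSE) {
  stopifnot(inherits(policy, "outreach_policy"))
  cm <- compile_sim(inputs, policy$specialty)
  sat_idx <- match(policy$satellite_id, cm$site_levels)
  if (is.na(sat_idx)) abort(sprintf("unknown satellite '%s'", policy$satellite_id))
  if (!is.null(seed)) set.seed(seed)
  as_tibble(iterate_once(cm, policy$theta, sat_idx, fixed_n, fixed_capacity))
}

#' Run the full paired counterfactual simulation
#'
#' Repeats [run_iteration()] `n_iter` times (default 5000). A master seed
#' spawns one child seed per iteration so runs are reproducible given
#' `(inputs, policy, n_iter, seed)`.
#'
#' @inheritParams run_iteration
#' @param n_iter Number of iterations.
#' @param seed Optional master seed.
#' @param .child_seeds Optional explicit vector of `n_iter` per-iteration
#'   seeds (used by [theta_grid_search()] to share common random numbers
#'   across grid points); overrides `seed`-derived children.
#' @return A `savings_distribution`: tibble with one row per iteration
#'   (columns as in [run_iteration()] plus `iteration`), with the policy,
#'   seed and `n_iter` stored as attributes.
#' @export
#' @examples
#' inputs <- generate_catchment(synthetic_spec(n_zctas = 10, total_incidence = 40, seed = 3))
#' pol <- outreach_policy(inputs$sites$site_id[2], "medical", 0.25)
#' dist <- run_simulation(inputs, pol, n_iter = 50, seed = 1)
#' estimate_savings(dist)
run_simulation <- function(inputs, policy, n_iter = 5000, seed = NULL,
                           fixed_n = FALSE, fixed_capacity = FALSE,
                           .child_seeds = NULL) {
  stopifnot(inherits(policy, "outreach_policy"), n_iter >= 1)
  cm <- compile_sim(inputs, policy$specialty)
  sat_idx <- match(policy$satellite_id, cm$site_levels)
  if (is.na(sat_idx)) abort(sprintf("unknown satellite '%s'", policy$satellite_id))

  if (is.null(.child_seeds)) {
    if (!is.null(seed)) set.seed(seed)
    .child_seeds <- sample.int(2147483646L, n_iter)
  }
  stopifnot(length(.child_seeds) == n_iter)

  rows <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    set.seed(.child_seeds[i])
    rows[[i]] <- iterate_once(cm, policy$theta, sat_idx, fixed_n, fixed_capacity)
  }
  out <- dplyr::bind_rows(rows)
  out$iteration <- seq_len(n_iter)
  out <- out[, c("iteration", "control_hours", "policy_hours",
                 "difference_hours", "m", "shifted_assigned", "unassigned")]
  structure(as_tibble(out),
            policy = policy, seed = seed, n_iter = n_iter,
            class = c("savings_distribution", class(as_tibble(out))))
}

#' Summarize a savings distribution
#'
#' Point estimate and percentile confidence interval for the travel-time
#' savings attributable to the policy. The mean is the average per-iteration
#' paired difference (control minus policy, hours); the CI is taken as the
#' empirical `(1-level)/2` and `1-(1-level)/2` quantiles of the per-iteration
#' differences (linear interpolation between order statistics, R's default
#' quantile type 7). Per-visit savings divide by the number of reallocated
#' slots: the point estimate is `mean(difference) / mean(m)` and the
#' per-visit CI takes quantiles of the per-iteration ratios `difference / m`
#' (iterations with `m = 0` excluded).
#'
#' @param dist A `savings_distribution` from [run_simulation()].
#' @param level Confidence level (default 0.95).
#' @return One-row tibble of class `savings_estimate`: `mean_hours`,
#'   `ci_low_hours`, `ci_high_hours`, `per_visit_mean_hours`,
#'   `per_visit_ci_low`, `per_visit_ci_high`, `n_iter`.
#' @export
estimate_savings <- function(dist, level = 0.95) {
  if (nrow(dist) == 0) abort("empty savings distribution")
  d <- dist$difference_hours
  a <- (1 - level) / 2
  ci <- quantile(d, c(a, 1 - a), names = FALSE)
  mean_m <- mean(dist$m)
  pv <- d[dist$m > 0] / dist$m[dist$m > 0]
  pv_ci <- if (length(pv) > 0) quantile(pv, c(a, 1 - a), names = FALSE) else c(NA_real_, NA_real_)
  out <- tibble(
    mean_hours = mean(d),
    ci_low_hours = ci[1], ci_high_hours = ci[2],
    per_visit_mean_hours = if (mean_m > 0) mean(d) / mean_m else NA_real_,
    per_visit_ci_low = pv_ci[1], per_visit_ci_high = pv_ci[2],
    n_iter = nrow(dist)
  )
  structure(out, level = level,
            class = c("savings_estimate", class(out)))
}
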