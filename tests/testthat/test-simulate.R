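test_that("a zero-theta policy yields exactly zero savings", {
  set.seed(61)
  for (rep in 1:20) {
    inputs <- random_small_inputs()
    pol <- random_policy(inputs, theta = 0)
    out <- run_iteration(inputs, pol, seed = sample.int(1e6, 1))
    expect_identical(out$difference_hours, 0)
    expect_identical(out$m, 0L)
  }
})

test_that("iterations are reproducible under a fixed seed", {
  inputs <- toy_inputs(sat_volume = 10)
  pol <- outreach_policy("S", "medical", 0.3)
  a <- run_iteration(inputs, pol, seed = 99)
  b <- run_iteration(inputs, pol, seed = 99)
  expect_identical(a, b)

  d1 <- run_simulation(inputs, pol, n_iter = 25, seed = 5)
  d2 <- run_simulation(inputs, pol, n_iter = 25, seed = 5)
  expect_identical(tidy(d1), tidy(d2))
  expect_equal(nrow(d1), 25)
})

test_that("two-site limit: savings equal shifted count times the travel gap", {
  # every patient lives in one ZCTA next to the satellite; control supply is
  # hub-only, so each shifted assignment saves exactly the round-trip gap
  ow_hub <- 75; ow_sat <- 5
  inputs <- toy_inputs(zcta_hub_minutes = ow_hub, zcta_sat_minutes = ow_sat,
                       incidence = c(a = 0, b = 30), hub_volume = 40,
                       sat_volume = 0)
  pol <- outreach_policy("S", "medical", 0.4)
  for (s in 1:50) {
    out <- run_iteration(inputs, pol, seed = s)
    expect_identical(
      out$difference_hours,
      out$shifted_assigned * 2 * (ow_hub - ow_sat) / 60
    )
  }
})

test_that("run_iteration matches the composed stage-by-stage pipeline", {
  inputs <- toy_inputs(sat_volume = 6)
  pol <- outreach_policy("S", "medical", 0.35)
  out <- run_iteration(inputs, pol, seed = 42)

  set.seed(42)
  dist <- build_joint_distribution(inputs$incidence, inputs$stages)
  cohort <- sample_annual_cohort(dist)
  cohort <- draw_specialty_demand(cohort, inputs$demand, "medical")
  demanding <- cohort[cohort$demand_medical, ]
  control <- sample_capacity(inputs$volumes, "medical")
  policy_alloc <- apply_policy(control, pol, "H")

  c_ctl <- build_cost_matrix(demanding, control, inputs$travel)
  c_pol <- build_cost_matrix(demanding, policy_alloc, inputs$travel)
  a_ctl <- greedy_assign(c_ctl, control$slots)
  a_pol <- greedy_assign(c_pol, policy_alloc$slots)

  expect_equal(out$control_hours, total_travel_time(c_ctl, a_ctl) / 60)
  expect_equal(out$policy_hours, total_travel_time(c_pol, a_pol) / 60)
  expect_equal(out$m, sum(policy_alloc$slots[policy_alloc$provenance == "reallocated"]))
})

test_that("common random numbers reduce the variance of the paired difference", {
  inputs <- generate_catchment(dartmouth_like_preset(seed = 7))
  pol <- outreach_policy("STJ", "medical", 0.45)
  d <- run_simulation(inputs, pol, n_iter = 150, seed = 20)
  expect_lt(stats::var(d$difference_hours),
            stats::var(d$control_hours) + stats::var(d$policy_hours))
})

test_that("savings are invariant to relabelling oncologists", {
  inputs <- toy_inputs(sat_volume = 6)
  relabelled <- inputs
  relabelled$volumes$oncologist_id <- rev(relabelled$volumes$oncologist_id)
  pol <- outreach_policy("S", "medical", 0.5)
  a <- run_simulation(inputs, pol, n_iter = 30, seed = 3,
                      fixed_capacity = TRUE)
  b <- run_simulation(relabelled, pol, n_iter = 30, seed = 3,
                      fixed_capacity = TRUE)
  expect_equal(a$difference_hours, b$difference_hours)
})

test_that("estimate_savings implements the percentile-method conventions", {
  mk <- function(d, m = 1L) tibble::tibble(difference_hours = d,
                                           m = rep(m, length(d)))
  # linear-interpolation quantiles on 0..100
  est <- estimate_savings(mk(0:100))
  expect_equal(est$ci_low_hours, 2.5)
  expect_equal(est$ci_high_hours, 97.5)
  expect_equal(est$mean_hours, 50)

  # degenerate constant sequence collapses to a point interval
  est2 <- estimate_savings(mk(rep(3.25, 10)))
  expect_equal(est2$mean_hours, 3.25)
  expect_equal(est2$ci_low_hours, 3.25)
  expect_equal(est2$ci_high_hours, 3.25)

  # per-visit fields divide by the reallocated count
  est3 <- estimate_savings(mk(c(10, 20), m = 5L))
  expect_equal(est3$per_visit_mean_hours, 15 / 5)

  # CI brackets the mean and theta = 0 runs give identically zero estimates
  inputs <- toy_inputs(sat_volume = 5)
  d0 <- run_simulation(inputs, outreach_policy("S", "medical", 0),
                       n_iter = 40, seed = 2)
  e0 <- estimate_savings(d0)
  expect_equal(c(e0$mean_hours, e0$ci_low_hours, e0$ci_high_hours), c(0, 0, 0))

  expect_error(estimate_savings(mk(numeric())), "empty")
})

test_that("unassigned counts always match across arms", {
  # demand far exceeding supply forces unassigned patients in both arms
  inputs <- toy_inputs(incidence = c(a = 60, b = 60), hub_volume = 20,
                       sat_volume = 0)
  pol <- outreach_policy("S", "medical", 0.5)
  d <- run_simulation(inputs, pol, n_iter = 40, seed = 8)
  expect_true(all(d$unassigned > 0))
})
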