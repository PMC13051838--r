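# Small input bundles built in code at test time.

# Minimal hand-written two-site system: one hub, one satellite, two ZCTAs.
toy_inputs <- function(zcta_sat_minutes = 10, zcta_hub_minutes = 60,
                       incidence = c(a = 40, b = 20),
                       hub_volume = 50, sat_volume = 0) {
  vols <- tibble::tibble(
    oncologist_id = c("o1", "o2"), site_id = c("H", "S"),
    specialty = "medical", mean_annual_volume = c(hub_volume, sat_volume)
  )
  outreach_inputs(
    sites = tibble::tibble(site_id = c("H", "S"), role = c("hub", "satellite"),
                           name = c("Hub", "Sat")),
    travel = tibble::tibble(
      zcta_id = rep(c("a", "b"), each = 2),
      site_id = rep(c("H", "S"), 2),
      one_way_minutes = c(20, 70, zcta_hub_minutes, zcta_sat_minutes)
    ),
    incidence = tibble::tibble(zcta_id = names(incidence), cancer_type = "lung",
                               mean_annual_cases = unname(incidence)),
    stages = tibble::tibble(cancer_type = "lung", stage = c("early", "late"),
                            prob = c(0.6, 0.4)),
    demand = tibble::tibble(cancer_type = "lung",
                            stage = rep(c("early", "late"), 2),
                            specialty = rep(c("medical", "radiation"), each = 2),
                            prob = c(0.9, 0.95, 0.4, 0.6)),
    volumes = vols[vols$mean_annual_volume > 0 | vols$site_id == "H", ]
  )
}

# Random miniature catchment for property-based checks: 2-5 ZCTAs, 1-3
# satellites, small incidence so iterations are cheap.
random_small_inputs <- function() {
  n_sat <- sample(1:3, 1)
  spec <- synthetic_spec(
    n_zctas = sample(2:6, 1),
    n_satellites = n_sat,
    extent_km = runif(1, 60, 250),
    total_incidence = runif(1, 3, 25),
    clustering = runif(1),
    hub_share = c(medical = runif(1, 0.3, 0.9), radiation = runif(1, 0.3, 0.9)),
    supply_demand_ratio = runif(1, 0.6, 1.4),
    max_volume_per_oncologist = sample(3:12, 1),
    seed = sample.int(1e6, 1)
  )
  generate_catchment(spec)
}

random_policy <- function(inputs, theta = NULL) {
  sats <- inputs$sites$site_id[inputs$sites$role == "satellite"]
  sp <- sample(unique(inputs$volumes$specialty), 1)
  outreach_policy(sample(sats, 1), sp,
                  theta %||% sample(seq(0, 1, 0.05), 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
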