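# oncoutreach

Stochastic counterfactual simulation for evaluating and optimizing **oncology
outreach policies** in hub-and-spoke cancer networks — arrangements where
oncologists based at a central ("hub") hospital travel to satellite clinics on
a set cadence so patients can receive specialty care closer to home.

The package is aimed at health-services researchers and capacity planners who
want to ask, before committing clinic schedules: *if we reallocated a fraction
θ of the hub's annual new-patient visits of one specialty to a given
satellite, how much round-trip travel time would next year's incident patients
save — and what θ maximizes that saving?*

## The model

An outreach policy is a triple *(satellite, specialty, θ)* with θ ∈ [0, 1] the
proportion of the hub's annual new-patient visits to reallocate. Each
simulation iteration draws one plausible year and compares two counterfactual
arms under **common random numbers** (identical patients, demand, arrival
order, and baseline capacity):

1. **Patients.** The annual cohort size is Poisson with mean λ (the total mean
   annual incidence); each patient's (ZCTA, cancer type, stage) is drawn from
   the joint distribution `p(z, t, s) = p(z, t) · p(s | t)`, which assumes
   residence and stage are conditionally independent given cancer type.
   Specialty demand is Bernoulli with probability depending on (type, stage).
2. **Capacity.** Each oncologist/site pair receives `Poisson(mean annual
   volume)` visit slots. In the policy arm, `m = ⌈θ · hub slots⌉` slot-units
   are drawn uniformly without replacement from the hub's columns and moved to
   the satellite (an oncologist may end up splitting time across two sites);
   the control arm keeps the historical allocation. Total slots are conserved.
3. **Assignment.** A cost matrix *C* holds each patient × oncologist/site pair
   round-trip travel time. Patients are assigned **greedily, first-come-first-
   served**: in arrival order each takes the cheapest column with remaining
   capacity. A globally optimal assignment is deliberately not used — it would
   ignore the chronological order in which incident patients book care.
4. **Outcome.** Total incurred travel time per arm is the inner product
   ⟨C, A⟩ of cost and Boolean assignment matrices. The paired difference
   (control − policy, hours) is recorded.

Over `n_iter` iterations (default 5000) the savings estimate is the mean
paired difference with a 95% **percentile-method** confidence interval;
per-visit savings divide by the reallocated count m. A grid search over
θ ∈ {0, 0.05, …, 1} traces the savings curve, which characteristically rises,
peaks at an interior θ*, and falls back toward or below zero as hub-proximal
patients start being displaced. Extensions compute **net savings** (subtracting
the travelling oncologist's hub–satellite hours, with visits delivered in
whole satellite days) and **follow-up scaling** (all follow-up visits also at
the satellite), and a bootstrap **supply/demand screening** ranks satellites
by the ratio of locally closest demand to historical supply.

Because real EHR and registry inputs are rarely shareable, the package ships a
synthetic-catchment generator (`generate_catchment()`) producing fully
validated input bundles on a planar geography, including a
`dartmouth_like_preset()` that emulates a rural academic network with one hub
and three satellites, one of which is strongly under-supplied relative to its
local demand.

## Worked example

```r
library(oncoutreach)

inputs <- generate_catchment(dartmouth_like_preset(seed = 7))
inputs
#> <outreach_inputs>
#>   sites:     4 (1 hub: LEB)
#>   ZCTAs:     64
#>   incidence: 586.0 mean annual cases over 3 cancer types
#>   volumes:   11 oncologist/site pairs (medical, radiation)

screen_sites(inputs, "medical", n_boot = 1000, seed = 1)
#>   site_id role      demand_mean demand_sd supply ratio candidate
#> 1 LEB     hub             135.      11.3     297 0.455 FALSE
#> 2 KEE     satellite       125.      11.4      95 1.32  TRUE
#> 3 MAN     satellite        56.0      7.48    105 0.534 FALSE
#> 4 STJ     satellite       210.      14.6      56 3.74  TRUE
```

The STJ satellite's demand/supply ratio (3.74) dwarfs the hub's (0.455): about
210 demanding patients a year live closest to a clinic supplying only 56
annual new-patient visits, so it is flagged as an outreach candidate. Optimize
the reallocation fraction for medical oncology there:

```r
curve <- theta_grid_search(inputs, "STJ", "medical", n_iter = 200, seed = 1)
glance(curve)
#>   optimal_theta mean_hours ci_low_hours ci_high_hours per_visit_mean_hours
#> 1          0.55       268.         192.          317.                 1.63
autoplot(curve)   # savings vs theta with the CI ribbon
```

Shifting 55% of the hub's medical-oncology visits saves about 268 hours of
patient travel per year (95% CI 192–317), roughly 1.6 hours per shifted visit.
Accounting for the oncologist's own travel (78.9 one-way minutes hub→STJ,
4 patients/day, whole-day trips) and for follow-up visits:

```r
ow <- site_travel_minutes(inputs, "LEB", "STJ")
d  <- run_simulation(inputs, outreach_policy("STJ", "medical", 0.55),
                     n_iter = 200, seed = 1)
net_savings(d, net_savings_params(), ow)
#>   mean_hours ci_low_hours ci_high_hours per_visit_mean_hours ...
#> 1       159.         83.9          201.                0.969
followup_scaling(d, 12)
#>   mean_hours ci_low_hours ci_high_hours per_visit_mean_hours ...
#> 1      3214.        2302.         3808.                 19.6
```

Net of oncologist travel the policy still saves ~159 hours; if all 12 annual
medical-oncology visits per patient moved with the policy, patient savings
would scale to ~3200 hours.

A thin command-line front end mirrors this workflow
(`inst/cli/oncoutreach synth|validate|screen|simulate|optimize|plot`), writing
CSV/JSON artifacts plus a `run_manifest.json` for provenance.

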