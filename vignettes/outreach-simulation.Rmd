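---
title: "Simulating and optimizing oncology outreach policies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and optimizing oncology outreach policies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoutreach)
```

## The question the simulator answers

In hub-and-spoke cancer networks, most specialist capacity sits at the hub
hospital while a large share of incident patients live closer to satellite
clinics. Outreach — oncologists travelling to satellites on a set cadence —
trades oncologist time for patient travel time. The simulator estimates the
round-trip patient travel-time savings that a specific outreach policy
*(satellite, specialty, θ)* would capture over the following year, where θ is
the proportion of the hub's annual new-patient visits of that specialty
reallocated to the satellite, and searches the θ grid for the saving-maximal
policy.

The estimand is counterfactual: the same year simulated twice, once with the
historical visit allocation (control) and once with the policy applied, with
every shared random quantity held identical between arms.

## Model components and assumptions

**Patient generator.** The joint distribution over (residence ZCTA, cancer
type, stage) is factored as `p(z, t) · p(s | t)`: residence and stage are
assumed conditionally independent given cancer type. This mirrors how such
inputs are typically available — registries provide ZCTA × type counts,
clinical records provide type × stage — and is the assumption that lets the
two sources be fused. The annual cohort size is `N ~ Poisson(λ)` with λ the
incidence-table total. Poisson count sampling is the simplest generative
choice consistent with the year-to-year variability such systems exhibit in
proximal patient counts (SDs close to √mean); `fixed_n = TRUE` freezes
`N = round(λ)` for debugging and variance decomposition. Specialty demand is
an independent Bernoulli per patient with probability indexed by (type,
stage, specialty).

**Arrival order.** First-come-first-served assignment needs an arrival order,
but nothing in the data defines one; we take the i.i.d. sampling order of the
cohort — a uniformly random permutation — and share it across arms. No
seasonality or within-year timing is modelled.

**Capacity.** Visit slots per oncologist/site pair are `Poisson(mean annual
volume)`, independent across pairs (`fixed_capacity = TRUE` uses
`round(mean)`). The policy transformation moves `m = ⌈θ · hub total⌉`
slot-units, drawn uniformly without replacement across the hub's columns of
the specialty, into new satellite columns appended after all original
columns. Rounding up is the unique rule consistent with the worked examples
the rule must reproduce (2 of 8 at θ = 0.25; 15 of 287 and 5 of 97 at
θ = 0.05); round-half-up would give 14 of 287. Moving slot-units rather than
whole clinicians reflects that a single oncologist can apportion time across
two sites. `m` is recomputed from each iteration's sampled hub total, so the
policy scales with the year's capacity draw.

**Assignment.** Patients are assigned in arrival order, each to the
cheapest (round-trip minutes) column with remaining capacity; ties break
toward the lowest column index under the deterministic column order (sites by
id, oncologists by id, reallocated columns last), making runs bit-for-bit
reproducible. Patients arriving after capacity is exhausted are unassigned —
a valid outcome counted separately; both arms have equal total slots, so
unassigned counts match per iteration (asserted at run time) and contribute
zero to both arms' totals. A globally optimal (Hungarian-style) assignment is
deliberately rejected in the pipeline: it would let later patients displace
earlier ones, which mis-models how incident patients actually book care. A
literal step-by-step reference implementation serves as the test oracle for
the compiled greedy routine.

**Outcome and inference.** Totals are inner products ⟨C, A⟩ in minutes,
converted to hours only at the reporting boundary. Savings are summarized by
the mean per-iteration paired difference and a percentile CI — empirical
`(1−level)/2` and `1−(1−level)/2` quantiles of the per-iteration differences,
using linear interpolation between order statistics (R's default quantile
type 7; stated for bit-reproducibility). The CI is computed on the paired
differences themselves, not on bootstrap means: it describes scenario
uncertainty, the spread of plausible annual outcomes, which is the quantity a
planner faces. Per-visit savings use `mean(difference) / mean(m)` with a CI
from the per-iteration ratios `difference / m` (m = 0 iterations excluded).

## Seeding and common random numbers

A master seed spawns one child seed per iteration; both arms of an iteration
consume the same child stream, so the cohort, demand, order and control
capacity are identical between arms and the paired difference isolates the
policy effect. `theta_grid_search()` additionally reuses the *same* child
seeds at every grid point by default. Common random numbers across the policy
lever is standard practice when comparing simulated policies: adjacent grid
points then differ only through θ, which sharpens the curve and the argmax at
a given `n_iter`. `grid_seeds = "independent"` gives fully independent runs
per grid point instead.

## The θ grid search and the shape of the curve

The default grid is 0 to 1 in 5% increments (21 points), one full simulation
per point; the optimal θ is the argmax of mean savings with ties toward the
smaller θ. On the bundled preset the curve is an inverted U: savings rise
while reallocation mostly serves satellite-proximal patients, peak at an
interior θ*, and decline toward (or below) zero as hub-proximal patients get
displaced to the distant satellite. CI width grows with θ because larger
reallocations amplify scenario-to-scenario variation. At moderate `n_iter`
the 2.5/97.5 percentile endpoints rest on a handful of tail observations, so
the *sample* widths can dip by a few percent where the population widths
plateau; the test suite therefore checks width monotonicity at the
Monte-Carlo resolution of the estimator (a joint bootstrap over the shared
iteration indices bounds each adjacent step), a check that converges to
strict monotonicity as `n_iter` grows. The grid is embarrassingly parallel
and an exhaustive sweep at `n_iter = 5000` runs in about a minute on a single
CPU at the preset's scale, so no search heuristic is enabled by default.

## Net savings and follow-up visits

Net savings subtract the travelling oncologist's time: delivering `m` visits
at `patients_per_day` (default 4, reflecting that only a minority of a
generalist day is spent on the modelled common cancers) takes
`⌈m / patients_per_day⌉` satellite days by default, each costing one
hub–satellite round trip. Whole-day rounding is the realistic default;
`day_granularity = FALSE` gives the exact fractional quotient. The
hub–satellite one-way minutes are passed explicitly — the ZCTA→site travel
table does not define site-to-site times — and `site_travel_minutes()`
derives them from the generator's stored geometry when available.

Follow-up scaling multiplies per-iteration patient savings by the average
annual visits per patient (defaults: 12 medical, 9 radiation). For the net
variant the oncologist's days are recomputed from `m × multiplier` visits;
because of whole-day rounding this is *not* `multiplier ×` the single-visit
travel, and the implementation (and a dedicated test) respects that
non-linearity.

## Site screening

Candidate satellites are found before any policy is simulated: each bootstrap
replicate samples a cohort, draws specialty demand, sends every demanding
patient to their closest site by one-way minutes (ties toward the first site
in the deterministic order), and tallies by site. The mean tally over
replicates divided by a site's historical annual volume is its demand/supply
ratio; zero-supply sites report an undefined (`NA`) ratio rather than an
error or infinity. "Substantially exceeding the hub's ratio" is not a defined
quantity, so the candidate flag uses a configurable multiple of the hub ratio
(default 1.5×) and the raw ratios are always reported for judgment.

## The synthetic catchment generator

Real encounter-level inputs are typically not shareable, so the generator
produces complete validated bundles with the statistical structure the
simulator assumes: ZCTA centroids on a plane (uniform, or clustered around
sites with probability `clustering`), travel time affine in Euclidean
distance (`terminal_minutes + 60·d/speed_kmh` — monotone in distance with a
terminal floor), Gamma-heterogeneous incidence weights, demand probabilities
increasing with stage band, and supply split hub-first. Defaults fix cancer
types to breast/colorectal/lung with `early`/`late` stage bands; both are
configurable, and stage labels are free-form strings throughout the package
since no clinical staging standard is enforced. The preset
`dartmouth_like_preset()` pins the per-site supply table — medical (297, 95,
105, 56) and radiation (97, 111, 0, 59) for (hub, KEE, MAN, STJ), including
one satellite with no radiation presence — and clusters incidence so the STJ
analogue is strongly under-supplied. Its demand probabilities (medical
0.85/0.95 early/late, radiation 0.35/0.55) are placeholders with the right
qualitative shape, not estimates from any health system; with the preset's
stage mix they imply roughly 526 annual medical and 260 radiation demanding
patients from λ = 586.

What passing tests on synthetic data do **not** show: planar geometry has no
road networks, rivers or seasonal travel; incidence clusters are isotropic;
demand probabilities are invented; oncologist behaviour (preferences,
attrition, scheduling) is absent. Results on real catchments require real
travel matrices and registry/EHR-derived tables supplied through the same CSV
bundle.

## Numerical and design choices

- Travel times are stored one-way in minutes; costs are round trips
  (2 × one-way); all reported savings are hours (divide by 60 at the
  boundary only).
- Quantiles: linear interpolation (type 7). Greedy ties: lowest column
  index. Both stated so independent implementations can match bit-for-bit.
- Degenerate inputs: λ = 0 cohorts are empty, `m = 0` policies return the
  control allocation unchanged (difference exactly 0), zero-supply sites
  screen with `NA` ratios, and empty cost matrices (no demanding patients)
  are valid 0 × k instances.
- Problem sizes in the test suite are chosen for tight feedback: the preset
  runs `n_iter = 200` per grid point (about 2 s for the full 21-point grid),
  property suites use miniature random catchments (λ ≤ 25), and distribution
  checks use one large fixed-seed cohort (N = 50 000). The method's default
  remains `n_iter = 5000`.

## Known limitations

Single-satellite, single-specialty policies only (joint multi-satellite
optimization is future work); no cost or quality-of-care modelling; no
within-year scheduling, waiting times or missed-appointment penalties; the
per-visit denominator is the reallocated slot count `m`, so per-visit figures
describe patients whose care was shifted, not all patients.
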