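#' Define an outreach policy
#'
#' A policy names the satellite receiving reallocated effort, the oncology
#' specialty, and the proportion `theta` of the hub's annual new-patient
#' visits of that specialty to move there.
#'
#' @param satellite_id Satellite site id.
#' @param specialty Specialty label (e.g. `"medical"`, `"radiation"`).
#' @param theta Proportion in `[0, 1]` of hub visits to reallocate.
#' @return An object of class `outreach_policy`.
#' @export
outreach_policy <- function(satellite_id, specialty, theta) {
  if (theta < 0 || theta > 1) abort("theta must be in [0, 1]")
  structure(list(satellite_id = satellite_id, specialty = specialty,
                 theta = theta),
            class = "outreach_policy")
}

#' @export
print.outreach_policy <- function(x, ...) {
  cat(sprintf("<outreach_policy> shift %.0f%% of hub %s visits to %s\n",
              100 * x$theta, x$specialty, x$satellite_id))
  invisible(x)
}

#' Sample annual visit capacity across oncologist/site pairs
#'
#' Draws one year of new-patient visit slots for every oncologist/site pair of
#' the given specialty: `slots ~ Poisson(mean_annual_volume)` independently
#' per pair (or `round(mean)` with `fixed = TRUE`). Columns are returned in
#' the deterministic order sites sorted by `site_id` then oncologists by
#' `oncologist_id`, which downstream code relies on for reproducible
#' tie-breaking.
#'
#' @param volumes Volumes tibble (`oncologist_id`, `site_id`, `specialty`,
#'   `mean_annual_volume`).
#' @param specialty Specialty to sample.
#' @param fixed If `TRUE`, use deterministic `round(mean)` slots.
#' @return A capacity allocation: tibble with columns `oncologist_id`,
#'   `site_id`, `specialty`, `slots`, `provenance` (all `"original"`).
#' @export
sample_capacity <- function(volumes, specialty, fixed = FALSE) {
  pairs <- volumes[volumes$specialty == specialty, ] |>
    dplyr::arrange(.data$site_id, .data$oncologist_id)
  if (nrow(pairs) == 0) abort(sprintf("no oncologist/site pairs for specialty '%s'", specialty))
  slots <- if (fixed) {
    as.integer(round(pairs$mean_annual_volume))
  } else {
    rpois(nrow(pairs), pairs$mean_annual_volume)
  }
  tibble(
    oncologist_id = pairs$oncologist_id,
    site_id = pairs$site_id,
    specialty = pairs$specialty,
    slots = as.integer(slots),
    provenance = "original"
  )
}

#' Number of hub visits reallocated at a given theta
#'
#' The reallocation rule rounds up: `ceiling(theta * hub_total)`. Rounding up
#' is the unique rule consistent with moving 2 of 8 visits at `theta = 0.25`
#' and 15 of 287 at `theta = 0.05` (round-half-up would give 14).
#'
#' @param theta Proportion in `[0, 1]`.
#' @param hub_total Non-negative integer total of hub visit slots for the
#'   specialty.
#' @return Integer count of slots to move; 0 when `theta = 0`.
#' @export
#' @examples
#' reallocated_count(0.25, 8)   # 2
#' reallocated_count(0.05, 287) # 15
reallocated_count <- function(theta, hub_total) {
  if (any(theta < 0 | theta > 1)) abort("theta must be in [0, 1]")
  if (any(hub_total < 0)) abort("hub_total must be non-negative")
  as.integer(ceiling(theta * hub_total))
}

#' Apply an outreach policy to a control capacity allocation
#'
#' Moves `m = reallocated_count(theta, hub slots of the specialty)` visit
#' slots from the hub to the policy's satellite. The `m` slot-units are drawn
#' uniformly without replacement across the hub's columns of that specialty,
#' so individual oncologists may end up splitting their time across two
#' sites: each affected oncologist loses the drawn slots at the hub and gains
#' a new column `(oncologist, satellite, specialty)` appended after all
#' original columns with provenance `"reallocated"`. Total slots are
#' conserved exactly and the control allocation is untouched.
#'
#' @param control Capacity allocation from [sample_capacity()].
#' @param policy An [outreach_policy()].
#' @param hub_id Hub site id.
#' @return A new capacity allocation tibble.
#' @export
apply_policy <- function(control, policy, hub_id) {
  stopifnot(inherits(policy, "outreach_policy"))
  is_hub <- control$site_id == hub_id & control$specialty == policy$specialty
  if (!any(is_hub)) abort("control allocation has no hub columns of the policy specialty")
  hub_total <- sum(control$slots[is_hub])
  m <- reallocated_count(policy$theta, hub_total)
  if (m == 0L) return(control)

  hub_cols <- which(is_hub)
  units <- rep(hub_cols, control$slots[hub_cols])
  moved <- units[sample.int(length(units), m)]
  moved_per_col <- tabulate(match(moved, hub_cols), nbins = length(hub_cols))

  out <- control
  out$slots[hub_cols] <- out$slots[hub_cols] - as.integer(moved_per_col)
  new_cols <- tibble(
    oncologist_id = control$oncologist_id[hub_cols],
    site_id = policy$satellite_id,
    specialty = policy$specialty,
    slots = as.integer(moved_per_col),
    provenance = "reallocated"
  ) |> dplyr::filter(.data$slots > 0)
  dplyr::bind_rows(out, new_cols)
}
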