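#' Build the joint patient distribution (the "patient generator")
#'
#' Combines the incidence table (ZCTA x cancer type) and the stage table
#' (stage | cancer type) into the joint distribution over (ZCTA, cancer type,
#' stage) under the assumption that ZCTA and stage are conditionally
#' independent given cancer type:
#' \deqn{p(z, t, s) = \frac{\mathrm{incidence}(z, t)}{\sum \mathrm{incidence}}
#'   \; p(s \mid t).}
#' The total mean annual incidence \eqn{\lambda} is the incidence-table total
#' and sets the expected annual cohort size.
#'
#' @param incidence Incidence tibble (`zcta_id`, `cancer_type`,
#'   `mean_annual_cases`).
#' @param stages Stage tibble (`cancer_type`, `stage`, `prob`).
#' @return A `patient_generator`: tibble with columns `zcta_id`,
#'   `cancer_type`, `stage`, `prob` summing to 1, with attribute `lambda`.
#' @export
#' @examples
#' inc <- tibble::tibble(zcta_id = c("a", "b"), cancer_type = "lung",
#'                       mean_annual_cases = c(30, 70))
#' st <- tibble::tibble(cancer_type = "lung", stage = c("early", "late"),
#'                      prob = c(0.5, 0.5))
#' build_joint_distribution(inc, st)
build_joint_distribution <- function(incidence, stages) {
  missing_types <- setdiff(unique(incidence$cancer_type), unique(stages$cancer_type))
  if (length(missing_types) > 0) {
    abort(sprintf("cancer type(s) missing from stage table: %s",
                  paste(missing_types, collapse = ", ")))
  }
  lambda <- sum(incidence$mean_annual_cases)
  if (lambda <= 0) abort("total incidence is zero")
  joint <- incidence |>
    dplyr::inner_join(stages, by = "cancer_type", relationship = "many-to-many") |>
    dplyr::mutate(prob = .data$mean_annual_cases / lambda * .data$prob) |>
    dplyr::select("zcta_id", "cancer_type", "stage", "prob")
  structure(joint, lambda = lambda, class = c("patient_generator", class(joint)))
}

#' Sample one annual incident cohort
#'
#' Draws the cohort size `N` (Poisson with mean \eqn{\lambda} by default, or
#' exactly `round(lambda)` with `fixed_n = TRUE`) and then `N` independent
#' patients from the joint (ZCTA, type, stage) distribution. The rows come out
#' in i.i.d. sampling order, which is already a uniformly random arrival
#' order; `order_index` runs 0..N-1 and defines the first-come-first-served
#' sequence used downstream.
#'
#' Uses the current RNG state; seed with `set.seed()` (or via the `seed`
#' arguments of the higher-level drivers) for reproducibility.
#'
#' @param dist A [build_joint_distribution()] result.
#' @param fixed_n If `TRUE`, use `round(lambda)` patients every year instead
#'   of a Poisson draw.
#' @return Tibble with columns `order_index`, `zcta_id`, `cancer_type`,
#'   `stage` (possibly zero rows when \eqn{\lambda = 0} rounds to none drawn).
#' @export
sample_annual_cohort <- function(dist, fixed_n = FALSE) {
  lambda <- attr(dist, "lambda")
  n <- if (fixed_n) as.integer(round(lambda)) else rpois(1L, lambda)
  if (n == 0L) {
    return(tibble(order_index = integer(), zcta_id = character(),
                  cancer_type = character(), stage = character()))
  }
  idx <- sample.int(nrow(dist), n, replace = TRUE, prob = dist$prob)
  tibble(
    order_index = 0:(n - 1L),
    zcta_id = dist$zcta_id[idx],
    cancer_type = dist$cancer_type[idx],
    stage = dist$stage[idx]
  )
}

#' Draw Bernoulli specialty demand for a cohort
#'
#' Flags each patient as demanding the given oncology specialty by an
#' independent Bernoulli draw with probability `prob(type, stage, specialty)`
#' from the demand table. Adds a logical column `demand_<specialty>`; all
#' other columns are untouched.
#'
#' @param cohort A cohort tibble from [sample_annual_cohort()].
#' @param demand Demand tibble (`cancer_type`, `stage`, `specialty`, `prob`).
#' @param specialty Specialty label present in `demand`.
#' @return The cohort with one added logical column.
#' @export
draw_specialty_demand <- function(cohort, demand, specialty) {
  dem <- demand[demand$specialty == specialty, ]
  if (nrow(dem) == 0) abort(sprintf("no demand rows for specialty '%s'", specialty))
  key <- paste(cohort$cancer_type, cohort$stage, sep = "\r")
  p <- dem$prob[match(key, paste(dem$cancer_type, dem$stage, sep = "\r"))]
  if (anyNA(p)) {
    bad <- which(is.na(p))[1]
    abort(sprintf("demand table does not cover (%s, %s) for specialty '%s'",
                  cohort$cancer_type[bad], cohort$stage[bad], specialty))
  }
  flag <- runif(nrow(cohort)) < p
  cohort[[paste0("demand_", specialty)]] <- flag
  cohort
}
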