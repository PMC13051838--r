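#' Build a patient-by-pair round-trip cost matrix
#'
#' Rows are the demanding patients in arrival order; columns are the capacity
#' allocation's oncologist/site pairs; element `(i, j)` is the round-trip
#' travel time in minutes from patient `i`'s ZCTA to column `j`'s site, i.e.
#' twice the one-way entry of the travel table.
#'
#' @param cohort Tibble of demanding patients in arrival order (needs
#'   `zcta_id`).
#' @param allocation Capacity allocation tibble (needs `site_id`).
#' @param travel Travel tibble (`zcta_id`, `site_id`, `one_way_minutes`).
#' @return Numeric matrix, `nrow(cohort)` x `nrow(allocation)` (a 0 x k
#'   matrix for an empty cohort).
#' @export
build_cost_matrix <- function(cohort, allocation, travel) {
  key <- paste(travel$zcta_id, travel$site_id, sep = "\r")
  want <- outer(cohort$zcta_id, allocation$site_id, paste, sep = "\r")
  idx <- match(want, key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    i <- (bad - 1L) %% max(nrow(cohort), 1L) + 1L
    j <- (bad - 1L) %/% max(nrow(cohort), 1L) + 1L
    abort(sprintf("travel table missing entry for (zcta %s, site %s)",
                  cohort$zcta_id[i], allocation$site_id[j]))
  }
  m <- matrix(2 * travel$one_way_minutes[idx],
              nrow = nrow(cohort), ncol = nrow(allocation))
  colnames(m) <- paste(allocation$oncologist_id, allocation$site_id, sep = "@")
  m
}

#' Greedy first-come-first-served assignment
#'
#' Iterates patients in row order; each is assigned to the minimum-cost column
#' with remaining capacity (ties broken toward the lowest column index) and
#' that column's remaining slots decrease by one. Patients who arrive after
#' all capacity is exhausted are left unassigned — a valid outcome, not an
#' error. A globally optimal assignment is deliberately not used: it would
#' ignore the chronological order in which incident patients book care.
#'
#' @param cost Cost matrix from [build_cost_matrix()].
#' @param slots Integer vector of per-column capacities, conformal with
#'   `cost`.
#' @return An `assignment` object: list with `assigned` (per-patient 1-based
#'   column index, `NA` for unassigned), `n_assigned`, `n_unassigned`, and
#'   `slots` as given.
#' @export
greedy_assign <- function(cost, slots) {
  if (length(slots) != ncol(cost)) abort("slots not conformal with cost columns")
  assigned <- greedy_assign_cpp(cost, as.integer(slots))
  structure(
    list(assigned = assigned,
         n_assigned = sum(!is.na(assigned)),
         n_unassigned = sum(is.na(assigned)),
         slots = as.integer(slots)),
    class = "assignment"
  )
}

#' @export
print.assignment <- function(x, ...) {
  cat(sprintf("<assignment> %d assigned, %d unassigned over %d column(s)\n",
              x$n_assigned, x$n_unassigned, length(x$slots)))
  invisible(x)
}

#' Boolean assignment matrix
#'
#' Expands an [greedy_assign()] result into the Boolean patients-by-pairs
#' matrix conformal with its cost matrix. Each row sums to 0 or 1 and column
#' sums never exceed the column's slots.
#'
#' @param assignment An `assignment` object.
#' @return Logical matrix.
#' @export
assignment_matrix <- function(assignment) {
  n <- length(assignment$assigned)
  m <- matrix(FALSE, n, length(assignment$slots))
  ok <- !is.na(assignment$assigned)
  m[cbind(which(ok), assignment$assigned[ok])] <- TRUE
  m
}

#' Total incurred travel time of an assignment
#'
#' The inner (sum) product of the cost and Boolean assignment matrices: the
#' sum over assigned patients of their chosen round-trip travel time, in
#' minutes. Unassigned patients contribute zero.
#'
#' @param cost Cost matrix.
#' @param assignment An `assignment` object (or a logical matrix conformal
#'   with `cost`).
#' @return Total minutes (scalar).
#' @export
total_travel_time <- function(cost, assignment) {
  if (inherits(assignment, "assignment")) {
    if (length(assignment$assigned) != nrow(cost) ||
        length(assignment$slots) != ncol(cost)) {
      abort("assignment not conformal with cost matrix")
    }
    ok <- !is.na(assignment$assigned)
    return(sum(cost[cbind(which(ok), assignment$assigned[ok])]))
  }
  if (!identical(dim(assignment), dim(cost))) {
    abort("assignment not conformal with cost matrix")
  }
  sum(cost[assignment])
}
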