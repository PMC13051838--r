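#' Assemble a validated bundle of simulation inputs
#'
#' An `outreach_inputs` object bundles the six tables the simulator consumes:
#' clinic sites, one-way travel times from each residence area (ZCTA) to each
#' site, mean annual cancer incidence by ZCTA and cancer type, the stage
#' distribution conditional on cancer type, the probability that a patient of a
#' given type and stage demands each oncology specialty, and historical mean
#' annual new-patient volumes per oncologist/site pair.
#'
#' @param sites Tibble with columns `site_id`, `role` (`"hub"` or
#'   `"satellite"`; exactly one hub), `name`.
#' @param travel Tibble with columns `zcta_id`, `site_id`, `one_way_minutes`
#'   (non-negative), complete over every ZCTA in `incidence` crossed with every
#'   site.
#' @param incidence Tibble with columns `zcta_id`, `cancer_type`,
#'   `mean_annual_cases` (non-negative; positive total).
#' @param stages Tibble with columns `cancer_type`, `stage`, `prob`; the
#'   probabilities must sum to 1 within each cancer type.
#' @param demand Tibble with columns `cancer_type`, `stage`, `specialty`
#'   (`"medical"` or `"radiation"`), `prob` in `[0, 1]`, covering every
#'   (type, stage) pair in `stages` for each specialty present.
#' @param volumes Tibble with columns `oncologist_id`, `site_id`, `specialty`,
#'   `mean_annual_volume` (non-negative).
#' @param params Optional named list of generator parameters carried in the
#'   manifest (e.g. site coordinates, driving speed) used by
#'   [site_travel_minutes()].
#'
#' @return An object of class `outreach_inputs`: a named list of the six
#'   tibbles plus `params`.
#' @seealso [read_outreach_inputs()], [validate_inputs()],
#'   [generate_catchment()]
#' @export
#' @examples
#' inputs <- generate_catchment(synthetic_spec(n_zctas = 12, seed = 1))
#' inputs
outreach_inputs <- function(sites, travel, incidence, stages, demand, volumes,
                            params = list()) {
  x <- structure(
    list(
      sites = as_tibble(sites),
      travel = as_tibble(travel),
      incidence = as_tibble(incidence),
      stages = as_tibble(stages),
      demand = as_tibble(demand),
      volumes = as_tibble(volumes),
      params = params
    ),
    class = "outreach_inputs"
  )
  check_schema(x)
  x
}

table_schemas <- list(
  sites = c("site_id", "role", "name"),
  travel = c("zcta_id", "site_id", "one_way_minutes"),
  incidence = c("zcta_id", "cancer_type", "mean_annual_cases"),
  stages = c("cancer_type", "stage", "prob"),
  demand = c("cancer_type", "stage", "specialty", "prob"),
  volumes = c("oncologist_id", "site_id", "specialty", "mean_annual_volume")
)

check_schema <- function(x) {
  for (nm in names(table_schemas)) {
    missing <- setdiff(table_schemas[[nm]], names(x[[nm]]))
    if (length(missing) > 0) {
      abort(sprintf("table '%s' is missing column(s): %s",
                    nm, paste(missing, collapse = ", ")))
    }
  }
  invisible(x)
}

#' @export
print.outreach_inputs <- function(x, ...) {
  hub <- x$sites$site_id[x$sites$role == "hub"]
  cat("<outreach_inputs>\n")
  cat(sprintf("  sites:     %d (%d hub: %s)\n", nrow(x$sites), length(hub),
              paste(hub, collapse = ", ")))
  cat(sprintf("  ZCTAs:     %d\n", dplyr::n_distinct(x$incidence$zcta_id)))
  cat(sprintf("  incidence: %.1f mean annual cases over %d cancer types\n",
              sum(x$incidence$mean_annual_cases),
              dplyr::n_distinct(x$incidence$cancer_type)))
  cat(sprintf("  volumes:   %d oncologist/site pairs (%s)\n", nrow(x$volumes),
              paste(sort(unique(x$volumes$specialty)), collapse = ", ")))
  invisible(x)
}

#' Read a simulation-input bundle from disk
#'
#' Reads the CSV/YAML bundle written by [write_outreach_inputs()] (or by the
#' `synth` CLI subcommand): a `manifest.yaml` naming the six CSV files plus any
#' generator parameters, and the CSV tables themselves. The bundle is validated
#' with [validate_inputs()] and reading fails with the full list of issues if
#' any invariant is violated.
#'
#' @param path Directory containing `manifest.yaml`, or a path to the manifest
#'   itself.
#' @return A validated [outreach_inputs()] object.
#' @export
read_outreach_inputs <- function(path) {
  manifest_path <- if (dir.exists(path)) file.path(path, "manifest.yaml") else path
  if (!file.exists(manifest_path)) {
    abort(sprintf("manifest not found: %s", manifest_path))
  }
  manifest <- yaml::read_yaml(manifest_path)
  dir <- dirname(manifest_path)

  read_one <- function(nm) {
    file <- manifest$files[[nm]]
    if (is.null(file)) abort(sprintf("manifest does not name a '%s' file", nm))
    fp <- file.path(dir, file)
    if (!file.exists(fp)) abort(sprintf("input file not found: %s", fp))
    tab <- readr::read_csv(fp, show_col_types = FALSE, progress = FALSE)
    missing <- setdiff(table_schemas[[nm]], names(tab))
    if (length(missing) > 0) {
      abort(sprintf("%s: missing column(s) %s", fp, paste(missing, collapse = ", ")))
    }
    tab
  }

  x <- outreach_inputs(
    sites = read_one("sites"),
    travel = read_one("travel"),
    incidence = read_one("incidence"),
    stages = read_one("stages"),
    demand = read_one("demand"),
    volumes = read_one("volumes"),
    params = manifest$params %||% list()
  )
  issues <- validate_inputs(x)
  if (length(issues) > 0) {
    abort(paste0("invalid input bundle:\n", paste("-", issues, collapse = "\n")))
  }
  x
}

#' Write a simulation-input bundle to disk
#'
#' Writes the six tables as plain CSV files plus a `manifest.yaml` naming them
#' and carrying any generator parameters. The round trip through
#' [read_outreach_inputs()] is lossless to the written numeric precision.
#'
#' @param inputs An [outreach_inputs()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_outreach_inputs <- function(inputs, dir) {
  stopifnot(inherits(inputs, "outreach_inputs"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- setNames(paste0(names(table_schemas), ".csv"), names(table_schemas))
  for (nm in names(files)) {
    readr::write_csv(inputs[[nm]][, table_schemas[[nm]]], file.path(dir, files[[nm]]))
  }
  manifest <- list(files = as.list(files))
  if (length(inputs$params) > 0) manifest$params <- inputs$params
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Validate a simulation-input bundle
#'
#' Checks every structural invariant the simulator relies on and reports each
#' violation as a human-readable message; it never raises. An empty character
#' vector means the bundle is valid.
#'
#' Checks: exactly one hub site and unique site ids; travel times non-negative
#' and complete over every (ZCTA, site) combination referenced by the incidence
#' table; non-negative incidence with a positive total; stage probabilities
#' summing to 1 within each cancer type; demand probabilities in `[0, 1]` and
#' complete over the (type, stage) domain for each specialty; unique
#' (oncologist, site, specialty) volume rows with non-negative volumes; and
#' referential integrity of site ids across tables.
#'
#' @param inputs An [outreach_inputs()] object.
#' @return Character vector of issues (empty when valid).
#' @export
validate_inputs <- function(inputs) {
  issues <- character()
  say <- function(...) issues <<- c(issues, sprintf(...))

  sites <- inputs$sites
  if (anyDuplicated(sites$site_id)) say("duplicate site_id in sites table")
  n_hub <- sum(sites$role == "hub")
  if (n_hub != 1) say("exactly one hub required (found %d)", n_hub)
  bad_role <- setdiff(unique(sites$role), c("hub", "satellite"))
  if (length(bad_role) > 0) {
    say("unknown site role(s): %s", paste(bad_role, collapse = ", "))
  }

  inc <- inputs$incidence
  if (any(inc$mean_annual_cases < 0)) say("negative mean_annual_cases in incidence table")
  if (nrow(inc) == 0 || sum(inc$mean_annual_cases) <= 0) say("total incidence is zero")

  trav <- inputs$travel
  if (any(trav$one_way_minutes < 0)) say("negative one_way_minutes in travel table")
  need <- tidyr::expand_grid(zcta_id = unique(inc$zcta_id), site_id = sites$site_id)
  miss <- dplyr::anti_join(need, trav, by = c("zcta_id", "site_id"))
  if (nrow(miss) > 0) {
    for (i in seq_len(min(nrow(miss), 5))) {
      say("travel table missing entry for (zcta %s, site %s)",
          miss$zcta_id[i], miss$site_id[i])
    }
    if (nrow(miss) > 5) say("... and %d more missing travel entries", nrow(miss) - 5)
  }

  st <- inputs$stages
  sums <- st |>
    dplyr::summarise(s = sum(.data$prob), .by = "cancer_type") |>
    dplyr::filter(abs(.data$s - 1) > 1e-9)
  for (i in seq_len(nrow(sums))) {
    say("stage probabilities for cancer type '%s' sum to %g, not 1",
        sums$cancer_type[i], sums$s[i])
  }
  missing_types <- setdiff(unique(inc$cancer_type), unique(st$cancer_type))
  if (length(missing_types) > 0) {
    say("cancer type(s) in incidence but not in stages: %s",
        paste(missing_types, collapse = ", "))
  }

  dem <- inputs$demand
  if (any(dem$prob < 0 | dem$prob > 1)) say("demand probabilities outside [0,1]")
  for (sp in unique(dem$specialty)) {
    cov <- dplyr::anti_join(
      st[, c("cancer_type", "stage")],
      dem[dem$specialty == sp, c("cancer_type", "stage")],
      by = c("cancer_type", "stage")
    )
    if (nrow(cov) > 0) {
      say("demand table for specialty '%s' missing %d (type, stage) pair(s), e.g. (%s, %s)",
          sp, nrow(cov), cov$cancer_type[1], cov$stage[1])
    }
  }

  vol <- inputs$volumes
  if (any(vol$mean_annual_volume < 0)) say("negative mean_annual_volume in volumes table")
  if (anyDuplicated(vol[, c("oncologist_id", "site_id", "specialty")])) {
    say("duplicate (oncologist_id, site_id, specialty) in volumes table")
  }
  bad_sites <- setdiff(unique(vol$site_id), sites$site_id)
  if (length(bad_sites) > 0) {
    say("volumes reference unknown site(s): %s", paste(bad_sites, collapse = ", "))
  }
  bad_tsites <- setdiff(unique(trav$site_id), sites$site_id)
  if (length(bad_tsites) > 0) {
    say("travel table references unknown site(s): %s", paste(bad_tsites, collapse = ", "))
  }

  issues
}

#' Hub site id of an input bundle
#' @param inputs An [outreach_inputs()] object.
#' @return The `site_id` of the unique hub site.
#' @export
hub_site <- function(inputs) {
  inputs$sites$site_id[inputs$sites$role == "hub"][1]
}

#' Site-to-site one-way travel minutes from manifest geometry
#'
#' Bundles produced by [generate_catchment()] carry site coordinates and the
#' speed/terminal parameters of the travel-time synthesis in `params`; this
#' computes the one-way driving minutes between two sites from that geometry,
#' as needed by [net_savings()] for the travelling oncologist.
#'
#' @param inputs An [outreach_inputs()] object with `params$site_coords`,
#'   `params$speed_kmh` and `params$terminal_minutes`.
#' @param from,to Site ids.
#' @return One-way minutes (scalar).
#' @export
site_travel_minutes <- function(inputs, from, to) {
  p <- inputs$params
  if (is.null(p$site_coords) || is.null(p$speed_kmh) || is.null(p$terminal_minutes)) {
    abort("inputs carry no site geometry; supply hub_satellite_one_way_minutes directly")
  }
  co <- p$site_coords
  i <- match(from, vapply(co, `[[`, "", "site_id"))
  j <- match(to, vapply(co, `[[`, "", "site_id"))
  if (is.na(i) || is.na(j)) abort("unknown site id in site_travel_minutes()")
  d <- sqrt((co[[i]]$x_km - co[[j]]$x_km)^2 + (co[[i]]$y_km - co[[j]]$y_km)^2)
  unname(p$terminal_minutes + 60 * d / p$speed_kmh)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
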