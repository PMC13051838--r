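#' Specification for a synthetic hub-and-spoke catchment
#'
#' Describes a planar catchment from which [generate_catchment()] builds a full
#' input bundle: ZCTA centroids scattered on a square plane (optionally
#' clustered around clinic sites), travel times derived from Euclidean distance
#' at a fixed driving speed plus a terminal overhead, incidence split across
#' cancer types, a stage distribution per type, specialty-demand probabilities
#' rising with stage, and supply volumes concentrated at the hub.
#'
#' @param n_zctas Number of ZCTA centroids (positive integer).
#' @param n_satellites Number of satellite sites (positive integer).
#' @param extent_km Side of the square plane, km.
#' @param total_incidence Mean annual incident cases summed over the catchment.
#' @param cancer_types Character vector of cancer-type labels.
#' @param type_shares Incidence share per cancer type (sums to 1).
#' @param stage_probs Named list: for each cancer type, a named numeric vector
#'   of stage probabilities (each summing to 1). Defaults to two bands,
#'   `early`/`late`, with type-specific splits when the default three types are
#'   used and 0.55/0.45 otherwise.
#' @param demand_probs Named list with one element per specialty; each element
#'   a named numeric vector of demand probabilities per stage band. The
#'   defaults (`medical` 0.85/0.95 and `radiation` 0.35/0.55 for early/late)
#'   are synthetic placeholders with the right qualitative shape (demand rises
#'   with stage), not estimates from any clinical dataset.
#' @param clustering Fraction in `[0, 1]` of ZCTAs drawn from Gaussian clusters
#'   centred on clinic sites (0 = fully uniform scatter).
#' @param site_weights Optional weights over sites (hub first, then
#'   satellites) for cluster membership; default uniform.
#' @param cluster_sd_km Spread of each site-centred cluster, km.
#' @param speed_kmh Driving speed for travel-time synthesis.
#' @param terminal_minutes Fixed overhead added to every one-way trip (parking,
#'   check-in), minutes.
#' @param hub_share Named numeric in `[0, 1]` per specialty: share of total
#'   annual new-patient supply held at the hub.
#' @param supply_demand_ratio Total supply relative to expected specialty
#'   demand (slightly above 1 means mild excess capacity).
#' @param max_volume_per_oncologist Cap used to split a site's volume into
#'   oncologist/site pairs.
#' @param seed Integer seed making the generated bundle fully reproducible.
#'
#' @return An object of class `synthetic_spec` (a named list).
#' @seealso [generate_catchment()], [dartmouth_like_preset()]
#' @export
synthetic_spec <- function(n_zctas = 40,
                           n_satellites = 3,
                           extent_km = 200,
                           total_incidence = 400,
                           cancer_types = c("breast", "colorectal", "lung"),
                           type_shares = NULL,
                           stage_probs = NULL,
                           demand_probs = list(
                             medical = c(early = 0.85, late = 0.95),
                             radiation = c(early = 0.35, late = 0.55)
                           ),
                           clustering = 0.7,
                           site_weights = NULL,
                           cluster_sd_km = 12,
                           speed_kmh = 70,
                           terminal_minutes = 12,
                           hub_share = c(medical = 0.55, radiation = 0.5),
                           supply_demand_ratio = 1.05,
                           max_volume_per_oncologist = 80,
                           seed = 1L) {
  if (is.null(type_shares)) {
    type_shares <- rep(1 / length(cancer_types), length(cancer_types))
  }
  if (is.null(stage_probs)) {
    stage_probs <- if (identical(sort(cancer_types), sort(c("breast", "colorectal", "lung")))) {
      list(
        breast = c(early = 0.65, late = 0.35),
        colorectal = c(early = 0.55, late = 0.45),
        lung = c(early = 0.35, late = 0.65)
      )[cancer_types]
    } else {
      setNames(rep(list(c(early = 0.55, late = 0.45)), length(cancer_types)),
               cancer_types)
    }
  }
  spec <- structure(
    list(
      n_zctas = as.integer(n_zctas), n_satellites = as.integer(n_satellites),
      extent_km = extent_km, total_incidence = total_incidence,
      cancer_types = cancer_types, type_shares = type_shares,
      stage_probs = stage_probs, demand_probs = demand_probs,
      clustering = clustering, site_weights = site_weights,
      cluster_sd_km = cluster_sd_km, speed_kmh = speed_kmh,
      terminal_minutes = terminal_minutes, hub_share = hub_share,
      supply_demand_ratio = supply_demand_ratio,
      max_volume_per_oncologist = max_volume_per_oncologist,
      seed = as.integer(seed),
      site_coords = NULL, volumes = NULL
    ),
    class = "synthetic_spec"
  )
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  with(spec, {
    if (n_zctas < 1 || n_satellites < 1) abort("counts must be positive")
    if (clustering < 0 || clustering > 1) abort("clustering must be in [0,1]")
    if (any(hub_share < 0 | hub_share > 1)) abort("hub_share must be in [0,1]")
    if (abs(sum(type_shares) - 1) > 1e-9) abort("type_shares must sum to 1")
    if (total_incidence <= 0) abort("total_incidence must be positive")
    for (tp in names(stage_probs)) {
      if (abs(sum(stage_probs[[tp]]) - 1) > 1e-9) {
        abort(sprintf("stage probabilities for '%s' must sum to 1", tp))
      }
    }
  })
  invisible(spec)
}

#' Generate a synthetic catchment input bundle
#'
#' Builds a complete, validated [outreach_inputs()] bundle from a
#' [synthetic_spec()]. Geography is a flat plane: the hub sits at the centre,
#' satellites on a ring around it, and ZCTA centroids are drawn either
#' uniformly or (with probability `clustering`) from Gaussian clusters centred
#' on sites. One-way travel minutes are `terminal_minutes + 60 * distance_km /
#' speed_kmh`, so travel time is monotone in distance and bounded below by the
#' terminal overhead. Per-ZCTA incidence weights are Gamma-distributed to give
#' realistic heterogeneity. Supply is allocated so the hub holds `hub_share` of
#' each specialty's total, the remainder split evenly across satellites, and
#' each site's volume is chopped into oncologist/site pairs of at most
#' `max_volume_per_oncologist` annual patients.
#'
#' The generation is deterministic given `spec` (including its seed): calling
#' twice yields bit-identical tables.
#'
#' @param spec A [synthetic_spec()].
#' @return A validated [outreach_inputs()] bundle whose `params` record the
#'   site coordinates and travel-synthesis parameters (see
#'   [site_travel_minutes()]).
#' @export
#' @examples
#' inputs <- generate_catchment(synthetic_spec(n_zctas = 12, seed = 42))
#' validate_inputs(inputs)  # character(0)
generate_catchment <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_spec(spec)
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
    code
  }
  withr_seed(generate_catchment_impl(spec))
}

generate_catchment_impl <- function(spec) {
  n_sites <- spec$n_satellites + 1L
  centre <- spec$extent_km / 2

  # hub at the centre; satellites on a ring at ~70% of the half-extent
  if (!is.null(spec$site_coords)) {
    coords <- spec$site_coords
  } else {
    ang <- 2 * pi * (seq_len(spec$n_satellites) - 1) / spec$n_satellites + pi / 7
    r <- 0.7 * centre
    coords <- rbind(
      c(centre, centre),
      cbind(centre + r * cos(ang), centre + r * sin(ang))
    )
  }
  site_id <- c("hub", sprintf("sat%02d", seq_len(spec$n_satellites)))
  if (!is.null(rownames(coords))) site_id <- rownames(coords)
  sites <- tibble(
    site_id = site_id,
    role = c("hub", rep("satellite", spec$n_satellites)),
    name = c("Hub medical center", sprintf("Satellite clinic %d", seq_len(spec$n_satellites)))
  )

  w <- spec$site_weights %||% rep(1, n_sites)
  w <- w / sum(w)
  clustered <- runif(spec$n_zctas) < spec$clustering
  owner <- sample.int(n_sites, spec$n_zctas, replace = TRUE, prob = w)
  zx <- ifelse(clustered,
               rnorm(spec$n_zctas, coords[owner, 1], spec$cluster_sd_km),
               runif(spec$n_zctas, 0, spec$extent_km))
  zy <- ifelse(clustered,
               rnorm(spec$n_zctas, coords[owner, 2], spec$cluster_sd_km),
               runif(spec$n_zctas, 0, spec$extent_km))
  zx <- pmin(pmax(zx, 0), spec$extent_km)
  zy <- pmin(pmax(zy, 0), spec$extent_km)
  zcta_id <- sprintf("z%03d", seq_len(spec$n_zctas))

  dist_km <- outer(seq_len(spec$n_zctas), seq_len(n_sites), function(i, j) {
    sqrt((zx[i] - coords[j, 1])^2 + (zy[i] - coords[j, 2])^2)
  })
  travel <- tidyr::expand_grid(zcta_id = zcta_id, site_id = sites$site_id) |>
    dplyr::mutate(one_way_minutes = spec$terminal_minutes +
                    60 * as.vector(t(dist_km)) / spec$speed_kmh)

  # Gamma weights give mild heterogeneity across ZCTAs within a fixed total
  zw <- rgamma(spec$n_zctas, shape = 5, rate = 1)
  zw <- zw / sum(zw)
  incidence <- tidyr::expand_grid(zcta_id = zcta_id, cancer_type = spec$cancer_types) |>
    dplyr::mutate(mean_annual_cases = spec$total_incidence *
                    rep(zw, each = length(spec$cancer_types)) *
                    rep(spec$type_shares, times = spec$n_zctas))

  stages <- purrr::imap(spec$stage_probs, function(p, tp) {
    tibble(cancer_type = tp, stage = names(p), prob = unname(p))
  }) |> purrr::list_rbind()

  demand <- purrr::imap(spec$demand_probs, function(p, sp) {
    tidyr::expand_grid(cancer_type = spec$cancer_types, stage = names(p)) |>
      dplyr::mutate(specialty = sp, prob = unname(p[stage]))
  }) |>
    purrr::list_rbind() |>
    dplyr::select("cancer_type", "stage", "specialty", "prob")

  volumes <- if (!is.null(spec$volumes)) {
    as_tibble(spec$volumes)
  } else {
    build_volumes(spec, sites, stages, demand)
  }

  outreach_inputs(
    sites = sites, travel = travel, incidence = incidence,
    stages = stages, demand = demand, volumes = volumes,
    params = list(
      speed_kmh = spec$speed_kmh,
      terminal_minutes = spec$terminal_minutes,
      seed = spec$seed,
      site_coords = purrr::map2(sites$site_id, seq_len(n_sites), function(id, j) {
        list(site_id = id, x_km = coords[j, 1], y_km = coords[j, 2])
      })
    )
  )
}

build_volumes <- function(spec, sites, stages, demand) {
  # expected demanding patients per specialty under the spec's distributions
  stage_mix <- stages |>
    dplyr::left_join(tibble(cancer_type = spec$cancer_types,
                            share = spec$type_shares),
                     by = "cancer_type") |>
    dplyr::mutate(w = .data$prob * .data$share)
  out <- list()
  onc_counter <- 0L
  for (sp in names(spec$demand_probs)) {
    pd <- demand[demand$specialty == sp, ]
    mean_p <- stage_mix |>
      dplyr::left_join(pd, by = c("cancer_type", "stage"),
                       suffix = c("", ".d")) |>
      dplyr::summarise(p = sum(.data$w * .data$prob.d)) |>
      dplyr::pull("p")
    total <- round(spec$supply_demand_ratio * spec$total_incidence * mean_p)
    hub_vol <- round(spec$hub_share[[sp]] * total)
    sat_vol <- rep((total - hub_vol) %/% spec$n_satellites, spec$n_satellites)
    extra <- (total - hub_vol) - sum(sat_vol)
    if (extra > 0) sat_vol[seq_len(extra)] <- sat_vol[seq_len(extra)] + 1
    site_vol <- c(hub_vol, sat_vol)
    for (j in seq_along(site_vol)) {
      v <- site_vol[j]
      if (v <= 0) next
      k <- ceiling(v / spec$max_volume_per_oncologist)
      per <- rep(v %/% k, k)
      if (v %% k > 0) per[seq_len(v %% k)] <- per[seq_len(v %% k)] + 1
      for (vv in per) {
        onc_counter <- onc_counter + 1L
        out[[length(out) + 1L]] <- tibble(
          oncologist_id = sprintf("onc%03d", onc_counter),
          site_id = sites$site_id[j], specialty = sp, mean_annual_volume = vv
        )
      }
    }
  }
  purrr::list_rbind(out)
}

#' Preset emulating a one-hub, three-satellite academic cancer network
#'
#' Returns a [synthetic_spec()] shaped like a rural academic hub-and-spoke
#' system: one hub and three satellites (`STJ`, `MAN`, `KEE` analogues), fixed
#' per-site supply volumes of (297, 95, 105, 56) annual new medical-oncology
#' patients and (97, 111, 0, 59) radiation-oncology patients for
#' (hub, KEE, MAN, STJ) — note one satellite has no radiation presence — and
#' an incidence surface clustered so that the `STJ` analogue's local demand
#' greatly exceeds its supply while the hub has comfortable excess capacity.
#' The demand probabilities are the package's synthetic placeholders, not
#' values estimated from any health system.
#'
#' @param seed Integer seed for [generate_catchment()].
#' @return A `synthetic_spec`.
#' @export
#' @examples
#' inputs <- generate_catchment(dartmouth_like_preset(seed = 7))
#' dplyr::count(inputs$volumes, site_id, specialty, wt = mean_annual_volume)
dartmouth_like_preset <- function(seed = 1L) {
  sites <- c("LEB", "KEE", "MAN", "STJ")
  coords <- rbind(
    LEB = c(100, 100),  # hub, centre
    KEE = c(55, 45),
    MAN = c(145, 35),
    STJ = c(100, 178)
  )
  med <- c(LEB = 297, KEE = 95, MAN = 105, STJ = 56)
  rad <- c(LEB = 97, KEE = 111, MAN = 0, STJ = 59)
  vol_rows <- list()
  idx <- 0L
  add <- function(site, sp, vols) {
    for (v in vols) {
      idx <<- idx + 1L
      vol_rows[[length(vol_rows) + 1L]] <<- tibble(
        oncologist_id = sprintf("onc%03d", idx), site_id = site,
        specialty = sp, mean_annual_volume = v
      )
    }
  }
  add("LEB", "medical", c(75, 75, 75, 72))
  add("KEE", "medical", 95)
  add("MAN", "medical", 105)
  add("STJ", "medical", 56)
  add("LEB", "radiation", c(49, 48))
  add("KEE", "radiation", 111)
  add("STJ", "radiation", 59)

  # cluster weights proportional to target proximal demand per site:
  # hub-heavy centre, a large under-served cluster near STJ
  demand_weights <- c(LEB = 183, KEE = 96, MAN = 72, STJ = 175)

  spec <- synthetic_spec(
    n_zctas = 64, n_satellites = 3, extent_km = 200,
    total_incidence = 586,
    clustering = 0.85,
    site_weights = demand_weights / sum(demand_weights),
    cluster_sd_km = 11,
    speed_kmh = 70, terminal_minutes = 12,
    seed = seed
  )
  spec$site_coords <- coords
  spec$volumes <- purrr::list_rbind(vol_rows)
  spec
}
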