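#' Scenario parameters for the sanitation-assault model
#'
#' Constructs the single source of truth for one model run: reported assault
#' incidence and its adjustment fractions, township demography, toilet supply
#' and cost, and the walking/trip behaviour that converts distance into
#' exposure time. Defaults are the Khayelitsha base case.
#'
#' Exactly one of `base_roundtrip_m` and `effective_area_km2` is the primary
#' geometric anchor. By default the 210 m baseline round trip is primary and
#' the effective settled area is derived from the distance law
#' `d(t) = sqrt(cluster_size * area_m2 / t)` evaluated at `baseline_toilets`.
#' If `effective_area_km2` is supplied, it becomes primary and
#' `base_roundtrip_m` is derived instead; supplying both is an error unless
#' they already satisfy the distance law to 1e-9 relative.
#'
#' @param reported_assaults_per_year Sexual assaults reported to police per
#'   year (count).
#' @param pct_outdoors Fraction of assaults occurring outdoors, in (0, 1].
#' @param pct_reported Fraction of assaults that are reported, in (0, 1].
#' @param pct_enroute Fraction of outdoor assaults occurring en route to or
#'   from a toilet, in (0, 1].
#' @param female_prop Proportion of the population that is female.
#' @param household_size Persons per family.
#' @param families_per_toilet Families sharing one toilet.
#' @param trips_per_day Round trips to a toilet per woman per day.
#' @param walk_speed_kph Average walking speed, km/h.
#' @param toilet_cost_rand Annual installation-plus-maintenance cost of one
#'   chemical toilet, South African rand.
#' @param fx_rand_per_usd Exchange rate, rand per US dollar.
#' @param assault_cost_usd Social cost of one sexual assault, US dollars
#'   (purchasing-power-parity adjusted).
#' @param cluster_size Toilets per facility location.
#' @param baseline_toilets Toilets currently installed (count).
#' @param days_per_year Days per year (fixed 365; leap years ignored).
#' @param base_roundtrip_m Mean round-trip walking distance at
#'   `baseline_toilets`, meters.
#' @param effective_area_km2 Effective settled area over which facility
#'   clusters are spread, km^2; optional (see Details).
#'
#' @return An object of class `"scenario_params"`: a named list of the
#'   validated parameter values with attribute `"primary_anchor"` recording
#'   which geometric anchor was supplied.
#' @seealso [sanitation_model()] which calibrates the model from these values.
#' @examples
#' p <- scenario_params()
#' p$baseline_toilets
#' # area implied by the 210 m anchor: 35.28 km^2
#' p$effective_area_km2
#' @export
scenario_params <- function(reported_assaults_per_year = 635,
                            pct_outdoors = 0.30,
                            pct_reported = 0.15,
                            pct_enroute = 0.50,
                            female_prop = 0.52,
                            household_size = 4,
                            families_per_toilet = 17.5,
                            trips_per_day = 6,
                            walk_speed_kph = 5,
                            toilet_cost_rand = 10315,
                            fx_rand_per_usd = 9.9,
                            assault_cost_usd = 53000,
                            cluster_size = 7,
                            baseline_toilets = 5600,
                            days_per_year = 365,
                            base_roundtrip_m = 210,
                            effective_area_km2 = NULL) {
  p <- list(
    reported_assaults_per_year = reported_assaults_per_year,
    pct_outdoors = pct_outdoors,
    pct_reported = pct_reported,
    pct_enroute = pct_enroute,
    female_prop = female_prop,
    household_size = household_size,
    families_per_toilet = families_per_toilet,
    trips_per_day = trips_per_day,
    walk_speed_kph = walk_speed_kph,
    toilet_cost_rand = toilet_cost_rand,
    fx_rand_per_usd = fx_rand_per_usd,
    assault_cost_usd = assault_cost_usd,
    cluster_size = cluster_size,
    baseline_toilets = baseline_toilets,
    days_per_year = days_per_year,
    base_roundtrip_m = base_roundtrip_m,
    effective_area_km2 = effective_area_km2
  )

  area_supplied <- !is.null(effective_area_km2)
  # 210-m anchor was explicitly overridden vs left at default
  dist_supplied <- !missing(base_roundtrip_m)

  for (nm in setdiff(names(p), "effective_area_km2")) {
    x <- p[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  pos <- c("reported_assaults_per_year", "pct_outdoors", "pct_reported",
           "pct_enroute", "household_size", "families_per_toilet",
           "walk_speed_kph", "toilet_cost_rand", "fx_rand_per_usd",
           "days_per_year", "base_roundtrip_m")
  for (nm in pos) if (p[[nm]] <= 0)
    stop("'", nm, "' must be strictly positive", call. = FALSE)
  for (nm in c("pct_outdoors", "pct_reported", "pct_enroute"))
    if (p[[nm]] > 1)
      stop("'", nm, "' is a fraction and must lie in (0, 1]", call. = FALSE)
  if (p$female_prop < 0 || p$female_prop > 1)
    stop("'female_prop' must lie in [0, 1]", call. = FALSE)
  if (p$trips_per_day < 0)
    stop("'trips_per_day' must be non-negative", call. = FALSE)
  if (p$assault_cost_usd < 0)
    stop("'assault_cost_usd' must be non-negative", call. = FALSE)
  if (p$cluster_size < 1)
    stop("'cluster_size' must be at least 1", call. = FALSE)
  if (p$baseline_toilets < p$cluster_size)
    stop("'baseline_toilets' must be at least 'cluster_size'", call. = FALSE)

  # resolve the geometric anchor pair through the distance law
  implied_area <- (p$baseline_toilets / p$cluster_size) *
    (p$base_roundtrip_m / 1000)^2
  if (area_supplied) {
    if (!is.numeric(effective_area_km2) || length(effective_area_km2) != 1L ||
        !is.finite(effective_area_km2) || effective_area_km2 <= 0)
      stop("'effective_area_km2' must be a single positive number",
           call. = FALSE)
    if (dist_supplied) {
      if (abs(implied_area - effective_area_km2) >
          1e-9 * abs(effective_area_km2))
        stop("'base_roundtrip_m' and 'effective_area_km2' were both ",
             "supplied but do not satisfy the distance law ",
             "d0 = sqrt(cluster_size * area / t0)", call. = FALSE)
      primary <- "base_roundtrip_m"
    } else {
      p$base_roundtrip_m <- 1000 * sqrt(
        p$cluster_size * effective_area_km2 / p$baseline_toilets)
      primary <- "effective_area_km2"
    }
  } else {
    p$effective_area_km2 <- implied_area
    primary <- "base_roundtrip_m"
  }

  structure(p, primary_anchor = primary, class = "scenario_params")
}

#' @export
print.scenario_params <- function(x, ...) {
  cat("Scenario parameters (", attr(x, "primary_anchor"),
      " is the geometric anchor)\n", sep = "")
  df <- data.frame(value = unlist(x))
  print(df, ...)
  invisible(x)
}

#' Coerce a named list to scenario parameters
#'
#' Accepts a named list (for instance parsed from a configuration file) whose
#' names are a subset of the [scenario_params()] arguments, and constructs a
#' validated parameter set with unnamed fields at their defaults.
#'
#' @param x Named list or `scenario_params` object.
#' @return A `scenario_params` object.
#' @export
as_scenario_params <- function(x) {
  if (inherits(x, "scenario_params")) return(x)
  x <- as.list(x)
  known <- names(formals(scenario_params))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown scenario parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(scenario_params, x)
}
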