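#' Assaults attributable to travel to and from toilets
#'
#' Applies the three-factor adjustment to reported incidence: inflate for
#' under-reporting, restrict to assaults occurring outdoors, and restrict to
#' the en-route share. At the base case the outdoor and en-route fractions
#' multiply to exactly the reporting fraction, so the adjusted count equals
#' the reported count.
#'
#' @param params A [scenario_params()] object.
#' @return Attributable assaults per year (numeric scalar).
#' @examples
#' attributable_assaults(scenario_params())  # 635 at the base case
#' @export
attributable_assaults <- function(params) {
  params <- as_scenario_params(params)
  if (params$pct_reported <= 0)
    stop("'pct_reported' must be strictly positive", call. = FALSE)
  params$reported_assaults_per_year * params$pct_outdoors *
    params$pct_enroute / params$pct_reported
}

#' Female population implied by the persons-per-toilet chain
#'
#' The township population is reconstructed from the toilet stock: toilets
#' times families per toilet times household size, and the female share is
#' taken of that total.
#'
#' @inheritParams attributable_assaults
#' @return Number of women (numeric scalar).
#' @examples
#' women_population(scenario_params())  # 203,840
#' @export
women_population <- function(params) {
  params <- as_scenario_params(params)
  params$baseline_toilets * params$families_per_toilet *
    params$household_size * params$female_prop
}

#' Calibrate the sanitation-assault model
#'
#' Fits the model's two derived constants from a scenario: the exposure-hour
#' assault hazard `r` and the distance-law constant `k` such that expected
#' annual assaults at a toilet stock `t` equal `k / sqrt(t)`.
#'
#' Calibration proceeds from the baseline: attributable assaults `A0` are the
#' adjusted reported incidence; the women population comes from the
#' persons-per-toilet chain; the baseline round-trip distance anchors the
#' spatial law `d(t) = sqrt(cluster_size * area_m2 / t)`; per-woman daily
#' exposure is `trips * d(t)/1000 / speed` hours; and `r` is `A0` divided by
#' annual woman-exposure-hours at baseline. Because `d(t)` scales as
#' `1/sqrt(t)`, assaults inherit the inverse-square-root law with
#' `k = A0 * sqrt(baseline_toilets)`.
#'
#' @param params A [scenario_params()] object (or coercible named list).
#' @return An object of class `"sanitation_model"`: a list with components
#'   `params` (the validated scenario) and `calibration`, the latter holding
#'   `attributable_assaults_A0`, `women_population`, `d0_roundtrip_m`,
#'   `exposure_h_per_woman_day_0`, `annual_exposure_hours_0`,
#'   `r_per_exposure_hour`, `k_constant`, `toilet_cost_usd` and
#'   `effective_area_km2`.
#' @seealso [predict.sanitation_model()], [optimal_toilets()], [tornado()],
#'   [psa()].
#' @examples
#' m <- sanitation_model()
#' coef(m)
#' predict(m, toilets = c(5600, 11300))
#' @export
sanitation_model <- function(params = scenario_params()) {
  params <- as_scenario_params(params)
  A0 <- attributable_assaults(params)
  W <- women_population(params)
  d0 <- params$base_roundtrip_m
  e0 <- params$trips_per_day * (d0 / 1000) / params$walk_speed_kph
  E0 <- W * e0 * params$days_per_year
  if (!is.finite(E0) || E0 <= 0)
    stop("calibration requires positive baseline exposure ",
         "(non-zero trips, distance and population)", call. = FALSE)
  cal <- list(
    attributable_assaults_A0 = A0,
    women_population = W,
    d0_roundtrip_m = d0,
    exposure_h_per_woman_day_0 = e0,
    annual_exposure_hours_0 = E0,
    r_per_exposure_hour = A0 / E0,
    k_constant = A0 * sqrt(params$baseline_toilets),
    toilet_cost_usd = params$toilet_cost_rand / params$fx_rand_per_usd,
    effective_area_km2 = params$effective_area_km2
  )
  structure(list(params = params, calibration = cal),
            class = "sanitation_model")
}

stopifnot_toilets <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 1))
    stop("toilet count must be numeric and at least 1", call. = FALSE)
  invisible(t)
}

#' Mean round-trip walking distance at a given toilet stock
#'
#' Evaluates the nearest-facility distance law
#' `d(t) = sqrt(cluster_size * area_m2 / t)`, the round-trip mean implied by
#' facility clusters placed uniformly at random with density `t / cluster /
#' area` (twice the Poisson nearest-neighbor mean `1 / (2 sqrt(lambda))`).
#'
#' @param model A [sanitation_model()] object.
#' @param toilets Toilet count(s), each at least 1; vectorized.
#' @return Round-trip distance(s) in meters.
#' @export
roundtrip_distance <- function(model, toilets) {
  stopifnot(inherits(model, "sanitation_model"))
  stopifnot_toilets(toilets)
  p <- model$params
  sqrt(p$cluster_size * p$effective_area_km2 * 1e6 / toilets)
}

#' Daily walking-exposure time per woman
#'
#' Converts round-trip distance into hours exposed per woman per day:
#' `trips_per_day * d(t)/1000 / walk_speed_kph`.
#'
#' @inheritParams roundtrip_distance
#' @return Hours per woman per day (vectorized over `toilets`).
#' @export
exposure_hours <- function(model, toilets) {
  p <- model$params
  p$trips_per_day * (roundtrip_distance(model, toilets) / 1000) /
    p$walk_speed_kph
}

#' Expected annual assaults at a given toilet stock
#'
#' The calibrated inverse-square-root law `k / sqrt(t)`. At the baseline
#' stock this reproduces the attributable assault count exactly.
#'
#' @inheritParams roundtrip_distance
#' @return Expected assaults per year (vectorized over `toilets`).
#' @export
expected_assaults <- function(model, toilets) {
  stopifnot(inherits(model, "sanitation_model"))
  stopifnot_toilets(toilets)
  model$calibration$k_constant / sqrt(toilets)
}

#' @export
coef.sanitation_model <- function(object, ...) {
  cal <- object$calibration
  c(r_per_exposure_hour = cal$r_per_exposure_hour,
    k_constant = cal$k_constant,
    toilet_cost_usd = cal$toilet_cost_usd,
    assault_cost_usd = object$params$assault_cost_usd,
    attributable_assaults_A0 = cal$attributable_assaults_A0)
}

#' Predict distances, exposure, assaults and costs over toilet counts
#'
#' @param object A [sanitation_model()].
#' @param toilets Toilet counts to evaluate; defaults to the baseline stock.
#' @param type `"all"` for a data frame of every output, or one of
#'   `"assaults"`, `"distance"`, `"exposure"`, `"cost"` for a numeric vector
#'   (cost is the composite total in USD/year).
#' @param ... Unused.
#' @return A data frame (`type = "all"`) with columns `toilets`, `locations`,
#'   `roundtrip_m`, `exposure_min_per_woman_day`, `assaults`,
#'   `direct_cost_usd`, `assault_cost_usd`, `total_cost_usd`; otherwise a
#'   numeric vector.
#' @export
predict.sanitation_model <- function(object, toilets = NULL,
                                     type = c("all", "assaults", "distance",
                                              "exposure", "cost"), ...) {
  type <- match.arg(type)
  if (is.null(toilets)) toilets <- object$params$baseline_toilets
  switch(type,
    assaults = expected_assaults(object, toilets),
    distance = roundtrip_distance(object, toilets),
    exposure = exposure_hours(object, toilets),
    cost = total_cost(object, toilets),
    all = cost_point(object, toilets)
  )
}

#' @export
print.sanitation_model <- function(x, ...) {
  cal <- x$calibration
  cat("Sanitation-assault exposure model\n")
  cat(sprintf("  baseline toilets:        %g (clusters of %g)\n",
              x$params$baseline_toilets, x$params$cluster_size))
  cat(sprintf("  attributable assaults:   %.1f / year\n",
              cal$attributable_assaults_A0))
  cat(sprintf("  women population:        %g\n", cal$women_population))
  cat(sprintf("  baseline round trip:     %.1f m (%.1f min exposure/day)\n",
              cal$d0_roundtrip_m, 60 * cal$exposure_h_per_woman_day_0))
  cat(sprintf("  hazard r:                %.4g assaults / exposure-hour\n",
              cal$r_per_exposure_hour))
  cat(sprintf("  distance-law constant k: %.1f (assaults = k / sqrt(t))\n",
              cal$k_constant))
  cat(sprintf("  toilet cost:             %.2f USD / toilet / year\n",
              cal$toilet_cost_usd))
  invisible(x)
}

#' @export
summary.sanitation_model <- function(object, ...) {
  opt <- optimal_toilets(object)
  structure(list(model = object, optimum = opt,
                 base = cost_point(object, object$params$baseline_toilets)),
            class = "summary.sanitation_model")
}

#' @export
print.summary.sanitation_model <- function(x, ...) {
  print(x$model)
  cat("\nBase case vs cost-minimizing optimum:\n")
  tab <- rbind(base = x$base, optimum = x$optimum$point)
  print(tab, digits = 4)
  invisible(x)
}
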