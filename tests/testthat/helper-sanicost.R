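# shared fixtures and independent oracles

base_model <- function() sanitation_model(scenario_params())

# closed-form per-parameter scaling of the cost-minimizing toilet count under
# the one-sided propagation semantics; independent of propagate_optimum()
sep_t_star <- function(model, varied) {
  p <- model$params
  f <- 1
  g <- function(nm, base_val) {
    if (is.null(varied[[nm]])) 1 else varied[[nm]] / base_val
  }
  f <- f * g("pct_outdoors", p$pct_outdoors)
  f <- f / g("pct_reported", p$pct_reported)
  f <- f * g("pct_enroute", p$pct_enroute)
  f <- f * g("female_prop", p$female_prop)
  f <- f * g("trips_per_day", p$trips_per_day)
  f <- f / g("walk_speed_kph", p$walk_speed_kph)
  f <- f * sqrt(g("cluster_size", p$cluster_size))
  f <- f * g("assault_cost_usd", p$assault_cost_usd)
  f <- f / g("toilet_cost_usd", model$calibration$toilet_cost_usd)
  optimal_toilets(model, check_numeric = FALSE)$t_star * f^(2 / 3)
}

# deterministic quadrature/convolution estimate of P(t* > baseline) under
# independent uniform draws: convolves the discretized log scale factors
quad_exceedance <- function(model, ranges = param_ranges(), n_atoms = 500,
                            n_bins = 4001) {
  p <- model$params
  cc <- model$calibration$toilet_cost_usd
  logf <- list(
    pct_outdoors = function(th) log(th / p$pct_outdoors),
    pct_reported = function(th) log(p$pct_reported / th),
    pct_enroute = function(th) log(th / p$pct_enroute),
    female_prop = function(th) log(th / p$female_prop),
    trips_per_day = function(th) log(th / p$trips_per_day),
    walk_speed_kph = function(th) log(p$walk_speed_kph / th),
    toilet_cost_usd = function(th) log(cc / th),
    assault_cost_usd = function(th) log(th / p$assault_cost_usd),
    cluster_size = function(th) 0.5 * log(th / p$cluster_size)
  )
  dist <- list(x = 0, p = 1)
  for (i in seq_len(nrow(ranges))) {
    th <- ranges$low[i] +
      (seq_len(n_atoms) - 0.5) / n_atoms * (ranges$high[i] - ranges$low[i])
    lx <- logf[[ranges$name[i]]](th)
    if (all(lx == 0)) next
    x <- as.vector(outer(dist$x, lx, "+"))
    pr <- as.vector(outer(dist$p, rep(1 / n_atoms, n_atoms)))
    br <- seq(min(x) - 1e-9, max(x) + 1e-9, length.out = n_bins)
    idx <- findInterval(x, br)
    p2 <- tapply(pr, idx, sum)
    x2 <- tapply(x * pr, idx, sum) / p2
    dist <- list(x = as.numeric(x2), p = as.numeric(p2))
  }
  tb <- optimal_toilets(model, check_numeric = FALSE)$t_star
  thr <- 1.5 * log(model$params$baseline_toilets / tb)
  sum(dist$p[dist$x > thr])
}

# hand-built facility layout (for analytic distance checks)
manual_layout <- function(x_km, y_km, cluster_size = 1) {
  structure(list(
    locations = data.frame(id = seq_along(x_km), sal_id = 1L,
                           x_km = x_km, y_km = y_km),
    clusters_per_sal = length(x_km), cluster_size = cluster_size,
    total_toilets = cluster_size * length(x_km)
  ), class = "facility_layout")
}
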