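#' Generate a synthetic small-area layer (SAL) grid
#'
#' Emulates a census small-area layer: a rectangle of given total area tiled
#' by square cells, each carrying a population. Populations are proportional
#' to cell area, perturbed by a seeded multiplicative log-normal spread and
#' renormalized so they sum exactly to `total_population`. Zero
#' `heterogeneity` gives uniform density.
#'
#' The grid dimensions are the factor pair of `n_sal` closest to square. If
#' every factorization is more elongated than `max_aspect` (e.g. a large
#' prime), the nearest count with an acceptable factorization is used and
#' recorded in the result.
#'
#' @param n_sal Number of small areas requested.
#' @param total_area_km2 Total area of the study rectangle, km^2.
#' @param total_population Total population, persons.
#' @param heterogeneity Standard deviation of the log multiplicative
#'   population perturbation (0 = uniform density).
#' @param seed Integer seed.
#' @param max_aspect Largest acceptable grid elongation (columns/rows).
#' @return A data frame of class `"sal_layer"` with columns `id`, `xmin`,
#'   `ymin`, `xmax`, `ymax` (km), `area_km2`, `population`, and attributes
#'   `region_km` (c(width, height)) and `grid` (c(rows, cols)).
#' @examples
#' sals <- generate_sals(4, 4, 1000, heterogeneity = 0.5, seed = 1)
#' sum(sals$population)  # exactly 1000
#' @export
generate_sals <- function(n_sal, total_area_km2, total_population,
                          heterogeneity = 0, seed = 1L, max_aspect = 25) {
  if (n_sal < 1 || total_area_km2 <= 0 || total_population <= 0 ||
      heterogeneity < 0)
    stop("need n_sal >= 1, positive area and population, and ",
         "non-negative heterogeneity", call. = FALSE)
  n_sal <- as.integer(n_sal)
  dims <- best_grid(n_sal, max_aspect)
  n_use <- dims[1] * dims[2]
  nr <- dims[1]; nc <- dims[2]

  side <- sqrt(total_area_km2 / n_use)   # square tiles
  width <- nc * side
  height <- nr * side
  row <- rep(seq_len(nr), each = nc)
  col <- rep(seq_len(nc), times = nr)
  sals <- data.frame(
    id = seq_len(n_use),
    xmin = (col - 1) * side, ymin = (row - 1) * side,
    xmax = col * side, ymax = row * side,
    area_km2 = side^2
  )
  set.seed(seed)
  w <- if (heterogeneity > 0) stats::rlnorm(n_use, 0, heterogeneity)
       else rep(1, n_use)
  raw <- sals$area_km2 * w
  sals$population <- total_population * raw / sum(raw)
  structure(sals, region_km = c(width = width, height = height),
            grid = c(rows = nr, cols = nc), requested_n_sal = n_sal,
            class = c("sal_layer", "data.frame"))
}

# factor pair (rows <= cols) of n closest to square; if the best pair is more
# elongated than max_aspect, walk outward to the nearest n with a better one
best_grid <- function(n, max_aspect = 25) {
  pair <- function(n) {
    r <- max(which(n %% seq_len(floor(sqrt(n))) == 0))
    c(r, n %/% r)
  }
  for (delta in 0:max(0, n - 1)) {
    for (cand in unique(c(n + delta, n - delta))) {
      if (cand < 1) next
      p <- pair(cand)
      if (p[2] / p[1] <= max_aspect) return(p)
    }
  }
  pair(n)
}

#' Allocate facility clusters to small areas and place them at random
#'
#' Converts a toilet stock into `round(total_toilets / cluster_size)` cluster
#' locations, apportions locations to SALs proportionally to population by
#' the largest-remainder (Hamilton) rule (ties broken by SAL id), and samples
#' each location uniformly within its SAL's rectangle.
#'
#' @param sals A [generate_sals()] layer.
#' @param total_toilets Total toilets to place (>= `cluster_size`).
#' @param cluster_size Toilets per location.
#' @param seed Integer seed for the uniform placement.
#' @return An object of class `"facility_layout"`: list with `locations`
#'   (data frame `id`, `sal_id`, `x_km`, `y_km`), `clusters_per_sal`,
#'   `cluster_size`, `total_toilets`.
#' @examples
#' sals <- generate_sals(16, 35.28, 392000, seed = 1)
#' lay <- allocate_clusters(sals, 5600, 7, seed = 2)
#' nrow(lay$locations)  # 800
#' @export
allocate_clusters <- function(sals, total_toilets, cluster_size = 7,
                              seed = 1L) {
  stopifnot(inherits(sals, "sal_layer"))
  if (cluster_size < 1 || total_toilets < cluster_size)
    stop("need cluster_size >= 1 and total_toilets >= cluster_size",
         call. = FALSE)
  n_loc <- round(total_toilets / cluster_size)
  counts <- largest_remainder(sals$population, n_loc)
  sal_id <- rep(sals$id, counts)
  set.seed(seed)
  # x for all locations in SAL-id order, then y: fixed consumption order
  u1 <- stats::runif(n_loc)
  u2 <- stats::runif(n_loc)
  i <- match(sal_id, sals$id)
  locations <- data.frame(
    id = seq_len(n_loc),
    sal_id = sal_id,
    x_km = sals$xmin[i] + u1 * (sals$xmax[i] - sals$xmin[i]),
    y_km = sals$ymin[i] + u2 * (sals$ymax[i] - sals$ymin[i])
  )
  structure(list(locations = locations, clusters_per_sal = counts,
                 cluster_size = cluster_size, total_toilets = total_toilets),
            class = "facility_layout")
}

# Hamilton apportionment of `total` integer seats proportional to weights
largest_remainder <- function(weights, total) {
  if (total == 0) return(integer(length(weights)))
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    # largest fractional parts first; ties broken by position (SAL id order)
    extra <- order(-(quota - base), seq_along(quota))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# chunked nearest-neighbor distances (km); torus = c(width, height) wraps
nearest_oneway_km <- function(px, py, lx, ly, torus = NULL) {
  m <- length(lx)
  n <- length(px)
  if (m == 0) stop("no facility locations", call. = FALSE)
  chunk <- max(1L, as.integer(5e6 %/% m))
  res <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    i <- s:e
    dx <- abs(outer(px[i], lx, "-"))
    dy <- abs(outer(py[i], ly, "-"))
    if (!is.null(torus)) {
      dx <- pmin(dx, torus[1] - dx)
      dy <- pmin(dy, torus[2] - dy)
    }
    d2 <- dx * dx + dy * dy
    res[i] <- sqrt(d2[cbind(seq_along(i), max.col(-d2, ties.method = "first"))])
  }
  res
}

#' Monte Carlo population-weighted mean nearest-facility distance
#'
#' Samples resident points (SAL chosen with probability proportional to
#' population, position uniform within the SAL), measures the Euclidean
#' distance to the nearest facility location anywhere in the region, and
#' returns the mean one-way distance with its standard error.
#'
#' Two boundary modes: `"bounded"` (realistic; residents near the region edge
#' have fewer nearby facilities, lengthening walks) and `"torus"`
#' (edge-corrected by wrapping both axes; converges to the stationary
#' nearest-neighbor closed form and is used for validation).
#'
#' @param sals A [generate_sals()] layer.
#' @param layout An [allocate_clusters()] layout over the same layer.
#' @param n_samples Number of resident samples (>= 1).
#' @param seed Integer seed.
#' @param boundary `"bounded"` or `"torus"`.
#' @return An object of class `"sim_estimate"`: list with `mean_oneway_m`,
#'   `mean_roundtrip_m` (twice one-way), `standard_error_m` (of the one-way
#'   mean), `n_samples`, `seed`, `boundary`, and `sal_counts`, the number of
#'   resident samples drawn from each SAL.
#' @export
simulate_mean_distance <- function(sals, layout, n_samples, seed = 1L,
                                   boundary = c("bounded", "torus")) {
  stopifnot(inherits(sals, "sal_layer"), inherits(layout, "facility_layout"))
  boundary <- match.arg(boundary)
  if (n_samples < 1) stop("'n_samples' must be at least 1", call. = FALSE)
  if (nrow(layout$locations) == 0)
    stop("facility layout is empty", call. = FALSE)
  set.seed(seed)
  idx <- sample.int(nrow(sals), n_samples, replace = TRUE,
                    prob = sals$population)
  px <- sals$xmin[idx] + stats::runif(n_samples) * (sals$xmax[idx] -
                                                      sals$xmin[idx])
  py <- sals$ymin[idx] + stats::runif(n_samples) * (sals$ymax[idx] -
                                                      sals$ymin[idx])
  torus <- if (boundary == "torus") attr(sals, "region_km") else NULL
  d_km <- nearest_oneway_km(px, py, layout$locations$x_km,
                            layout$locations$y_km, torus = torus)
  d_m <- 1000 * d_km
  se <- if (n_samples >= 2) stats::sd(d_m) / sqrt(n_samples) else NA_real_
  structure(list(mean_oneway_m = mean(d_m), mean_roundtrip_m = 2 * mean(d_m),
                 standard_error_m = se, n_samples = n_samples, seed = seed,
                 boundary = boundary,
                 sal_counts = tabulate(idx, nbins = nrow(sals))),
            class = "sim_estimate")
}

#' @export
print.sim_estimate <- function(x, ...) {
  cat(sprintf(
    "Simulated nearest-facility distance (%s, n = %d):\n", x$boundary,
    x$n_samples))
  cat(sprintf("  one way %.1f m (SE %.2f), round trip %.1f m\n",
              x$mean_oneway_m, x$standard_error_m, x$mean_roundtrip_m))
  invisible(x)
}

#' Closed-form mean one-way distance to the nearest facility location
#'
#' For facility locations distributed uniformly at random (a stationary
#' Poisson pattern) with density `lambda` per km^2, the mean distance from a
#' uniform point to the nearest location is `1 / (2 sqrt(lambda))` km. The
#' round trip is twice this, which is exactly the
#' `d(t) = sqrt(cluster_size * area / t)` law used by the incidence model.
#'
#' @param location_density_per_km2 Facility locations per km^2 (> 0).
#' @return Mean one-way distance in meters.
#' @examples
#' closed_form_oneway_m(800 / 35.28)  # 105 m one way (210 m round trip)
#' @export
closed_form_oneway_m <- function(location_density_per_km2) {
  if (any(location_density_per_km2 <= 0))
    stop("density must be strictly positive", call. = FALSE)
  1000 / (2 * sqrt(location_density_per_km2))
}
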