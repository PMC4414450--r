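test_that("synthetic small-area layers tile the region and conserve people", {
  sals <- generate_sals(583, 35.28, 392000, heterogeneity = 0, seed = 1)
  expect_identical(nrow(sals), 583L)
  expect_identical(unname(attr(sals, "grid")), c(11L, 53L))
  expect_equal(sum(sals$area_km2), 35.28, tolerance = 1e-9)
  expect_equal(sum(sals$population), 392000, tolerance = 1e-9)
  # zero heterogeneity: identical density everywhere
  dens <- sals$population / sals$area_km2
  expect_equal(dens, rep(392000 / 35.28, 583), tolerance = 1e-9)
  # tiles are disjoint and match their stated area
  expect_equal(sals$area_km2, (sals$xmax - sals$xmin) * (sals$ymax -
                                                           sals$ymin),
               tolerance = 1e-12)
  reg <- attr(sals, "region_km")
  expect_equal(sum(sals$area_km2), unname(reg[1] * reg[2]), tolerance = 1e-9)
  expect_error(generate_sals(0, 1, 1), "n_sal >= 1")
  expect_error(generate_sals(4, -1, 1), "positive area")
})

test_that("heterogeneous populations are reproducible for a fixed seed", {
  s <- generate_sals(4, 4.0, 1000, heterogeneity = 0.5, seed = 1)
  expect_equal(s$population,
               c(155.3503600899, 232.9284957433, 139.9234591756,
                 471.7976849912),
               tolerance = 1e-9)
  expect_equal(sum(s$population), 1000, tolerance = 1e-9)
  s2 <- generate_sals(4, 4.0, 1000, heterogeneity = 0.5, seed = 1)
  expect_identical(s$population, s2$population)
})

test_that("cluster allocation apportions by population with bounded error", {
  sals <- generate_sals(583, 35.28, 392000, heterogeneity = 0.4, seed = 2)
  lay <- allocate_clusters(sals, 5600, 7, seed = 3)
  expect_identical(nrow(lay$locations), 800L)
  expect_identical(sum(lay$clusters_per_sal), 800L)
  # largest remainder: each SAL within one cluster of exact proportionality
  quota <- 800 * sals$population / sum(sals$population)
  expect_true(all(abs(lay$clusters_per_sal - quota) < 1))
  # every location inside its own SAL's rectangle
  i <- match(lay$locations$sal_id, sals$id)
  expect_true(all(lay$locations$x_km >= sals$xmin[i] &
                    lay$locations$x_km <= sals$xmax[i] &
                    lay$locations$y_km >= sals$ymin[i] &
                    lay$locations$y_km <= sals$ymax[i]))
  # expanded stock: 11300 toilets in clusters of 7 -> 1614 locations
  lay2 <- allocate_clusters(sals, 11300, 7, seed = 3)
  expect_identical(nrow(lay2$locations), 1614L)
  expect_error(allocate_clusters(sals, 3, 7), "total_toilets >=")
})

test_that("equal-population areas split clusters symmetrically", {
  sals <- generate_sals(2, 2, 1000, heterogeneity = 0, seed = 1)
  lay <- allocate_clusters(sals, 14, 7, seed = 1)
  expect_identical(lay$clusters_per_sal, c(1L, 1L))
})

test_that("closed-form nearest-location distance obeys the density law", {
  expect_equal(closed_form_oneway_m(800 / 35.28), 105, tolerance = 1e-9)
  d <- closed_form_oneway_m(3)
  expect_equal(closed_form_oneway_m(12), d / 2, tolerance = 1e-12)
  expect_error(closed_form_oneway_m(0), "positive")
})

test_that("single central facility matches the analytic square integral", {
  L <- 2
  sals <- generate_sals(1, L^2, 1000, seed = 1)
  lay <- manual_layout(L / 2, L / 2)
  est <- simulate_mean_distance(sals, lay, 20000, seed = 4)
  analytic <- 1000 * L * (sqrt(2) + asinh(1)) / 6
  expect_lt(abs(est$mean_oneway_m - analytic), 3 * est$standard_error_m)
  expect_equal(est$mean_roundtrip_m, 2 * est$mean_oneway_m)
})

test_that("quadrupling location density halves the simulated mean", {
  # average over layouts: a single realization's conditional mean carries
  # layout-to-layout variation on top of resident-sampling error
  sals <- generate_sals(1, 36, 50000, seed = 1)
  mean_over_layouts <- function(toilets, seeds) {
    sapply(seeds, function(s) {
      lay <- allocate_clusters(sals, toilets, 7, seed = s)
      simulate_mean_distance(sals, lay, 5000, seed = s + 100,
                             boundary = "torus")$mean_oneway_m
    })
  }
  m1 <- mean_over_layouts(350, 1:12)    # 50 locations each
  m4 <- mean_over_layouts(1400, 13:24)  # 200 locations each
  se <- sqrt(stats::var(m1) / 12 + 4 * stats::var(m4) / 12)
  expect_lt(abs(mean(m1) - 2 * mean(m4)), 3 * se)
})

test_that("residents are sampled proportionally to population", {
  sals <- generate_sals(4, 4, 1000, heterogeneity = 0, seed = 1)
  # double one SAL's population relative to the others
  sals$population <- c(2, 1, 1, 1) * 250
  lay <- allocate_clusters(sals, 7, 7, seed = 2)
  est <- simulate_mean_distance(sals, lay, 1e5, seed = 10)
  counts <- est$sal_counts
  gof <- stats::chisq.test(counts, p = sals$population / sum(sals$population))
  expect_gt(gof$p.value, 0.01)
  # the doubled SAL receives about twice each single share
  expect_equal(counts[1] / mean(counts[2:4]), 2, tolerance = 0.05)
})

test_that("bounded walks are never shorter than torus walks", {
  sals <- generate_sals(16, 35.28, 392000, heterogeneity = 0.3, seed = 8)
  lay <- allocate_clusters(sals, 700, 7, seed = 8)
  b <- simulate_mean_distance(sals, lay, 20000, seed = 9,
                              boundary = "bounded")
  t <- simulate_mean_distance(sals, lay, 20000, seed = 9, boundary = "torus")
  # torus distance is pointwise <= bounded distance for the same residents
  expect_gte(b$mean_oneway_m, t$mean_oneway_m)
})

test_that("distance simulation is seed-deterministic and validates inputs", {
  sals <- generate_sals(9, 9, 900, seed = 1)
  lay <- allocate_clusters(sals, 70, 7, seed = 2)
  a <- simulate_mean_distance(sals, lay, 5000, seed = 3)
  b <- simulate_mean_distance(sals, lay, 5000, seed = 3)
  expect_identical(a$mean_oneway_m, b$mean_oneway_m)
  expect_gt(a$standard_error_m, 0)
  expect_error(simulate_mean_distance(sals, lay, 0), "at least 1")
})
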