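test_that("composite cost reproduces the headline totals", {
  m <- base_model()
  expect_equal(total_cost(m, 5600) / 1e6, 39.49, tolerance = 1e-3)
  opt <- optimal_toilets(m, check_numeric = FALSE)
  expect_equal(total_cost(m, opt$t_star) / 1e6, 35.47, tolerance = 1e-3)
  # zero assault burden leaves the pure linear facility cost
  m0 <- sanitation_model(scenario_params(assault_cost_usd = 0))
  expect_equal(total_cost(m0, c(1, 5600, 2e4)),
               m0$calibration$toilet_cost_usd * c(1, 5600, 2e4),
               tolerance = 1e-12)
})

test_that("closed-form optimum matches its structure and printed summary", {
  m <- base_model()
  opt <- optimal_toilets(m)
  expect_equal(round_to(opt$t_star, 100), 11300)
  expect_equal(round(opt$point$assaults), 446)
  expect_lt(opt$agreement_rel, 1e-3)
  # first-order condition at the stationary point, machine precision
  cc <- m$calibration$toilet_cost_usd
  ss <- m$params$assault_cost_usd
  kk <- m$calibration$k_constant
  expect_equal(cc, 0.5 * ss * kk * opt$t_star^(-1.5), tolerance = 1e-12)
  # second derivative positive: interior minimum
  h <- 1
  curv <- total_cost(m, opt$t_star + h) - 2 * total_cost(m, opt$t_star) +
    total_cost(m, opt$t_star - h)
  expect_gt(curv, 0)
})

test_that("optimum is homogeneous of degree 0 in (c, s) and scales as s^(2/3)", {
  m <- base_model()
  t_base <- optimal_toilets(m, check_numeric = FALSE)$t_star
  for (f in c(0.25, 3, 10)) {
    mf <- sanitation_model(scenario_params(toilet_cost_rand = 10315 * f,
                                           assault_cost_usd = 53000 * f))
    expect_equal(optimal_toilets(mf, check_numeric = FALSE)$t_star, t_base,
                 tolerance = 1e-12)
  }
  m2 <- sanitation_model(scenario_params(assault_cost_usd = 2 * 53000))
  expect_equal(optimal_toilets(m2, check_numeric = FALSE)$t_star,
               t_base * 2^(2 / 3), tolerance = 1e-12)
})

test_that("numeric minimizer agrees with the closed form across random scenarios", {
  set.seed(42)
  for (i in 1:1000) {
    p <- scenario_params(
      reported_assaults_per_year = runif(1, 50, 5000),
      toilet_cost_rand = runif(1, 1000, 50000),
      assault_cost_usd = runif(1, 5000, 2e5)
    )
    opt <- optimal_toilets(sanitation_model(p))
    expect_lt(opt$agreement_rel, 1e-3)
  }
})

test_that("zero assault burden warns and pins the optimum to the boundary", {
  m0 <- sanitation_model(scenario_params(assault_cost_usd = 0))
  expect_warning(opt <- optimal_toilets(m0), "boundary")
  expect_identical(opt$t_star, 1)
})

test_that("cost-neutral expansion bound matches bisection and a grid scan", {
  m <- base_model()
  cnu <- cost_neutral_upper(m)
  expect_equal(round_to(cnu, 100), 21400)
  expect_equal(round(expected_assaults(m, cnu)), 325)
  # at the bound, total cost equals the baseline total
  expect_equal(total_cost(m, cnu), total_cost(m, 5600), tolerance = 1e-9)
  expect_lt(expected_assaults(m, cnu), expected_assaults(m, 5600))
  # independent oracle: 1-toilet grid scan of the increasing branch
  opt_t <- optimal_toilets(m, check_numeric = FALSE)$t_star
  grid <- seq(ceiling(opt_t), 50000)
  below <- grid[total_cost(m, grid) <= total_cost(m, 5600)]
  expect_lte(abs(max(below) - cnu), 1)
})

test_that("cost-neutral bound degenerates to the optimum at tangency", {
  # choose the assault cost that puts the optimum exactly at the baseline
  m <- base_model()
  s_tangent <- 2 * m$calibration$toilet_cost_usd * 5600^1.5 /
    m$calibration$k_constant
  mt <- sanitation_model(scenario_params(assault_cost_usd = s_tangent))
  opt <- optimal_toilets(mt, check_numeric = FALSE)
  expect_equal(opt$t_star, 5600, tolerance = 1e-9)
  expect_equal(cost_neutral_upper(mt), opt$t_star, tolerance = 1e-6)
})

test_that("marginal table shows diminishing returns to extra toilets", {
  m <- base_model()
  tab <- marginal_table(m, 1:4)
  expect_equal(tab$toilets, c(5600, 11200, 16800, 22400))
  expect_equal(tab$assaults, c(635, 449, 366.6, 317.5), tolerance = 2e-3)
  expect_equal(round(tab$averted_vs_previous[2:4]), c(186, 82, 49))
  expect_true(is.na(tab$averted_vs_previous[1]))
  # the quadrupled stock halves assaults exactly (inverse square root)
  expect_equal(tab$assaults[4], 635 / 2, tolerance = 1e-12)

  one <- marginal_table(m, 1)
  expect_identical(nrow(one), 1L)
  expect_error(marginal_table(m, c(2, 3)), "start at 1")
  expect_error(marginal_table(m, c(1, 3, 2)), "ascending")
})

test_that("cost curve is linear in facilities, convex in total", {
  m <- base_model()
  cc <- cost_curve(m, 1000, 30000, n_points = 291)
  # direct cost exactly linear: second differences vanish
  expect_equal(max(abs(diff(diff(cc$direct_cost_usd)))), 0, tolerance = 1e-6)
  expect_equal(cc$direct_cost_usd,
               m$calibration$toilet_cost_usd * cc$toilets, tolerance = 1e-12)
  # total cost convex: discrete second differences non-negative
  expect_true(all(diff(diff(cc$total_cost_usd)) > -1e-6))
  # grid minimum brackets the closed-form optimum within one step
  t_star <- optimal_toilets(m, check_numeric = FALSE)$t_star
  step <- diff(cc$toilets[1:2])
  expect_lte(abs(cc$toilets[which.min(cc$total_cost_usd)] - t_star), step)
  # printed direct-cost anchors
  expect_equal(total_cost(sanitation_model(
    scenario_params(assault_cost_usd = 0)), 5600) / 1e6, 5.835,
    tolerance = 1e-3)
  expect_equal(m$calibration$toilet_cost_usd * t_star / 1e6, 11.82,
               tolerance = 1e-3)
  expect_error(cost_curve(m, 5000, 5000), "t_min < t_max")
})
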