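#' Composite annual social cost
#'
#' The sum of the direct facility cost and the monetized assault burden:
#' `c * t + s * k / sqrt(t)` with `c` the annual per-toilet cost in USD,
#' `s` the social cost per assault, and `k` the calibrated distance-law
#' constant. Convex in `t` with a unique interior minimum when all three are
#' positive.
#'
#' @inheritParams roundtrip_distance
#' @return Total cost in USD/year (vectorized over `toilets`).
#' @export
total_cost <- function(model, toilets) {
  stopifnot(inherits(model, "sanitation_model"))
  stopifnot_toilets(toilets)
  model$calibration$toilet_cost_usd * toilets +
    model$params$assault_cost_usd * expected_assaults(model, toilets)
}

#' Full cost/exposure summary at given toilet counts
#'
#' @inheritParams roundtrip_distance
#' @return A data frame with one row per element of `toilets` and columns
#'   `toilets`, `locations` (toilets / cluster size, unrounded), `roundtrip_m`,
#'   `exposure_min_per_woman_day`, `assaults`, `direct_cost_usd`,
#'   `assault_cost_usd`, `total_cost_usd`.
#' @export
cost_point <- function(model, toilets) {
  stopifnot(inherits(model, "sanitation_model"))
  stopifnot_toilets(toilets)
  a <- expected_assaults(model, toilets)
  direct <- model$calibration$toilet_cost_usd * toilets
  burden <- model$params$assault_cost_usd * a
  data.frame(
    toilets = toilets,
    locations = toilets / model$params$cluster_size,
    roundtrip_m = roundtrip_distance(model, toilets),
    exposure_min_per_woman_day = 60 * exposure_hours(model, toilets),
    assaults = a,
    direct_cost_usd = direct,
    assault_cost_usd = burden,
    total_cost_usd = direct + burden
  )
}

#' Cost-minimizing toilet count
#'
#' Minimizes the composite cost in closed form,
#' `t* = (s k / (2 c))^(2/3)` (the stationary point of `c t + s k t^(-1/2)`),
#' and cross-checks it with a bounded one-dimensional numeric minimization.
#' The two must agree to 0.1% relative; their realized relative difference is
#' returned.
#'
#' @param model A [sanitation_model()].
#' @param check_numeric Run the [stats::optimize()] cross-check (default TRUE).
#' @return An object of class `"toilet_optimum"`: list with `t_star`
#'   (unrounded), `t_star_numeric`, `agreement_rel`, `solver`, and `point`,
#'   the [cost_point()] row at the closed-form optimum.
#' @examples
#' opt <- optimal_toilets(sanitation_model())
#' opt$t_star        # about 11,347
#' opt$point$assaults  # about 446
#' @export
optimal_toilets <- function(model, check_numeric = TRUE) {
  stopifnot(inherits(model, "sanitation_model"))
  cc <- model$calibration$toilet_cost_usd
  ss <- model$params$assault_cost_usd
  kk <- model$calibration$k_constant
  if (cc <= 0) stop("toilet cost must be positive to optimize", call. = FALSE)
  if (ss * kk <= 0) {
    warning("assault burden is zero: cost is increasing in toilets and the ",
            "optimum sits at the domain boundary t = 1", call. = FALSE)
    t_star <- 1
  } else {
    t_star <- (ss * kk / (2 * cc))^(2 / 3)
  }
  t_num <- NA_real_
  agree <- NA_real_
  if (check_numeric && ss * kk > 0) {
    upper <- max(100 * t_star, 10)
    t_num <- stats::optimize(function(t) total_cost(model, t),
                             interval = c(1, upper), tol = 1e-10)$minimum
    agree <- abs(t_num - t_star) / t_star
    if (agree > 1e-3)
      warning("numeric minimizer differs from the closed form by more ",
              "than 0.1%", call. = FALSE)
  }
  structure(list(t_star = t_star, t_star_numeric = t_num,
                 agreement_rel = agree,
                 solver = if (check_numeric) "closed_form+numeric"
                          else "closed_form",
                 point = cost_point(model, t_star)),
            class = "toilet_optimum")
}

#' @export
print.toilet_optimum <- function(x, ...) {
  cat("Cost-minimizing toilet stock\n")
  cat(sprintf("  t* = %.1f toilets (reported as %g)\n",
              x$t_star, round(x$t_star / 100) * 100))
  if (is.finite(x$agreement_rel))
    cat(sprintf("  closed form vs numeric minimizer: %.2g relative\n",
                x$agreement_rel))
  print(x$point, digits = 4)
  invisible(x)
}

#' Cost-neutral upper expansion bound
#'
#' The largest toilet stock whose composite cost does not exceed the
#' baseline's: the root above the optimum of
#' `total_cost(t) = total_cost(baseline)`, found by bracketed bisection on the
#' increasing branch.
#'
#' @param model A [sanitation_model()].
#' @param tol Relative bisection tolerance on `t` (default 1e-9).
#' @return The cost-neutral toilet count (numeric scalar, unrounded).
#' @examples
#' cost_neutral_upper(sanitation_model())  # about 21,400
#' @export
cost_neutral_upper <- function(model, tol = 1e-9) {
  stopifnot(inherits(model, "sanitation_model"))
  t0 <- model$params$baseline_toilets
  opt <- optimal_toilets(model, check_numeric = FALSE)
  target <- total_cost(model, t0)
  c_min <- total_cost(model, opt$t_star)
  if (target <= c_min * (1 + 1e-12)) {
    if (abs(t0 - opt$t_star) <= 1e-6 * opt$t_star) return(opt$t_star)
    stop("baseline is already at or below the cost minimum; ",
         "no cost-neutral expansion exists", call. = FALSE)
  }
  f <- function(t) total_cost(model, t) - target
  lo <- opt$t_star
  hi <- 2 * lo
  while (f(hi) < 0) hi <- 2 * hi
  while ((hi - lo) > tol * hi) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Diminishing-returns table over multiples of the baseline stock
#'
#' Evaluates expected assaults at multiples of the baseline toilet stock and
#' the assaults averted relative to the previous row, quantifying the
#' diminishing marginal benefit of the inverse-square-root law.
#'
#' @param model A [sanitation_model()].
#' @param multiples Ascending factors starting at 1.
#' @return Data frame with columns `multiple`, `toilets`, `assaults`,
#'   `averted_vs_previous` (NA in the first row).
#' @examples
#' marginal_table(sanitation_model(), 1:3)
#' @export
marginal_table <- function(model, multiples = 1:3) {
  stopifnot(inherits(model, "sanitation_model"))
  if (length(multiples) < 1 || multiples[1] != 1 || is.unsorted(multiples,
                                                               strictly = TRUE))
    stop("'multiples' must be strictly ascending and start at 1",
         call. = FALSE)
  t <- multiples * model$params$baseline_toilets
  a <- expected_assaults(model, t)
  data.frame(multiple = multiples, toilets = t, assaults = a,
             averted_vs_previous = c(NA, -diff(a)))
}

#' Cost curve over a toilet grid
#'
#' Evaluates every cost component on an evenly spaced grid; the direct cost
#' column is exactly linear in toilets and the total is convex.
#'
#' @param model A [sanitation_model()].
#' @param t_min,t_max Grid bounds (1 <= t_min < t_max).
#' @param n_points Number of grid points (>= 2).
#' @return A data frame of [cost_point()] rows, class `"cost_curve"`.
#' @export
cost_curve <- function(model, t_min = 1000, t_max = 30000, n_points = 200) {
  stopifnot(inherits(model, "sanitation_model"))
  if (t_min < 1 || t_min >= t_max || n_points < 2)
    stop("need 1 <= t_min < t_max and n_points >= 2", call. = FALSE)
  grid <- seq(t_min, t_max, length.out = n_points)
  out <- cost_point(model, grid)
  class(out) <- c("cost_curve", "data.frame")
  out
}

#' Plot the composite cost decomposition
#'
#' Draws direct facility cost, assault burden and their sum against the
#' toilet stock, marking the baseline and the closed-form optimum.
#'
#' @param x A [sanitation_model()].
#' @param t_min,t_max,n_points Grid passed to [cost_curve()].
#' @param ... Further arguments to [graphics::matplot()].
#' @return Invisibly, the plotted cost curve.
#' @export
plot.sanitation_model <- function(x, t_min = 1000, t_max = 30000,
                                  n_points = 200, ...) {
  cc <- cost_curve(x, t_min, t_max, n_points)
  m <- cbind(cc$direct_cost_usd, cc$assault_cost_usd, cc$total_cost_usd) / 1e6
  graphics::matplot(cc$toilets, m, type = "l", lty = c(2, 3, 1),
                    col = c("grey40", "grey40", "black"), lwd = c(1, 1, 2),
                    xlab = "toilets", ylab = "annual cost (million USD)", ...)
  opt <- optimal_toilets(x, check_numeric = FALSE)
  graphics::abline(v = c(x$params$baseline_toilets, opt$t_star),
                   lty = c(3, 1), col = "grey70")
  graphics::legend("topright", c("facilities", "assault burden", "total"),
                   lty = c(2, 3, 1), col = c("grey40", "grey40", "black"),
                   lwd = c(1, 1, 2), bty = "n")
  invisible(cc)
}
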