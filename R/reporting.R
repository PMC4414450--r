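#' Report-rounding helper
#'
#' Rounds a value to the nearest multiple of `nearest`. Display rounding is a
#' reporting-layer convention only; every downstream computation in the
#' package consumes unrounded values.
#'
#' @param x Numeric.
#' @param nearest Positive rounding unit (e.g. 100 for toilet counts, 1e6 for
#'   USD reported in millions).
#' @return Rounded numeric.
#' @export
round_to <- function(x, nearest = 1) {
  if (nearest <= 0) stop("'nearest' must be positive", call. = FALSE)
  nearest * round(x / nearest)
}

#' Assemble a run configuration
#'
#' Bundles everything one reproducible end-to-end run needs: the scenario,
#' the sensitivity ranges, probabilistic-analysis settings, and the spatial
#' validation settings. The defaults reproduce the base case with no edits.
#'
#' @param scenario A [scenario_params()] object or named list of overrides.
#' @param ranges A [param_ranges()] data frame.
#' @param n_draws Probabilistic-analysis iterations (default 5000).
#' @param seed Seed for the probabilistic analysis.
#' @param n_sal Number of synthetic small areas.
#' @param n_samples Resident samples in the spatial validation.
#' @param boundary_mode `"bounded"` or `"torus"` for the reported simulation
#'   (the validation ratio is always computed in torus mode).
#' @param sim_seed Seed for the spatial stage.
#' @param rounded Apply display rounding to the headline table.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(scenario = scenario_params(),
                       ranges = param_ranges(),
                       n_draws = 5000, seed = 1L,
                       n_sal = 583, n_samples = 100000,
                       boundary_mode = "bounded", sim_seed = 1L,
                       rounded = TRUE) {
  structure(list(scenario = as_scenario_params(scenario), ranges = ranges,
                 psa = list(n_draws = n_draws, seed = seed),
                 simulation = list(n_sal = n_sal, n_samples = n_samples,
                                   boundary_mode = boundary_mode,
                                   seed = sim_seed),
                 rounded = rounded),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The file is flat key-value YAML with optional sections `scenario`,
#' `psa`, `simulation`, `ranges` (a list of name/low/base/high records) and
#' `rounded`; missing keys take their defaults. Writing and re-reading a
#' configuration is idempotent.
#'
#' @param path File path.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ranges <- if (!is.null(y$ranges)) {
    r <- do.call(rbind, lapply(y$ranges, as.data.frame))
    class(r) <- c("param_ranges", "data.frame")
    r
  } else param_ranges()
  args <- list(scenario = if (is.null(y$scenario)) scenario_params()
               else as_scenario_params(y$scenario),
               ranges = ranges)
  if (!is.null(y$psa$n_draws)) args$n_draws <- y$psa$n_draws
  if (!is.null(y$psa$seed)) args$seed <- y$psa$seed
  for (nm in c("n_sal", "n_samples", "boundary_mode"))
    if (!is.null(y$simulation[[nm]])) args[[nm]] <- y$simulation[[nm]]
  if (!is.null(y$simulation$seed)) args$sim_seed <- y$simulation$seed
  if (!is.null(y$rounded)) args$rounded <- y$rounded
  do.call(run_config, args)
}

#' Write a run configuration to a YAML file
#'
#' @param config A [run_config()] object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  sc <- unclass(config$scenario)
  attributes(sc) <- list(names = names(sc))
  y <- list(
    scenario = sc,
    ranges = lapply(seq_len(nrow(config$ranges)), function(i)
      as.list(config$ranges[i, c("name", "low", "base", "high")])),
    psa = config$psa,
    simulation = config$simulation,
    rounded = config$rounded
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Headline summary table: base case versus cost-minimizing optimum
#'
#' Builds the base-vs-optimum comparison: toilet stock, expected assaults,
#' mean round-trip distance, direct facility cost, assault burden and total
#' cost, with a percent-change column. Display rounding (toilets to the
#' nearest 100, costs to the nearest million USD, assaults and meters to
#' integers, percent change to the nearest 10 points) is applied to the
#' returned table only; the unrounded values are attached as attribute
#' `"unrounded"`, and percent changes are always computed from unrounded
#' values.
#'
#' @param model A [sanitation_model()].
#' @param rounded Apply display rounding (default TRUE).
#' @return Data frame with columns `base`, `optimal`, `pct_change` and one
#'   row per quantity.
#' @examples
#' base_case_table(sanitation_model())
#' @export
base_case_table <- function(model, rounded = TRUE) {
  stopifnot(inherits(model, "sanitation_model"))
  opt <- optimal_toilets(model)
  if (opt$point$assaults * model$params$assault_cost_usd == 0)
    warning("assault burden is zero: the optimum sits at the domain boundary",
            call. = FALSE)
  b <- cost_point(model, model$params$baseline_toilets)
  o <- opt$point
  rows <- c("toilets", "assaults", "roundtrip_m", "direct_cost_musd",
            "assault_cost_musd", "total_cost_musd")
  base <- c(b$toilets, b$assaults, b$roundtrip_m, b$direct_cost_usd / 1e6,
            b$assault_cost_usd / 1e6, b$total_cost_usd / 1e6)
  optv <- c(o$toilets, o$assaults, o$roundtrip_m, o$direct_cost_usd / 1e6,
            o$assault_cost_usd / 1e6, o$total_cost_usd / 1e6)
  pct <- 100 * (optv / base - 1)
  un <- data.frame(base = base, optimal = optv, pct_change = pct,
                   row.names = rows)
  out <- un
  if (rounded) {
    unit <- c(100, 1, 1, 1, 1, 1)      # toilets to nearest 100
    out$base <- mapply(round_to, base, unit)
    out$optimal <- mapply(round_to, optv, unit)
    out$pct_change <- round_to(pct, 10)
  }
  attr(out, "unrounded") <- un
  out
}

#' Run the base-case report
#'
#' Calibrates the scenario in `config`, produces the headline
#' base-vs-optimum table, and (optionally) writes the rounded table and its
#' unrounded companion as CSV.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, or NULL to skip writing.
#' @return List with `model`, `optimum`, `table` (rounded per config) and
#'   `unrounded`.
#' @export
run_base_case <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  model <- sanitation_model(config$scenario)
  tab <- base_case_table(model, rounded = config$rounded)
  res <- list(model = model, optimum = optimal_toilets(model), table = tab,
              unrounded = attr(tab, "unrounded"))
  if (!is.null(out_dir)) {
    ensure_dir(out_dir)
    write_csv_safe(cbind(quantity = rownames(tab), tab),
                   file.path(out_dir, "base_case.csv"))
    write_csv_safe(cbind(quantity = rownames(res$unrounded), res$unrounded),
                   file.path(out_dir, "base_case_unrounded.csv"))
  }
  res
}

ensure_dir <- function(path) {
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("cannot create output directory: ", path, call. = FALSE)
  invisible(path)
}

write_csv_safe <- function(df, path) {
  tryCatch(utils::write.csv(df, path, row.names = FALSE),
           error = function(e) stop("failed writing '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Run the full pipeline and write an artifact bundle
#'
#' Calibrate, optimize, trace the cost curve, run the tornado and
#' probabilistic analyses, and validate the distance law on a synthetic
#' small-area layer. Writes every stage's CSV, a plain-text run log (seeds,
#' parameter echo, stage order) and a YAML summary. With fixed seeds the CSV
#' outputs are byte-identical across runs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed), or NULL to return
#'   results without writing.
#' @return List with components `base` (see [run_base_case()]), `curve`,
#'   `tornado`, `psa`, `spatial` (list with the configured-mode
#'   estimate, the torus estimate, the closed form and their ratio) and
#'   `summary` (named list of headline numbers).
#' @export
run_full <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))
  stage <- function(name, expr) {
    say("stage: %s", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  say("sanicost run_full; psa seed %d; sim seed %d",
      config$psa$seed, config$simulation$seed)

  base <- stage("calibrate+optimize", run_base_case(config, out_dir = NULL))
  model <- base$model
  curve <- stage("cost_curve",
                 cost_curve(model, 1000, 30000, n_points = 291))
  torn <- stage("tornado", tornado(model, config$ranges))
  psa_res <- stage("psa", psa(model, config$ranges,
                              n_draws = config$psa$n_draws,
                              seed = config$psa$seed))
  spatial <- stage("spatial_validation", {
    p <- model$params
    sals <- generate_sals(config$simulation$n_sal, p$effective_area_km2,
                          women_population(p) / p$female_prop,
                          heterogeneity = 0.3,
                          seed = config$simulation$seed)
    lay <- allocate_clusters(sals, p$baseline_toilets, p$cluster_size,
                             seed = config$simulation$seed)
    est <- simulate_mean_distance(sals, lay, config$simulation$n_samples,
                                  seed = config$simulation$seed,
                                  boundary = config$simulation$boundary_mode)
    torus <- simulate_mean_distance(sals, lay, config$simulation$n_samples,
                                    seed = config$simulation$seed,
                                    boundary = "torus")
    dens <- nrow(lay$locations) / p$effective_area_km2
    cf <- closed_form_oneway_m(dens)
    list(estimate = est, torus = torus, closed_form_oneway_m = cf,
         ratio_torus_vs_closed_form = torus$mean_oneway_m / cf)
  })
  summary <- list(
    t_star = base$optimum$t_star,
    assaults_at_optimum = base$optimum$point$assaults,
    total_cost_musd_base = base$unrounded["total_cost_musd", "base"],
    total_cost_musd_optimum = base$unrounded["total_cost_musd", "optimal"],
    cost_neutral_upper = cost_neutral_upper(model),
    psa_fraction_exceeding_baseline = psa_res$fraction_exceeding_baseline,
    spatial_ratio_torus_vs_closed_form =
      spatial$ratio_torus_vs_closed_form
  )
  say("psa exceedance fraction: %.4f",
      summary$psa_fraction_exceeding_baseline)
  say("spatial torus/closed-form ratio: %.4f",
      summary$spatial_ratio_torus_vs_closed_form)

  if (!is.null(out_dir)) {
    ensure_dir(out_dir)
    run_base_case(config, out_dir = out_dir)
    write_csv_safe(curve[, c("toilets", "locations", "direct_cost_usd",
                             "assault_cost_usd", "total_cost_usd",
                             "assaults", "roundtrip_m")],
                   file.path(out_dir, "cost_curve.csv"))
    write_csv_safe(torn, file.path(out_dir, "tornado.csv"))
    write_csv_safe(cbind(psa_res$draws, t_star = psa_res$t_star),
                   file.path(out_dir, "psa_draws.csv"))
    yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  list(base = base, curve = curve, tornado = torn, psa = psa_res,
       spatial = spatial, summary = summary)
}
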