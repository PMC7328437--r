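# Orchestration of full runs: multi-day simulations at 5-minute steps with
# warm-up, final-day reporting, and replicate aggregation with bootstrap
# confidence intervals.

#' Run configuration
#'
#' @param n_days simulated days; only the final day is reported (the model
#'   reaches its daily equilibrium cycle after about two warm-up days).
#' @param step_minutes step length; must divide 60.
#' @param n_replicates independent replicates for [run_replicates()].
#' @param warmup_days warm-up days discarded before the reported day.
#' @param seed master seed; replicate seeds are derived from it by a
#'   counter.
#' @return A list of class `surf_run_config`.
#' @export
run_config <- function(n_days = 14, step_minutes = 5, n_replicates = 50,
                       warmup_days = 2, seed = 1) {
  stopifnot(n_days > warmup_days, 60 %% step_minutes == 0, n_replicates >= 1)
  structure(list(n_days = n_days, step_minutes = step_minutes,
                 n_replicates = n_replicates, warmup_days = warmup_days,
                 seed = seed),
            class = "surf_run_config")
}

# Buildings/sensors flattened for the engine; sensor discs are centred on
# the sensor's snapped network node.
town_to_engine <- function(town) {
  b <- town$buildings
  list(node_x = town$nodes$x, node_y = town$nodes$y,
       edge_u = match(town$edges$u, town$nodes$id),
       edge_v = match(town$edges$v, town$nodes$id),
       edge_len = town$edges$length_m,
       building_node = b$node, building_x = b$x, building_y = b$y,
       building_fun = match(b$fun, FUNCTIONS),
       sensor_x = town$nodes$x[town$sensors$node],
       sensor_y = town$nodes$y[town$sensors$node],
       sensor_r = town$sensors$radius_m)
}

# Check that the town can host every configured flexible activity of the
# groups present in the population.
check_coverage <- function(town, population, params) {
  groups <- unique(population$agents$group)
  need <- unique(stats::na.omit(unlist(lapply(groups, function(g)
    REQUIRED_FUNCTION[names(params$activities[[g]])]))))
  missing <- setdiff(need, town$buildings$fun)
  if (length(missing))
    stop("town has no building with function ",
         paste(sQuote(missing), collapse = ", "),
         " required by configured activities")
}

#' Run a single simulation replicate
#'
#' Steps every agent through `n_days` at `step_minutes` resolution and
#' reports the final day: hourly sensor footfall, the per-agent per-step
#' activity log (`0` codes travel), and the attributed crossing events.
#' Deterministic given `replicate_seed`.
#'
#' @param town a [surf_town()].
#' @param population a [synthesize_population()] result.
#' @param params model parameters.
#' @param config a [run_config()].
#' @param replicate_seed seed for this replicate's random stream.
#' @return A list of class `surf_run`: `footfall` (sensors x 24), `log`
#'   (agents x steps-per-day), `events` (data.frame), `groups`.
#' @export
run_simulation <- function(town, population, params = default_params(),
                           config = run_config(), replicate_seed = 1) {
  stopifnot(inherits(town, "surf_town"),
            inherits(population, "surf_population"))
  validate_params(params)
  n <- nrow(population$agents)
  spd <- 1440 %/% config$step_minutes
  if (n == 0) {
    ff <- matrix(0L, nrow(town$sensors), 24,
                 dimnames = list(as.character(town$sensors$id),
                                 sprintf("h%02d", 0:23)))
    return(structure(list(footfall = ff,
                          log = matrix(integer(0), 0, spd),
                          events = data.frame(agent = integer(0),
                                              sensor_id = character(0),
                                              step = integer(0)),
                          groups = character(0)),
                     class = "surf_run"))
  }
  check_coverage(town, population, params)
  cfg <- list(step_minutes = config$step_minutes, n_days = config$n_days,
              walking_speed_mps = params$global$walking_speed_mps,
              initial_radius_m = params$allocation$initial_radius_m,
              max_doublings = params$allocation$max_doublings,
              daily_jitter_min = params$global$daily_jitter_min)
  res <- with_seed(replicate_seed,
                   run_engine_cpp(town_to_engine(town),
                                  population_to_engine(population, town),
                                  params_to_engine(params), cfg))
  ff <- res$footfall
  dimnames(ff) <- list(as.character(town$sensors$id), sprintf("h%02d", 0:23))
  structure(list(
    footfall = ff,
    log = res$log,
    events = data.frame(
      agent = res$event_agent,
      sensor_id = as.character(town$sensors$id)[res$event_sensor],
      step = res$event_step),
    groups = population$agents$group),
    class = "surf_run")
}

#' Run and aggregate independent replicates
#'
#' Executes `config$n_replicates` replicates (seeds
#' `config$seed + 1, + 2, ...`) and aggregates the final-day footfall:
#' per sensor-hour mean across replicates with percentile bootstrap
#' confidence intervals.
#'
#' @inheritParams run_simulation
#' @param ci_level confidence level of the bootstrap intervals.
#' @param n_boot bootstrap resamples.
#' @param keep_logs keep per-replicate activity logs (needed for
#'   [schedule_stats()]).
#' @param verbose print a progress line per replicate.
#' @return A list of class `surf_replicates`: `mean`, `ci_lo`, `ci_hi`
#'   (sensors x 24), `per_replicate` (sensors x 24 x n array), `runs`
#'   (list of `surf_run` if `keep_logs`), `groups`, `config`.
#' @export
run_replicates <- function(town, population, params = default_params(),
                           config = run_config(), ci_level = 0.99,
                           n_boot = 1000, keep_logs = TRUE,
                           verbose = FALSE) {
  stopifnot(config$n_replicates >= 1)
  runs <- vector("list", config$n_replicates)
  for (i in seq_len(config$n_replicates)) {
    runs[[i]] <- run_simulation(town, population, params, config,
                                replicate_seed = config$seed + i)
    if (verbose) message("replicate ", i, "/", config$n_replicates, " done")
  }
  per <- simplify2array(lapply(runs, `[[`, "footfall"))
  agg <- aggregate_replicates(per, ci_level = ci_level, n_boot = n_boot,
                              boot_seed = config$seed)
  structure(c(agg, list(per_replicate = per,
                        runs = if (keep_logs) runs,
                        groups = population$agents$group,
                        config = config)),
            class = "surf_replicates")
}

#' Aggregate per-replicate footfall tables
#'
#' Mean across replicates per sensor-hour cell plus percentile bootstrap
#' confidence intervals (resampling replicates with replacement).
#'
#' @param per_replicate sensors x 24 x n_replicates array.
#' @param ci_level confidence level.
#' @param n_boot bootstrap resamples.
#' @param boot_seed seed for the bootstrap resampling.
#' @return List with `mean`, `ci_lo`, `ci_hi` matrices.
#' @export
aggregate_replicates <- function(per_replicate, ci_level = 0.99,
                                 n_boot = 1000, boot_seed = 1) {
  stopifnot(length(dim(per_replicate)) == 3)
  n <- dim(per_replicate)[3]
  mu <- apply(per_replicate, c(1, 2), mean)
  alpha <- (1 - ci_level) / 2
  flat <- matrix(per_replicate, ncol = n)       # cells x replicates
  boots <- with_seed(boot_seed, {
    idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), n_boot, n)
    apply(idx, 1, function(ii) rowMeans(flat[, ii, drop = FALSE]))
  })                                            # cells x n_boot
  qs <- apply(boots, 1, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  lo <- matrix(qs[1, ], nrow(mu), ncol(mu), dimnames = dimnames(mu))
  hi <- matrix(qs[2, ], nrow(mu), ncol(mu), dimnames = dimnames(mu))
  list(mean = mu, ci_lo = lo, ci_hi = hi)
}

#' @export
print.surf_replicates <- function(x, ...) {
  cat("surf replicate aggregate:", dim(x$per_replicate)[3], "replicates,",
      nrow(x$mean), "sensors\n")
  cat("pooled hourly curve:\n")
  print(round(pooled_hourly_curve(x), 1))
  invisible(x)
}
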