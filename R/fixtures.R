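# Synthetic demo inputs: a full runnable input set (town, commuting OD
# matrix, retired counts, parameters, and a pseudo-observed footfall
# series) generated with no external data.  The pseudo-observed series
# deliberately contains the footprint of a group absent from the model
# configuration -- a school pulse peaking mid-afternoon -- so the iterative
# diversification workflow (find residual, add group, residual shrinks)
# can be exercised end-to-end.

#' Demo fixture specification
#'
#' @param n_blocks,buildings_per_block,n_sensors town size (see
#'   [generate_synthetic_town()]).
#' @param n_commuters,n_retired group sizes.
#' @param seed master fixture seed.
#' @param school_pulse_hour hour of the injected un-modelled footfall
#'   component (children leaving school).
#' @param school_pulse_frac peak magnitude of the injection as a fraction
#'   of the reference run's maximum pooled hourly count; 0 disables it.
#' @param obs_noise Poisson-resample the observed counts.
#' @param obs_replicates replicates of the internal reference run behind
#'   the observed series.
#' @return A list of class `surf_fixture_spec`.
#' @export
fixture_spec <- function(n_blocks = 6, buildings_per_block = 8,
                         n_sensors = 8, n_commuters = 2000,
                         n_retired = 2000, seed = 42,
                         school_pulse_hour = 15, school_pulse_frac = 0.35,
                         obs_noise = TRUE, obs_replicates = 2) {
  stopifnot(n_commuters >= 0, n_retired >= 0, school_pulse_frac >= 0)
  structure(as.list(environment()), class = "surf_fixture_spec")
}

#' Synthetic demo town
#'
#' @param spec a [fixture_spec()].
#' @return A [surf_town()].
#' @export
demo_town <- function(spec = fixture_spec()) {
  generate_synthetic_town(spec$n_blocks, spec$buildings_per_block,
                          n_sensors = spec$n_sensors, seed = spec$seed)
}

#' Synthetic commuting OD matrix and retired counts
#'
#' Commuters are spread over random (home, work) zone pairs among zones
#' with the required buildings; retired people over zones with residential
#' buildings.  Totals match the fixture specification's group sizes
#' exactly.
#'
#' @param town a [surf_town()].
#' @param spec a [fixture_spec()].
#' @return List with `od` and `retired` data.frames.
#' @export
demo_demand <- function(town, spec = fixture_spec()) {
  b <- town$buildings
  res_zones <- sort(unique(b$zone_id[b$fun == "residential"]))
  off_zones <- sort(unique(b$zone_id[b$fun == "office"]))
  with_seed(spec$seed + 1, {
    od <- data.frame(home_zone = character(0), work_zone = character(0),
                     count = numeric(0))
    if (spec$n_commuters > 0) {
      od <- data.frame(
        home_zone = sample(res_zones, spec$n_commuters, replace = TRUE),
        work_zone = sample(off_zones, spec$n_commuters, replace = TRUE))
      od <- stats::aggregate(cbind(count = rep(1, nrow(od))) ~
                               home_zone + work_zone, od, sum)
    }
    retired <- data.frame(zone = character(0), count = numeric(0))
    if (spec$n_retired > 0) {
      rz <- sample(res_zones, spec$n_retired, replace = TRUE)
      retired <- data.frame(zone = names(table(rz)),
                            count = as.numeric(table(rz)))
    }
    list(od = validate_od(od, town), retired = retired)
  })
}

#' In-memory demo inputs
#'
#' Generates the full input set (town, demand tables, parameters,
#' population) without touching the filesystem.
#'
#' @param spec a [fixture_spec()].
#' @param params model parameters.
#' @return List `town`, `od`, `retired`, `params`, `population`.
#' @export
demo_inputs <- function(spec = fixture_spec(), params = default_params()) {
  town <- demo_town(spec)
  dem <- demo_demand(town, spec)
  pop <- synthesize_population(town, dem$od, dem$retired, params,
                               seed = spec$seed + 2)
  list(town = town, od = dem$od, retired = dem$retired, params = params,
       population = pop)
}

#' Write a complete runnable demo input set
#'
#' Writes town files, `od.csv`, `retired.csv`, `params.yaml` and a
#' pseudo-observed `obs.csv` into `dir`.  The observed series is the
#' footfall of an internal commuter+retired reference run plus the
#' injected school pulse plus (optionally) Poisson noise; everything is
#' deterministic given the fixture seed.
#'
#' @param dir output directory.
#' @param spec a [fixture_spec()].
#' @param params model parameters to ship alongside.
#' @param config run configuration of the internal reference run
#'   (defaults to `obs_replicates` replicates of a 14-day run).
#' @param verbose print progress.
#' @return Invisibly, a list with the written paths and the reference
#'   aggregate.
#' @export
make_demo_inputs <- function(dir, spec = fixture_spec(),
                             params = default_params(), config = NULL,
                             verbose = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inp <- demo_inputs(spec, params)
  save_town(inp$town, dir)
  write.csv(inp$od, file.path(dir, "od.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(inp$retired, file.path(dir, "retired.csv"), row.names = FALSE,
            quote = FALSE)
  write_params(params, file.path(dir, "params.yaml"))
  if (is.null(config))
    config <- run_config(n_replicates = spec$obs_replicates,
                         seed = spec$seed + 3)
  agg <- run_replicates(inp$town, inp$population, params, config,
                        keep_logs = FALSE, verbose = verbose)
  obs <- observed_from_reference(agg$mean, spec)
  write_footfall_csv(obs, file.path(dir, "obs.csv"))
  invisible(list(dir = dir, town = inp$town, population = inp$population,
                 reference = agg, observed = obs,
                 paths = file.path(dir, c("buildings.geojson", "nodes.csv",
                                          "edges.csv", "sensors.csv",
                                          "od.csv", "retired.csv",
                                          "params.yaml", "obs.csv"))))
}

#' Inject the un-modelled group and observation noise
#'
#' Adds a Gaussian-shaped hourly pulse (the school group) to a reference
#' footfall table, scaled per sensor by the sensor's share of total
#' footfall, then optionally Poisson-resamples each cell.
#'
#' @param reference sensors x 24 reference footfall matrix.
#' @param spec a [fixture_spec()].
#' @return sensors x 24 observed matrix.
#' @export
observed_from_reference <- function(reference, spec = fixture_spec()) {
  pulse <- school_pulse_shape(spec$school_pulse_hour) *
    spec$school_pulse_frac * max(pooled_hourly_curve(reference))
  share <- rowSums(reference)
  share <- if (sum(share) > 0) share / sum(share) else
    rep(1 / nrow(reference), nrow(reference))
  obs <- reference + outer(share * nrow(reference), pulse)
  if (spec$obs_noise)
    obs[] <- with_seed(spec$seed + 4, rpois(length(obs), lambda = obs))
  obs
}

# Unit-peak Gaussian bump over hours 0..23.
school_pulse_shape <- function(peak_hour, sd_hours = 1) {
  exp(-((0:23 - peak_hour)^2) / (2 * sd_hours^2))
}
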