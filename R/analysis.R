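# Analysis: schedule statistics against time-use-survey targets, pooled
# and per-sensor hourly footfall curves, Z-scores, smoothing, and
# simulated-vs-observed comparison.

#' Schedule statistics from activity logs
#'
#' Episodes are maximal runs of one activity in an agent's final-day log;
#' travel steps are excluded (they carry code 0 and break runs).  Per
#' (group, activity): the participation rate (% of agents with at least
#' one episode on the reported day, averaged over replicates), episode
#' duration mean and median in minutes (pooled over replicates), episode
#' count, and start/end-hour histograms.
#'
#' @param x a `surf_replicates`, a single `surf_run`, or a list of
#'   `surf_run`.
#' @param step_minutes log resolution (minutes per step).
#' @return A data.frame of class `surf_schedule_stats` with one row per
#'   (group, activity); start/end histograms are in
#'   `attr(, "start_hist")` / `attr(, "end_hist")` (24-counters keyed
#'   `group.activity`).
#' @export
schedule_stats <- function(x, step_minutes = 5) {
  runs <- if (inherits(x, "surf_replicates")) x$runs
          else if (inherits(x, "surf_run")) list(x)
          else x
  if (is.null(runs) || !length(runs))
    stop("no activity logs available (was keep_logs = FALSE?)")
  if (any(vapply(runs, function(r) nrow(r$log) == 0, logical(1))))
    stop("empty activity log")
  groups <- runs[[1]]$groups
  spd <- ncol(runs[[1]]$log)

  # one rle per replicate over the row-concatenated log with -1 separators
  # between agents, so runs never span agents
  episodes <- do.call(rbind, lapply(seq_along(runs), function(r) {
    lg <- runs[[r]]$log
    v <- as.vector(t(cbind(lg, -1L)))
    rl <- rle(v)
    start_idx <- cumsum(c(1L, rl$lengths[-length(rl$lengths)]))
    keep <- rl$values > 0
    agent <- (start_idx[keep] - 1L) %/% (spd + 1L) + 1L
    s0 <- (start_idx[keep] - 1L) %% (spd + 1L)         # 0-based step of day
    len <- rl$lengths[keep]
    data.frame(replicate = r, agent = agent, group = groups[agent],
               activity = ACTIVITIES[rl$values[keep]],
               start_hour = (s0 * step_minutes) %/% 60,
               end_hour = ((s0 + len - 1L) * step_minutes) %/% 60,
               duration = len * step_minutes)
  }))
  episodes$key <- paste(episodes$group, episodes$activity, sep = ".")
  keys <- sort(unique(episodes$key))
  n_group <- table(groups)
  hist_start <- list(); hist_end <- list()
  rows <- lapply(keys, function(key) {
    ep <- episodes[episodes$key == key, ]
    gp <- ep$group[1]; ac <- ep$activity[1]
    hist_start[[key]] <<- tabulate(ep$start_hour + 1L, 24)
    hist_end[[key]] <<- tabulate(ep$end_hour + 1L, 24)
    # participation: mean over replicates of the % of group agents with
    # at least one episode on the reported day
    per_rep <- vapply(seq_along(runs), function(r)
      length(unique(ep$agent[ep$replicate == r])), integer(1))
    part <- mean(per_rep / n_group[[gp]]) * 100
    data.frame(group = gp, activity = ac, participation = part,
               mean_duration = mean(ep$duration),
               median_duration = median(ep$duration),
               n_episodes = nrow(ep))
  })
  out <- do.call(rbind, rows)
  attr(out, "start_hist") <- hist_start
  attr(out, "end_hist") <- hist_end
  class(out) <- c("surf_schedule_stats", "data.frame")
  out
}

#' Packaged time-use-survey calibration targets
#'
#' The participation and duration statistics for away-from-home activities
#' of commuters and retired people used to calibrate the model, with their
#' tolerances (`pp` = absolute percentage points, `rel` = relative
#' fraction, `abs_min` = absolute minutes).
#'
#' @return data.frame with columns `group`, `activity`, `metric`, `value`,
#'   `tolerance`, `tolerance_type`.
#' @export
uktus_targets <- function() {
  read.csv(system.file("extdata", "uktus_targets.csv", package = "surf"),
           stringsAsFactors = FALSE)
}

#' Evaluate schedule statistics against calibration targets
#'
#' @param stats a [schedule_stats()] result.
#' @param targets a target table, by default [uktus_targets()].
#' @return data.frame with simulated and target values, absolute and
#'   relative deviations, and a pass flag per target.
#' @export
evaluate_targets <- function(stats, targets = uktus_targets()) {
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    t <- targets[i, ]
    row <- stats[stats$group == t$group & stats$activity == t$activity, ]
    if (nrow(row) == 0)
      stop("no simulated statistics for (", t$group, ", ", t$activity, ")")
    sim <- switch(t$metric,
                  participation = row$participation,
                  mean_duration = row$mean_duration,
                  median_duration = row$median_duration,
                  stop("unknown metric ", sQuote(t$metric)))
    dev <- sim - t$value
    pass <- switch(t$tolerance_type,
                   pp = abs(dev) <= t$tolerance,
                   rel = abs(dev) <= t$tolerance * t$value,
                   abs_min = abs(dev) <= t$tolerance)
    data.frame(t, simulated = sim, abs_dev = abs(dev),
               rel_dev = abs(dev) / t$value, pass = pass)
  })
  do.call(rbind, rows)
}

#' Pooled hourly footfall curve
#'
#' The mean footfall across all sensors at each hour (of replicate-mean
#' counts when given an aggregate).
#'
#' @param x a `surf_replicates` aggregate, a `surf_run`, or a sensors x 24
#'   matrix.
#' @return Numeric 24-vector.
#' @export
pooled_hourly_curve <- function(x) {
  m <- if (inherits(x, "surf_replicates")) x$mean
       else if (inherits(x, "surf_run")) x$footfall
       else x
  stopifnot(ncol(m) == 24)
  setNames(colMeans(m), sprintf("h%02d", 0:23))
}

#' Z-score standardisation
#'
#' `(x - mean(x)) / sd(x)` with the population (divide-by-n) standard
#' deviation, so simulated and observed curves share a scale.
#'
#' @param series numeric vector with positive spread.
#' @return Standardised vector (mean 0, sd 1).
#' @export
zscore <- function(series) {
  s <- sqrt(mean((series - mean(series))^2))
  if (s == 0) stop("Z-score undefined for a constant series")
  (series - mean(series)) / s
}

#' Smooth an hourly curve
#'
#' Locally-weighted linear (loess) smoothing for presentation; constants
#' and straight lines are reproduced exactly.  Smoothed curves never feed
#' quantitative comparisons.
#'
#' @param series numeric vector (typically 24 hourly values).
#' @param bandwidth window half-width in points (> 0).
#' @return Smoothed vector of the same length.
#' @export
smooth_curve <- function(series, bandwidth = 4) {
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  n <- length(series)
  x <- seq_len(n)
  span <- min(1, max(3, 2 * bandwidth + 1) / n)
  fit <- loess(series ~ x, span = span, degree = 1,
               family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  as.numeric(predict(fit, x))
}

#' Compare a simulated and an observed hourly curve
#'
#' Both curves are Z-scored; the residual is `observed - simulated` on the
#' Z scale; RMSE and the Pearson correlation summarise agreement.
#'
#' @param sim_curve,obs_curve numeric vectors of equal length,
#'   non-constant.
#' @return A list of class `surf_comparison`: `sim_z`, `obs_z`,
#'   `residual`, `rmse`, `pearson_r`.
#' @export
compare_curves <- function(sim_curve, obs_curve) {
  if (length(sim_curve) != length(obs_curve))
    stop("curve length mismatch: ", length(sim_curve), " vs ",
         length(obs_curve))
  sz <- zscore(sim_curve); oz <- zscore(obs_curve)
  res <- oz - sz
  structure(list(sim_z = sz, obs_z = oz, residual = res,
                 rmse = sqrt(mean(res^2)),
                 pearson_r = stats::cor(sim_curve, obs_curve)),
            class = "surf_comparison")
}

#' Compare simulated and observed footfall tables
#'
#' Pooled comparison of the mean-across-sensors hourly curves, or a
#' per-sensor list of comparisons.
#'
#' @param sim a `surf_replicates` aggregate (or sensors x 24 matrix).
#' @param obs an observed sensors x 24 matrix (see
#'   [read_footfall_csv()]).
#' @param per_sensor compare each sensor separately.
#' @return A `surf_comparison`, or a named list of them.
#' @export
compare_footfall <- function(sim, obs, per_sensor = FALSE) {
  sm <- if (inherits(sim, "surf_replicates")) sim$mean else sim
  if (per_sensor) {
    ids <- intersect(rownames(sm), rownames(obs))
    out <- lapply(ids, function(id) compare_curves(sm[id, ], obs[id, ]))
    names(out) <- ids
    return(out)
  }
  compare_curves(pooled_hourly_curve(sm), pooled_hourly_curve(obs))
}

#' @export
print.surf_comparison <- function(x, ...) {
  cat("simulated vs observed hourly curves: RMSE(Z) =",
      round(x$rmse, 3), ", Pearson r =", round(x$pearson_r, 3), "\n")
  worst <- which.max(abs(x$residual))
  cat("largest residual at hour", worst - 1, "(",
      round(x$residual[worst], 2), "on the Z scale )\n")
  invisible(x)
}
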