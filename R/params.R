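# Activity-intensity parameterisation.
#
# Each (group, activity) pair has linear background-intensity dynamics --
# the background grows by grow_rate per 5-min step while the activity is
# not being performed and shrinks by decay_rate per step (clipped at zero)
# while it is -- plus a rectangular time-intensity profile: `amplitude`
# inside [window_start, window_end) minutes-of-day (shifted per agent and
# jittered per day), zero outside.  The total intensity is their sum and
# the highest total wins, subject to a minimal-duration lock.
#
# Intensity units are anchored by the at-home amplitude of 1: every other
# amplitude is pitched against the competitor the activity has to displace
# (the home floor for evening/weekend-style activities, the office for the
# lunch break), so switching thresholds are amplitude differences.

#' Default model parameters
#'
#' Returns the shipped parameterisation of the intensity model, calibrated
#' so that the final-day schedule statistics of a synthetic-town run match
#' the UK Time Use Survey statistics used as calibration targets
#' (participation rates, episode durations, office hours).
#'
#' Structure: `$global` (heterogeneity scales, step length, walking speed),
#' `$allocation` (search-radius policy) and `$activities$<group>$<activity>`
#' with `grow_rate`, `decay_rate` (intensity units per step), `amplitude`,
#' `window_start`, `window_end` (minutes of day; `start > end` wraps
#' midnight), `min_duration_min` and `init_max` (upper bound of the uniform
#' background initialisation).
#'
#' @return A nested parameter list of class `surf_params`.
#' @export
default_params <- function() {
  act <- function(grow, decay, amplitude, ws, we, min_dur, init_max = 0)
    list(grow_rate = grow, decay_rate = decay, amplitude = amplitude,
         window_start = ws, window_end = we, min_duration_min = min_dur,
         init_max = init_max)
  h <- function(hh, mm = 0) hh * 60 + mm

  p <- list(
    global = list(
      sigma_rate = 0.2,          # lognormal sd of grow-rate multipliers
      sigma_duration = 0.9,      # lognormal sd of min-duration multipliers
      duration_mult_range = c(0.25, 4.5),
      window_offset_min = 30,    # per-agent uniform window shift (+/-)
      daily_jitter_min = 10,     # per-day uniform window jitter (+/-)
      walking_speed_mps = 1.4,
      step_minutes = 5
    ),
    allocation = list(initial_radius_m = 500, max_doublings = 6),
    activities = list(
      commuter = list(
        at_home = act(0.0005, 0.01, 1.0, h(0), h(24), 30),
        work = act(0.00005, 0.05, 2.0, h(7, 45), h(16, 15), 60),
        shop_food = act(2.42e-4, 0.20, 0.75, h(11, 30), h(19, 30), 27,
                        init_max = 0.26),
        lunch_out = act(4.0e-5, 0.20, 1.75, h(12), h(14), 30,
                        init_max = 0.25),
        evening_social = act(9.8e-5, 0.15, 0.65, h(18, 30), h(22, 30), 60,
                             init_max = 0.35),
        sports = act(1.85e-4, 0.15, 0.70, h(17), h(21, 30), 60,
                     init_max = 0.31)
      ),
      retired = list(
        at_home = act(0.0005, 0.01, 1.0, h(0), h(24), 30),
        shop_food = act(4.45e-4, 0.20, 0.75, h(9), h(16, 30), 45,
                        init_max = 0.25),
        shop_leisure = act(1.75e-4, 0.15, 0.70, h(9, 30), h(16), 60,
                           init_max = 0.30),
        lunch_out = act(1.01e-4, 0.20, 0.65, h(12), h(14), 30,
                        init_max = 0.35),
        evening_social = act(1.0e-4, 0.15, 0.65, h(18, 30), h(22, 30), 60,
                             init_max = 0.35),
        sports = act(1.85e-4, 0.15, 0.70, h(14), h(19), 60,
                     init_max = 0.30)
      )
    )
  )
  structure(p, class = "surf_params")
}

#' Read or write a parameter file
#'
#' Parameters are stored as YAML with the same nesting as
#' [default_params()].
#'
#' @param path file path.
#' @param params a `surf_params` list.
#' @return `read_params` returns a validated `surf_params`;
#'   `write_params` returns `path` invisibly.
#' @export
read_params <- function(path) {
  p <- yaml::read_yaml(path)
  class(p) <- "surf_params"
  validate_params(p)
  p
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "surf_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' Validate a parameter list
#'
#' Checks the structural invariants of the intensity model: decay faster
#' than growth (`decay_rate > grow_rate >= 0`), non-negative amplitudes,
#' minimal durations of at least one step, and windows within a day.
#'
#' @param params a `surf_params` list.
#' @return `params`, invisibly; errors describe the offending entry.
#' @export
validate_params <- function(params) {
  g <- params$global
  stopifnot(g$sigma_rate >= 0, g$sigma_duration >= 0,
            g$step_minutes >= 1, 60 %% g$step_minutes == 0,
            g$walking_speed_mps > 0)
  stopifnot(params$allocation$initial_radius_m > 0,
            params$allocation$max_doublings >= 0)
  for (grp in names(params$activities)) {
    if (!grp %in% GROUPS) stop("unknown group ", sQuote(grp))
    acts <- params$activities[[grp]]
    bad <- setdiff(names(acts), GROUP_ACTIVITIES[[grp]])
    if (length(bad))
      stop("activity ", sQuote(bad[1]), " is not applicable to group ",
           sQuote(grp))
    for (a in names(acts)) {
      x <- acts[[a]]
      if (!(x$decay_rate > x$grow_rate && x$grow_rate >= 0))
        stop(grp, "/", a, ": requires decay_rate > grow_rate >= 0")
      if (x$amplitude < 0) stop(grp, "/", a, ": amplitude must be >= 0")
      if (x$min_duration_min < g$step_minutes)
        stop(grp, "/", a, ": min_duration_min below one step")
      if (x$window_start < 0 || x$window_start >= 1440 ||
          x$window_end < 0 || x$window_end > 1440)
        stop(grp, "/", a, ": window outside [00:00, 24:00]")
    }
  }
  invisible(params)
}

# Convert nested activity parameters into the group x activity matrices the
# compiled engine consumes.
params_to_engine <- function(params) {
  m <- function() matrix(0, 2, 7, dimnames = list(GROUPS, ACTIVITIES))
  grow <- m(); decay <- m(); amp <- m(); ws <- m(); we <- m(); init <- m()
  mind <- m()
  active <- matrix(0L, 2, 7, dimnames = list(GROUPS, ACTIVITIES))
  step <- params$global$step_minutes
  for (grp in names(params$activities)) {
    for (a in names(params$activities[[grp]])) {
      x <- params$activities[[grp]][[a]]
      grow[grp, a] <- x$grow_rate
      decay[grp, a] <- x$decay_rate
      amp[grp, a] <- x$amplitude
      ws[grp, a] <- x$window_start
      we[grp, a] <- x$window_end
      init[grp, a] <- if (is.null(x$init_max)) 0 else x$init_max
      mind[grp, a] <- x$min_duration_min / step   # fractional steps
      active[grp, a] <- 1L
    }
  }
  list(grow = grow, decay = decay, amplitude = amp, window_start = ws,
       window_end = we, init_max = init, min_dur_steps = mind,
       active = active)
}
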