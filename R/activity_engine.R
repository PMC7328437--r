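# Behavioural core at the single-agent level.  These functions define the
# reference semantics of the intensity dynamics; the compiled engine applies
# the same rules to whole populations.

#' Time intensity of an activity
#'
#' The time-of-day motivation component: `amplitude` inside the activity's
#' window (shifted by the agent's offset, wrapping at midnight), zero
#' outside.
#'
#' @param params a `surf_params` list.
#' @param group `"commuter"` or `"retired"`.
#' @param activity activity name.
#' @param time_of_day minutes since midnight, in `[0, 1440)`; vectorised.
#' @param agent_offset window shift in minutes (per-agent offset plus any
#'   daily jitter).
#' @return Numeric intensity (vector).
#' @export
time_intensity <- function(params, group, activity, time_of_day,
                           agent_offset = 0) {
  x <- params$activities[[group]][[activity]]
  if (is.null(x)) stop("activity ", sQuote(activity),
                       " not configured for group ", sQuote(group))
  stopifnot(all(time_of_day >= 0), all(time_of_day < 1440))
  tt <- (time_of_day - agent_offset) %% 1440
  inw <- if (x$window_start == x$window_end) rep(FALSE, length(tt))
         else if (x$window_start < x$window_end)
           tt >= x$window_start & tt < x$window_end
         else tt >= x$window_start | tt < x$window_end
  ifelse(inw, x$amplitude, 0)
}

#' Create a single-agent behavioural state
#'
#' @param group agent group.
#' @param params model parameters (defines the applicable activities).
#' @param current_activity starting activity.
#' @param background named starting background intensities (default all 0).
#' @param rate_mult named grow-rate multipliers (default all 1).
#' @param dur_mult named minimal-duration multipliers (default all 1).
#' @param offset_min window offset in minutes.
#' @return A list of class `surf_agent_state`.
#' @export
agent_state <- function(group, params, current_activity = "at_home",
                        background = NULL, rate_mult = NULL, dur_mult = NULL,
                        offset_min = 0) {
  acts <- names(params$activities[[group]])
  if (is.null(acts)) stop("group ", sQuote(group), " not configured")
  bg <- setNames(numeric(length(acts)), acts)
  if (!is.null(background)) bg[names(background)] <- background
  rm_ <- setNames(rep(1, length(acts)), acts)
  if (!is.null(rate_mult)) rm_[names(rate_mult)] <- rate_mult
  dm <- setNames(rep(1, length(acts)), acts)
  if (!is.null(dur_mult)) dm[names(dur_mult)] <- dur_mult
  stopifnot(current_activity %in% acts, all(bg >= 0), all(rm_ > 0))
  structure(list(group = group, current_activity = current_activity,
                 elapsed = 0L, background = bg, rate_mult = rm_,
                 dur_mult = dm, offset_min = offset_min,
                 travelling = FALSE),
            class = "surf_agent_state")
}

#' Update background intensities by one or more steps
#'
#' Linear dynamics: the activity currently performed decays by
#' `decay_rate` per step (clipped at zero); every other applicable
#' activity grows by `grow_rate` times the agent's rate multiplier.  A
#' travelling agent performs nothing, so all activities grow.
#'
#' @param state a [agent_state()].
#' @param params model parameters.
#' @param dt_steps number of steps to apply.
#' @return The new background vector (named).
#' @export
update_background <- function(state, params, dt_steps = 1) {
  acts <- params$activities[[state$group]]
  bg <- state$background
  for (s in seq_len(dt_steps)) {
    for (a in names(bg)) {
      if (!state$travelling && a == state$current_activity) {
        bg[a] <- max(0, bg[a] - acts[[a]]$decay_rate)
      } else {
        bg[a] <- bg[a] + acts[[a]]$grow_rate * state$rate_mult[a]
      }
    }
  }
  bg
}

#' Total intensities at a time of day
#'
#' Background plus time intensity for every activity applicable to the
#' agent's group.
#'
#' @inheritParams update_background
#' @param time_of_day minutes since midnight.
#' @param jitter_min optional named per-activity window jitter (minutes).
#' @return Named numeric vector of total intensities.
#' @export
total_intensity <- function(state, params, time_of_day, jitter_min = NULL) {
  acts <- names(params$activities[[state$group]])
  jit <- setNames(numeric(length(acts)), acts)
  if (!is.null(jitter_min)) jit[names(jitter_min)] <- jitter_min
  ti <- vapply(acts, function(a)
    time_intensity(params, state$group, a, time_of_day,
                   state$offset_min + jit[a]), numeric(1))
  state$background[acts] + ti
}

#' Choose the next activity
#'
#' The activity with the highest total intensity drives behaviour, subject
#' to the minimal-duration lock on the current activity.  An exact tie
#' involving the current activity keeps it; a tie among other activities is
#' broken by the canonical activity order.
#'
#' @param state a [agent_state()].
#' @param totals named total intensities (from [total_intensity()]).
#' @param params model parameters.
#' @return The name of the chosen activity.
#' @export
choose_activity <- function(state, totals, params) {
  if (state$travelling) stop("travelling agents do not re-decide")
  if (length(totals) == 0) stop("no applicable activities (misconfigured group)")
  x <- params$activities[[state$group]][[state$current_activity]]
  min_dur <- agent_min_dur_steps(x$min_duration_min,
                                 state$dur_mult[state$current_activity],
                                 params$global$step_minutes)
  if (state$elapsed < min_dur) return(state$current_activity)
  ord <- intersect(ACTIVITIES, names(totals))   # canonical order
  totals <- totals[ord]
  best <- max(totals)
  if (totals[state$current_activity] >= best) return(state$current_activity)
  ord[which(totals == best)[1]]
}

# Agent-specific minimal duration in steps (>= 1).
agent_min_dur_steps <- function(min_duration_min, dur_mult, step_minutes) {
  max(1L, as.integer(ceiling(min_duration_min * dur_mult / step_minutes - 1e-9)))
}

#' Simulate one agent's activity schedule without space
#'
#' Runs the behavioural core for a single agent with teleport travel (the
#' spatial side disabled): per step, background intensities are updated,
#' then the activity choice rule is applied.  With zero heterogeneity and
#' jitter the trace is deterministic.
#'
#' @param params model parameters.
#' @param agent a [agent_state()] defining group, multipliers and offset.
#' @param n_days days to simulate.
#' @param daily_jitter_min per-day uniform window jitter (+/- minutes);
#'   0 disables the only stochastic element.
#' @param seed optional seed for the jitter draws.
#' @return A character matrix `n_days x steps_per_day` of activity names.
#' @export
simulate_single_agent <- function(params, agent, n_days,
                                  daily_jitter_min = 0, seed = NULL) {
  run <- function() {
    step <- params$global$step_minutes
    spd <- 1440 %/% step
    acts <- params$activities[[agent$group]]
    state <- agent
    state$elapsed <- agent_min_dur_steps(
      acts[[state$current_activity]]$min_duration_min,
      state$dur_mult[state$current_activity], step)
    out <- matrix(NA_character_, n_days, spd)
    jit <- setNames(numeric(length(acts)), names(acts))
    for (d in seq_len(n_days)) {
      if (daily_jitter_min > 0)
        jit[] <- runif(length(acts), -daily_jitter_min, daily_jitter_min)
      for (s in seq_len(spd)) {
        tod <- (s - 1) * step
        state$background <- update_background(state, params)
        state$elapsed <- state$elapsed + 1L
        chosen <- choose_activity(state, total_intensity(state, params, tod,
                                                         jit), params)
        if (!identical(chosen, state$current_activity)) {
          state$current_activity <- chosen
          state$elapsed <- 0L
        }
        out[d, s] <- state$current_activity
      }
    }
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
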