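# Agent population synthesis from census-style tables: one commuter agent
# per origin-destination unit and one retired agent per person in the
# per-zone retired counts, with anchor buildings sampled inside zones.

#' Load a commuting origin-destination matrix
#'
#' Reads a CSV with columns `home_zone,work_zone,count`, sums duplicate
#' zone pairs, and validates the zone ids against the town.
#'
#' @param path CSV path.
#' @param town a [surf_town()].
#' @return data.frame of class `surf_od` with one row per zone pair.
#' @export
load_od_matrix <- function(path, town) {
  od <- read.csv(path, colClasses = c("character", "character", "numeric"))
  names(od) <- c("home_zone", "work_zone", "count")
  validate_od(od, town)
}

validate_od <- function(od, town) {
  if (nrow(od)) {
    unknown <- setdiff(c(od$home_zone, od$work_zone), town$zones)
    if (length(unknown))
      stop("OD matrix references unknown zone ", sQuote(unknown[1]))
    if (any(od$count < 0)) stop("OD counts must be >= 0")
    if (any(od$count != round(od$count))) stop("OD counts must be integers")
    od <- stats::aggregate(count ~ home_zone + work_zone, od, sum)
  }
  structure(od, class = c("surf_od", "data.frame"))
}

#' Load per-zone retired-population counts
#'
#' @param path CSV path with columns `zone,count`.
#' @param town a [surf_town()].
#' @return data.frame with one row per zone.
#' @export
load_retired_counts <- function(path, town) {
  rc <- read.csv(path, colClasses = c("character", "numeric"))
  names(rc) <- c("zone", "count")
  unknown <- setdiff(rc$zone, town$zones)
  if (length(unknown))
    stop("retired counts reference unknown zone ", sQuote(unknown[1]))
  if (any(rc$count < 0) || any(rc$count != round(rc$count)))
    stop("retired counts must be non-negative integers")
  stats::aggregate(count ~ zone, rc, sum)
}

#' Synthesize the agent population
#'
#' Creates one commuter agent per unit of the OD matrix (home sampled
#' uniformly among the residential buildings of the home zone, workplace
#' uniformly among the offices of the work zone) and one retired agent per
#' unit of the retired counts.  Heterogeneity is drawn per agent: a
#' lognormal multiplier on each activity's background grow rate
#' (`sigma_rate`), a lognormal multiplier on each activity's minimal
#' duration (`sigma_duration`, truncated to `duration_mult_range`), and a
#' uniform offset applied to all of the agent's time windows
#' (`window_offset_min`).
#'
#' @param town a [surf_town()].
#' @param od a [load_od_matrix()] result (or equivalent data.frame).
#' @param retired_counts a [load_retired_counts()] result.
#' @param params model parameters; heterogeneity scales come from
#'   `params$global`.
#' @param seed integer seed; the population is deterministic given it.
#' @param scale optional sampling fraction in (0, 1]; person-units are
#'   independently kept with this probability for desk-scale runs.
#' @return An object of class `surf_population`: `$agents` (one row per
#'   agent: `id`, `group`, `home_building`, `work_building`, `offset_min`)
#'   plus the heterogeneity matrices `$rate_mult` and `$dur_mult`
#'   (agent x activity).
#' @export
synthesize_population <- function(town, od, retired_counts,
                                  params = default_params(), seed = 1,
                                  scale = 1) {
  stopifnot(inherits(town, "surf_town"), scale > 0, scale <= 1)
  b <- town$buildings
  res_by_zone <- split(seq_len(nrow(b))[b$fun == "residential"],
                       b$zone_id[b$fun == "residential"])
  off_by_zone <- split(seq_len(nrow(b))[b$fun == "office"],
                       b$zone_id[b$fun == "office"])
  pick <- function(pool, zone, n, what) {
    idx <- pool[[zone]]
    if (is.null(idx))
      stop("zone ", sQuote(zone), " has demand but no ", what, " building")
    idx[sample.int(length(idx), n, replace = TRUE)]
  }

  with_seed(seed, {
    home <- integer(0); work <- integer(0); group <- character(0)
    if (!is.null(od) && nrow(od)) {
      for (r in seq_len(nrow(od))) {
        n <- od$count[r]
        if (scale < 1) n <- sum(runif(n) < scale)
        if (n == 0) next
        home <- c(home, pick(res_by_zone, od$home_zone[r], n, "residential"))
        work <- c(work, pick(off_by_zone, od$work_zone[r], n, "office"))
        group <- c(group, rep("commuter", n))
      }
    }
    if (!is.null(retired_counts) && nrow(retired_counts)) {
      for (r in seq_len(nrow(retired_counts))) {
        n <- retired_counts$count[r]
        if (scale < 1) n <- sum(runif(n) < scale)
        if (n == 0) next
        home <- c(home, pick(res_by_zone, retired_counts$zone[r], n,
                             "residential"))
        work <- c(work, rep(NA_integer_, n))
        group <- c(group, rep("retired", n))
      }
    }
    n <- length(home)
    g <- params$global
    rng <- g$duration_mult_range
    rate_mult <- matrix(exp(rnorm(n * 7, 0, g$sigma_rate)), n, 7,
                        dimnames = list(NULL, ACTIVITIES))
    dur_mult <- matrix(exp(rnorm(n * 7, 0, g$sigma_duration)), n, 7,
                       dimnames = list(NULL, ACTIVITIES))
    dur_mult[] <- pmin(pmax(dur_mult, rng[1]), rng[2])
    dur_mult[, "at_home"] <- 1     # anchoring activities keep fixed floors
    dur_mult[, "work"] <- 1
    agents <- data.frame(
      id = seq_len(n), group = group,
      home_building = b$id[home],
      work_building = ifelse(is.na(work), NA_character_, b$id[work]),
      offset_min = runif(n, -g$window_offset_min, g$window_offset_min))
    structure(list(agents = agents, rate_mult = rate_mult,
                   dur_mult = dur_mult), class = "surf_population")
  })
}

#' @export
print.surf_population <- function(x, ...) {
  cat("surf population:", nrow(x$agents), "agents (",
      sum(x$agents$group == "commuter"), "commuters,",
      sum(x$agents$group == "retired"), "retired )\n")
  invisible(x)
}

#' Subset a population by group
#'
#' @param population a [synthesize_population()] result.
#' @param groups groups to keep.
#' @return A `surf_population` containing only those agents.
#' @export
filter_population <- function(population, groups) {
  keep <- population$agents$group %in% groups
  structure(list(agents = population$agents[keep, , drop = FALSE],
                 rate_mult = population$rate_mult[keep, , drop = FALSE],
                 dur_mult = population$dur_mult[keep, , drop = FALSE]),
            class = "surf_population")
}

# Flatten population to the structures the engine consumes.
population_to_engine <- function(population, town) {
  a <- population$agents
  hb <- match(a$home_building, town$buildings$id)
  wb <- match(a$work_building, town$buildings$id)
  if (anyNA(hb)) stop("population references unknown home building")
  list(group = match(a$group, GROUPS),
       home_building = hb,
       work_building = ifelse(is.na(wb), 0L, wb),
       offset_min = a$offset_min,
       rate_mult = unname(population$rate_mult),
       dur_mult = unname(population$dur_mult))
}
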