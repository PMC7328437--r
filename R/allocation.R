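# Spatial allocation of flexible activities: a uniform random building with
# the required function within a search radius of the previous activity,
# with the radius iteratively doubled until candidates are found.

#' Allocation policy
#'
#' @param initial_radius_m starting search radius (metres).
#' @param max_doublings maximum number of radius doublings.
#' @return A list of class `surf_allocation_policy`.
#' @export
allocation_policy <- function(initial_radius_m = 500, max_doublings = 6) {
  stopifnot(initial_radius_m > 0, max_doublings >= 0)
  structure(list(initial_radius_m = initial_radius_m,
                 max_doublings = max_doublings),
            class = "surf_allocation_policy")
}

#' Allocate a building for a flexible activity
#'
#' Candidates are the buildings carrying the activity's required function
#' whose Euclidean distance to `from_point` is at most
#' `r0 * 2^k`, for the smallest `k <= max_doublings` that yields a
#' non-empty set; one candidate is chosen uniformly at random.  Anchored
#' activities (`at_home`, `work`) bypass the search and return `anchor`.
#'
#' @param town a [surf_town()].
#' @param activity activity name.
#' @param from_point numeric `c(x, y)`: the location of the previous
#'   activity.
#' @param policy an [allocation_policy()].
#' @param anchor building id returned for anchored activities.
#' @return One row of `town$buildings`.
#' @export
allocate_location <- function(town, activity, from_point,
                              policy = allocation_policy(), anchor = NULL) {
  stopifnot(activity %in% ACTIVITIES)
  fun <- REQUIRED_FUNCTION[[activity]]
  if (is.na(fun)) {
    if (is.null(anchor)) stop("activity ", sQuote(activity),
                              " is anchored; supply the agent's anchor")
    return(town$buildings[town$buildings$id == anchor, ])
  }
  cand <- town$buildings[town$buildings$fun == fun, , drop = FALSE]
  d <- sqrt((cand$x - from_point[1])^2 + (cand$y - from_point[2])^2)
  r <- policy$initial_radius_m
  for (k in 0:policy$max_doublings) {
    hit <- which(d <= r)
    if (length(hit)) {
      return(cand[hit[sample.int(length(hit), 1)], ])
    }
    r <- r * 2
  }
  stop("no building with function ", sQuote(fun), " within ",
       policy$initial_radius_m * 2^policy$max_doublings, " m")
}
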