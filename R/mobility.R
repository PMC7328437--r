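# Routing and movement: A* shortest paths on the street network and
# constant-speed advancement in discrete steps.

#' Shortest path between two network nodes
#'
#' A* search with the Euclidean distance as heuristic (admissible because
#' every edge is at least as long as the straight line between its
#' endpoints).  Returns a route object that [advance()] can move along.
#'
#' @param town a [surf_town()] (or a list with `$nodes` and `$edges`).
#' @param origin_node,dest_node node ids.
#' @return A list of class `surf_route`: `nodes` (id sequence), `coords`
#'   (matrix), `seg_lengths`, `total_m`, `traversed_m` (0), and `expanded`
#'   (A* node expansions, for diagnostics).
#' @export
shortest_path <- function(town, origin_node, dest_node) {
  nodes <- town$nodes; edges <- town$edges
  oi <- match(origin_node, nodes$id)
  di <- match(dest_node, nodes$id)
  if (is.na(oi) || is.na(di)) stop("unknown node id")
  if (oi == di) {
    return(structure(list(nodes = origin_node,
                          coords = cbind(nodes$x[oi], nodes$y[oi]),
                          seg_lengths = numeric(0), total_m = 0,
                          traversed_m = 0, expanded = 0L),
                     class = "surf_route"))
  }
  res <- astar_cpp(nodes$x, nodes$y,
                   match(edges$u, nodes$id), match(edges$v, nodes$id),
                   edges$length_m, oi, di)
  idx <- res$path
  seg <- sqrt(diff(nodes$x[idx])^2 + diff(nodes$y[idx])^2)
  # use true edge lengths, not chord lengths
  key <- paste(pmin(edges$u, edges$v), pmax(edges$u, edges$v))
  elen <- setNames(edges$length_m, key)
  ids <- nodes$id[idx]
  seg <- unname(elen[paste(pmin(ids[-length(ids)], ids[-1]),
                           pmax(ids[-length(ids)], ids[-1]))])
  structure(list(nodes = ids,
                 coords = cbind(nodes$x[idx], nodes$y[idx]),
                 seg_lengths = seg, total_m = res$cost, traversed_m = 0,
                 expanded = res$expanded),
            class = "surf_route")
}

#' Advance along a route at constant speed
#'
#' Moves `speed_m_per_s * dt_s` metres along the route, capped at its total
#' length; the position is interpolated along the current edge.
#'
#' @param route a [shortest_path()] result.
#' @param speed_m_per_s walking speed.
#' @param dt_s step duration in seconds.
#' @return A list: `route` (with updated `traversed_m`), `position`
#'   (`c(x, y)`), and `arrived` (logical).
#' @export
advance <- function(route, speed_m_per_s, dt_s) {
  stopifnot(inherits(route, "surf_route"))
  if (route$traversed_m >= route$total_m && route$total_m > 0)
    stop("route already complete")
  route$traversed_m <- min(route$total_m,
                           route$traversed_m + speed_m_per_s * dt_s)
  list(route = route, position = route_position(route),
       arrived = route$traversed_m >= route$total_m)
}

# Interpolated coordinates at the current traversed distance.
route_position <- function(route) {
  if (route$total_m == 0 || length(route$seg_lengths) == 0)
    return(route$coords[1, ])
  cum <- cumsum(route$seg_lengths)
  i <- which(route$traversed_m <= cum + 1e-9)[1]
  if (is.na(i)) return(route$coords[nrow(route$coords), ])
  start <- if (i == 1) 0 else cum[i - 1]
  f <- (route$traversed_m - start) / route$seg_lengths[i]
  route$coords[i, ] + f * (route$coords[i + 1, ] - route$coords[i, ])
}
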