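# The spatial world: street network, function-tagged buildings, zones and
# footfall sensors.  Coordinates are planar metres throughout; projection is
# an input concern.

#' Construct and validate a town
#'
#' A `surf_town` bundles the immutable spatial world of a simulation: a
#' connected street network, buildings with exactly one function tag each,
#' statistical zones, and footfall sensors.  Buildings and sensors are
#' snapped to their nearest network node; all travel happens on the network.
#'
#' @param nodes data.frame with columns `id`, `x`, `y` (metres).
#' @param edges data.frame with columns `u`, `v` (node ids) and optionally
#'   `length_m`; missing lengths default to the Euclidean distance.
#' @param buildings data.frame with columns `id`, `x`, `y`, `fun`
#'   (one of [surf_functions()]) and `zone_id`.
#' @param sensors data.frame with columns `id`, `x`, `y`, `radius_m`.
#' @return An object of class `surf_town`.
#' @export
surf_town <- function(nodes, edges, buildings, sensors) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  buildings <- as.data.frame(buildings)
  sensors <- as.data.frame(sensors)
  stopifnot(all(c("id", "x", "y") %in% names(nodes)),
            all(c("u", "v") %in% names(edges)),
            all(c("id", "x", "y", "fun", "zone_id") %in% names(buildings)),
            all(c("id", "x", "y", "radius_m") %in% names(sensors)))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (anyDuplicated(buildings$id)) stop("duplicate building ids")

  ui <- match(edges$u, nodes$id)
  vi <- match(edges$v, nodes$id)
  if (anyNA(ui) || anyNA(vi)) stop("edge references unknown node id")
  eucl <- sqrt((nodes$x[ui] - nodes$x[vi])^2 + (nodes$y[ui] - nodes$y[vi])^2)
  if (is.null(edges$length_m)) edges$length_m <- eucl
  edges$length_m[is.na(edges$length_m)] <- eucl[is.na(edges$length_m)]
  if (any(edges$length_m <= 0))
    stop("edge lengths must be positive")
  if (any(edges$length_m < eucl - 1e-6))
    stop("edge length shorter than the Euclidean distance between endpoints")

  g <- igraph::graph_from_edgelist(cbind(ui, vi), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(nodes) - igraph::vcount(g)))
  comp <- igraph::components(g)
  if (comp$no > 1)
    stop("disconnected road network: component sizes ",
         paste(sort(comp$csize, decreasing = TRUE), collapse = ", "))

  bad <- !buildings$fun %in% FUNCTIONS
  if (any(bad))
    stop("unknown building function ", sQuote(buildings$fun[bad][1]),
         " for building ", sQuote(buildings$id[bad][1]))
  bbox <- c(xmin = min(nodes$x, buildings$x), xmax = max(nodes$x, buildings$x),
            ymin = min(nodes$y, buildings$y), ymax = max(nodes$y, buildings$y))
  if (any(sensors$radius_m <= 0)) stop("sensor detection radius must be > 0")

  buildings$node <- nearest_node_idx(nodes, buildings$x, buildings$y)
  sensors$node <- nearest_node_idx(nodes, sensors$x, sensors$y)

  structure(list(nodes = nodes, edges = edges, buildings = buildings,
                 sensors = sensors,
                 zones = sort(unique(buildings$zone_id)), bbox = bbox),
            class = "surf_town")
}

#' @export
print.surf_town <- function(x, ...) {
  cat("surf town:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges,",
      nrow(x$buildings), "buildings,", length(x$zones), "zones,",
      nrow(x$sensors), "sensors\n")
  print(table(x$buildings$fun))
  invisible(x)
}

# Index (row) of the nearest node for each (x, y); ties broken by the
# smallest node id.
nearest_node_idx <- function(nodes, x, y) {
  ord <- order(nodes$id)
  vapply(seq_along(x), function(i) {
    d <- (nodes$x[ord] - x[i])^2 + (nodes$y[ord] - y[i])^2
    ord[which.min(d)]
  }, integer(1))
}

#' Nearest network node to a point
#'
#' Returns the id of the node minimising the Euclidean distance to `point`;
#' ties are broken by the smallest node id.
#'
#' @param town a [surf_town()].
#' @param point numeric length-2 vector `c(x, y)` in metres.
#' @return A node id.
#' @export
nearest_node <- function(town, point) {
  stopifnot(inherits(town, "surf_town"), length(point) == 2)
  if (nrow(town$nodes) == 0) stop("empty network")
  town$nodes$id[nearest_node_idx(town$nodes, point[1], point[2])]
}

#' Load a town from standard files
#'
#' Buildings are read from a GeoJSON FeatureCollection (Point or Polygon
#' features with `id`, `function` and `zone_id` properties; polygons are
#' reduced to the mean of their ring vertices), the road network from
#' `nodes.csv` (`id,x,y`) and `edges.csv` (`u,v,length_m`), and sensors
#' from a CSV (`id,x,y,radius_m`).
#'
#' @param buildings_path path to the buildings GeoJSON file.
#' @param network_path either a directory containing `nodes.csv` and
#'   `edges.csv`, or a character vector of the two file paths.
#' @param sensors_path path to the sensors CSV.
#' @return A validated [surf_town()].
#' @export
load_town <- function(buildings_path, network_path, sensors_path) {
  gj <- jsonlite::read_json(buildings_path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("buildings file is not a FeatureCollection")
  feats <- lapply(gj$features, function(f) {
    geom <- f$geometry
    if (identical(geom$type, "Point")) {
      xy <- as.numeric(unlist(geom$coordinates))
    } else if (identical(geom$type, "Polygon")) {
      ring <- geom$coordinates[[1]]
      m <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
      # drop the closing vertex if the ring is explicitly closed
      if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      xy <- colMeans(m)
    } else {
      stop("unsupported geometry type ", sQuote(geom$type),
           " for feature ", sQuote(f$properties$id))
    }
    pr <- f$properties
    if (is.null(pr$`function`))
      stop("building feature ", sQuote(pr$id), " has no function tag")
    data.frame(id = pr$id, x = xy[1], y = xy[2],
               fun = pr$`function`, zone_id = pr$zone_id)
  })
  buildings <- do.call(rbind, feats)

  if (length(network_path) == 1 && dir.exists(network_path))
    network_path <- file.path(network_path, c("nodes.csv", "edges.csv"))
  nodes <- read.csv(network_path[1])
  edges <- read.csv(network_path[2])
  sensors <- read.csv(sensors_path)
  surf_town(nodes, edges, buildings, sensors)
}

#' Save a town to standard files
#'
#' Writes `buildings.geojson`, `nodes.csv`, `edges.csv` and `sensors.csv`
#' into `dir`; [load_town()] on the result reproduces the town exactly.
#'
#' @param town a [surf_town()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_town <- function(town, dir) {
  stopifnot(inherits(town, "surf_town"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  feats <- lapply(seq_len(nrow(town$buildings)), function(i) {
    b <- town$buildings[i, ]
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(b$x, b$y)),
         properties = list(id = b$id, `function` = b$fun, zone_id = b$zone_id))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file.path(dir, "buildings.geojson"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(town$nodes[c("id", "x", "y")], file.path(dir, "nodes.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(town$edges[c("u", "v", "length_m")], file.path(dir, "edges.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(town$sensors[c("id", "x", "y", "radius_m")],
            file.path(dir, "sensors.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Generate a synthetic gridded town
#'
#' Builds a square grid street network of `(n_blocks + 1)^2` nodes with
#' blocks of side `block_m`, places buildings at random positions along
#' block-perimeter streets with functions drawn from `function_mix`, tiles
#' one statistical zone over each block, and places sensors on the most
#' central nodes.  Every building function that `function_mix` gives
#' positive probability is guaranteed to appear at least once so that the
#' generated town can host all configured activities.
#'
#' @param n_blocks blocks per side (>= 1).
#' @param buildings_per_block buildings placed in each block.
#' @param function_mix named probabilities over [surf_functions()]; must sum
#'   to 1 and give positive mass to every function required by
#'   `required_functions`.
#' @param n_sensors number of sensors, placed on central nodes.
#' @param seed integer seed; the town is deterministic given the seed.
#' @param block_m block side length in metres.
#' @param sensor_radius_m detection radius of every sensor.
#' @param required_functions functions that must be available; defaults to
#'   the full vocabulary (the shipped parameterisation uses all seven).
#' @return A validated [surf_town()].
#' @export
generate_synthetic_town <- function(n_blocks, buildings_per_block,
                                    function_mix = default_function_mix(),
                                    n_sensors = 8, seed = 1, block_m = 150,
                                    sensor_radius_m = 20,
                                    required_functions = FUNCTIONS) {
  stopifnot(n_blocks >= 1, buildings_per_block >= 1, n_sensors >= 1)
  mix <- unlist(function_mix)
  if (abs(sum(mix) - 1) > 1e-8) stop("function_mix must sum to 1")
  if (!all(names(mix) %in% FUNCTIONS))
    stop("unknown function in function_mix: ",
         paste(setdiff(names(mix), FUNCTIONS), collapse = ", "))
  missing <- setdiff(required_functions, names(mix)[mix > 0])
  if (length(missing))
    stop("function_mix omits required building function(s): ",
         paste(missing, collapse = ", "))

  with_seed(seed, {
    side <- n_blocks + 1
    gx <- rep(0:n_blocks, times = side) * block_m
    gy <- rep(0:n_blocks, each = side) * block_m
    nodes <- data.frame(id = seq_len(side^2), x = gx, y = gy)
    nid <- function(r, c) (r - 1) * side + c     # row-major node id
    eh <- do.call(rbind, lapply(1:side, function(r)
      cbind(nid(r, 1:n_blocks), nid(r, 2:side))))
    ev <- do.call(rbind, lapply(1:side, function(c)
      cbind(nid(1:n_blocks, c), nid(2:side, c))))
    edges <- data.frame(u = c(eh[, 1], ev[, 1]), v = c(eh[, 2], ev[, 2]))
    edges$length_m <- block_m

    n_bld <- n_blocks^2 * buildings_per_block
    blk_r <- rep(rep(1:n_blocks, each = n_blocks), each = buildings_per_block)
    blk_c <- rep(rep(1:n_blocks, times = n_blocks), each = buildings_per_block)
    # position along a random perimeter street of the block, nudged 10 m in
    side_pick <- sample(4, n_bld, replace = TRUE)
    t <- runif(n_bld) * block_m
    x0 <- (blk_c - 1) * block_m
    y0 <- (blk_r - 1) * block_m
    bx <- ifelse(side_pick == 1, x0 + t,
          ifelse(side_pick == 2, x0 + block_m - 10,
          ifelse(side_pick == 3, x0 + t, x0 + 10)))
    by <- ifelse(side_pick == 1, y0 + 10,
          ifelse(side_pick == 2, y0 + t,
          ifelse(side_pick == 3, y0 + block_m - 10, y0 + t)))
    fun <- sample(names(mix), n_bld, replace = TRUE, prob = mix)
    # guarantee availability of every required function
    for (f in setdiff(required_functions, unique(fun))) {
      dom <- names(which.max(table(fun)))
      fun[sample(which(fun == dom), 1)] <- f
    }
    buildings <- data.frame(
      id = sprintf("B%04d", seq_len(n_bld)), x = bx, y = by, fun = fun,
      zone_id = sprintf("Z%02d_%02d", blk_r, blk_c))

    ctr <- c(mean(nodes$x), mean(nodes$y))
    d <- sqrt((nodes$x - ctr[1])^2 + (nodes$y - ctr[2])^2)
    sel <- order(d, nodes$id)[seq_len(min(n_sensors, nrow(nodes)))]
    sensors <- data.frame(id = sprintf("S%02d", seq_along(sel)),
                          x = nodes$x[sel], y = nodes$y[sel],
                          radius_m = sensor_radius_m)
    surf_town(nodes, edges, buildings, sensors)
  })
}

#' Default building-function mix for synthetic towns
#'
#' Residential dominates, offices are the next most common, and the five
#' leisure/retail functions share the remainder, loosely mirroring a small
#' market town.
#'
#' @return Named numeric probabilities summing to 1.
#' @export
default_function_mix <- function() {
  c(residential = 0.44, office = 0.16, supermarket = 0.08,
    leisure_shop = 0.08, restaurant = 0.08, pub = 0.08,
    sports_facility = 0.08)
}
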