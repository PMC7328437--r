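# Small worlds and parameter sets built in code for the tests.

# A 4-node line network with three buildings and one sensor on node 2.
toy_line_town <- function(sensor_radius = 20) {
  nodes <- data.frame(id = 1:4, x = c(0, 100, 200, 300), y = 0)
  edges <- data.frame(u = 1:3, v = 2:4, length_m = 100)
  buildings <- data.frame(
    id = c("H", "W", "S"), x = c(0, 295, 105), y = c(5, 5, 5),
    fun = c("residential", "office", "supermarket"),
    zone_id = c("ZA", "ZB", "ZA"))
  sensors <- data.frame(id = "S1", x = 100, y = 0,
                        radius_m = sensor_radius)
  surf_town(nodes, edges, buildings, sensors)
}

# Minimal commuter-only parameter set: home and work only, noise off.
# Work recurs daily, so noise-off runs are day-periodic.
noise_off_params <- function() {
  p <- default_params()
  p$global$sigma_rate <- 0
  p$global$sigma_duration <- 0
  p$global$window_offset_min <- 0
  p$global$daily_jitter_min <- 0
  p$activities$commuter <- p$activities$commuter[c("at_home", "work")]
  p$activities$retired <- p$activities$retired["at_home"]
  for (g in names(p$activities))
    for (a in names(p$activities[[g]]))
      p$activities[[g]][[a]]$init_max <- 0
  p
}

# Noise-off parameters where food shopping fires daily (amplitude above the
# home floor inside its window), still day-periodic.
daily_shop_params <- function() {
  p <- noise_off_params()
  p$activities$commuter$shop_food <-
    list(grow_rate = 1e-4, decay_rate = 0.2, amplitude = 1.3,
         window_start = 17.5 * 60, window_end = 19 * 60,
         min_duration_min = 30, init_max = 0)
  p
}

# One-commuter population living at building H, working at W.
toy_population <- function(town, group = "commuter", n = 1,
                           offset_min = 0) {
  agents <- data.frame(
    id = seq_len(n), group = group,
    home_building = "H",
    work_building = if (group == "commuter") "W" else NA_character_,
    offset_min = offset_min)
  structure(list(agents = agents,
                 rate_mult = matrix(1, n, 7, dimnames = list(NULL, surf_activities())),
                 dur_mult = matrix(1, n, 7, dimnames = list(NULL, surf_activities()))),
            class = "surf_population")
}

# Random connected graph for routing tests: a random spanning tree plus
# extra chords; edge lengths inflate the Euclidean distance.
random_network <- function(n_nodes, n_extra = n_nodes, seed = 1) {
  set.seed(seed)
  nodes <- data.frame(id = seq_len(n_nodes),
                      x = runif(n_nodes, 0, 1000),
                      y = runif(n_nodes, 0, 1000))
  u <- integer(0); v <- integer(0)
  for (i in 2:n_nodes) { u <- c(u, sample(i - 1, 1)); v <- c(v, i) }
  for (k in seq_len(n_extra)) {
    pair <- sample(n_nodes, 2)
    u <- c(u, pair[1]); v <- c(v, pair[2])
  }
  keep <- !duplicated(paste(pmin(u, v), pmax(u, v))) & u != v
  u <- u[keep]; v <- v[keep]
  eucl <- sqrt((nodes$x[u] - nodes$x[v])^2 + (nodes$y[u] - nodes$y[v])^2)
  edges <- data.frame(u = u, v = v,
                      length_m = eucl * runif(length(u), 1, 1.5))
  list(nodes = nodes, edges = edges)
}

# igraph shortest-path length between two nodes (Dijkstra oracle).
igraph_distance <- function(net, from, to) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$u, to = net$edges$v),
    directed = FALSE,
    vertices = data.frame(name = net$nodes$id))
  igraph::distances(g, v = as.character(from), to = as.character(to),
                    weights = net$edges$length_m)[1, 1]
}

# The acceptance-scale demo run is expensive; compute it once per session.
acceptance_cache <- new.env(parent = emptyenv())

acceptance_run <- function() {
  if (is.null(acceptance_cache$agg)) {
    inp <- demo_inputs(fixture_spec(n_commuters = 2000, n_retired = 2000,
                                    seed = 42))
    agg <- run_replicates(inp$town, inp$population, inp$params,
                          run_config(n_days = 14, n_replicates = 10,
                                     seed = 2024))
    acceptance_cache$inp <- inp
    acceptance_cache$agg <- agg
    acceptance_cache$stats <- schedule_stats(agg)
  }
  list(inp = acceptance_cache$inp, agg = acceptance_cache$agg,
       stats = acceptance_cache$stats)
}

stat_row <- function(stats, group, activity) {
  stats[stats$group == group & stats$activity == activity, ]
}
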