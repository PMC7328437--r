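# Virtual footfall sensors: a crossing event is recorded each time an
# agent's step segment enters a sensor's detection disc from outside;
# remaining inside across steps does not re-count.

#' Record sensor crossing events for one step
#'
#' Given agent positions at the start and end of a step, returns one event
#' per (agent, sensor) whose detection disc the straight step segment
#' enters from outside.  The inside/outside state must be carried between
#' consecutive calls; agents that start inside a disc generate no event
#' until they leave and re-enter.
#'
#' @param pos_t,pos_t1 numeric matrices (agents x 2) of positions at `t`
#'   and `t + dt`.
#' @param sensors sensor data.frame (`id`, `x`, `y`, `radius_m`).
#' @param inside logical matrix (agents x sensors) of the current
#'   inside-disc state; defaults to the state implied by `pos_t`.
#' @return A list: `events` (data.frame `agent`, `sensor_id`) and the
#'   updated `inside` matrix.
#' @export
record_crossings <- function(pos_t, pos_t1, sensors, inside = NULL) {
  pos_t <- rbind(pos_t); pos_t1 <- rbind(pos_t1)
  n <- nrow(pos_t); m <- nrow(sensors)
  if (is.null(inside)) {
    inside <- outer(seq_len(n), seq_len(m), Vectorize(function(i, j)
      sqrt((pos_t[i, 1] - sensors$x[j])^2 +
           (pos_t[i, 2] - sensors$y[j])^2) <= sensors$radius_m[j]))
  }
  ev_agent <- integer(0); ev_sensor <- character(0)
  for (j in seq_len(m)) {
    for (i in seq_len(n)) {
      d_end <- sqrt((pos_t1[i, 1] - sensors$x[j])^2 +
                    (pos_t1[i, 2] - sensors$y[j])^2)
      if (!inside[i, j]) {
        dmin <- seg_point_dist_cpp(pos_t[i, 1], pos_t[i, 2],
                                   pos_t1[i, 1], pos_t1[i, 2],
                                   sensors$x[j], sensors$y[j])
        if (dmin <= sensors$radius_m[j]) {
          ev_agent <- c(ev_agent, i)
          ev_sensor <- c(ev_sensor, as.character(sensors$id[j]))
        }
      }
      inside[i, j] <- d_end <= sensors$radius_m[j]
    }
  }
  list(events = data.frame(agent = ev_agent, sensor_id = ev_sensor),
       inside = inside)
}

#' Bin crossing events into hourly footfall totals
#'
#' @param events data.frame with columns `sensor_id` and `time_min`
#'   (minutes since midnight of the reported day).
#' @param sensor_ids all sensor ids (so silent sensors appear as zero
#'   rows).
#' @return A sensors x 24 integer matrix of hourly counts (a footfall
#'   table for one day).
#' @export
hourly_totals <- function(events, sensor_ids) {
  out <- matrix(0L, length(sensor_ids), 24,
                dimnames = list(as.character(sensor_ids),
                                sprintf("h%02d", 0:23)))
  if (nrow(events)) {
    stopifnot(all(events$time_min >= 0), all(events$time_min < 1440))
    hr <- floor(events$time_min / 60)
    tab <- table(factor(as.character(events$sensor_id),
                        levels = as.character(sensor_ids)),
                 factor(hr, levels = 0:23))
    out[] <- out + unclass(tab)
  }
  out
}

#' Write a footfall table as CSV
#'
#' Long format `sensor_id,hour,count`, the interchange format for observed
#' and simulated series.
#'
#' @param footfall sensors x 24 matrix (rownames are sensor ids).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_footfall_csv <- function(footfall, path) {
  df <- data.frame(sensor_id = rep(rownames(footfall), times = 24),
                   hour = rep(0:23, each = nrow(footfall)),
                   count = as.vector(footfall))
  df <- df[order(df$sensor_id, df$hour), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a footfall table from CSV
#'
#' @param path CSV with columns `sensor_id,hour,count`.
#' @return A sensors x 24 matrix.
#' @export
read_footfall_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("sensor_id", "hour", "count") %in% names(df)))
  ids <- sort(unique(as.character(df$sensor_id)))
  out <- matrix(0, length(ids), 24,
                dimnames = list(ids, sprintf("h%02d", 0:23)))
  out[cbind(match(as.character(df$sensor_id), ids), df$hour + 1)] <- df$count
  out
}
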