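test_that("zero agents give all-zero footfall and empty logs", {
  town <- toy_line_town()
  pop <- toy_population(town)
  pop$agents <- pop$agents[0, ]
  pop$rate_mult <- pop$rate_mult[0, , drop = FALSE]
  pop$dur_mult <- pop$dur_mult[0, , drop = FALSE]
  run <- run_simulation(town, pop, noise_off_params(),
                        run_config(n_days = 3), replicate_seed = 1)
  expect_true(all(run$footfall == 0))
  expect_equal(nrow(run$log), 0)
  expect_equal(nrow(run$events), 0)
})

test_that("runs are bit-reproducible under the same replicate seed", {
  inp <- demo_inputs(fixture_spec(n_commuters = 40, n_retired = 40,
                                  seed = 7))
  r1 <- run_simulation(inp$town, inp$population, inp$params,
                       run_config(n_days = 4), replicate_seed = 99)
  r2 <- run_simulation(inp$town, inp$population, inp$params,
                       run_config(n_days = 4), replicate_seed = 99)
  expect_identical(r1, r2)
  r3 <- run_simulation(inp$town, inp$population, inp$params,
                       run_config(n_days = 4), replicate_seed = 100)
  expect_false(identical(r1$footfall, r3$footfall))
})

test_that("one commuter crossing a mid-route sensor registers two passes", {
  # home at node 1, office at node 4, sensor on node 2: the commute
  # passes the disc once out, once back; noise off, no other activities
  town <- toy_line_town()
  pop <- toy_population(town)
  run <- run_simulation(town, pop, noise_off_params(),
                        run_config(n_days = 3), replicate_seed = 3)
  expect_equal(sum(run$footfall), 2)
  # morning pass in the 07:00 hour (leaves at 07:45), evening at 16:15+
  expect_equal(sum(run$footfall[1, 8:9]), 1)
  expect_equal(sum(run$footfall[1, 17]), 1)
  # the log contains one work episode covering the office hours
  rl <- rle(as.vector(run$log[1, ]))
  expect_equal(sum(rl$values == 2), 1)
  expect_equal(sum(run$log[1, ] == 0), 2)   # one travel step each way
})

test_that("activity logs cover every agent and step", {
  inp <- demo_inputs(fixture_spec(n_commuters = 25, n_retired = 25,
                                  seed = 8))
  run <- run_simulation(inp$town, inp$population, inp$params,
                        run_config(n_days = 3), replicate_seed = 4)
  expect_equal(dim(run$log), c(50, 288))
  expect_true(all(run$log %in% 0:7))
  # exactly one state per agent-step: travelling or a single activity
  expect_false(anyNA(run$log))
  # retired agents never work, commuters never leisure-shop
  expect_true(all(run$log[run$groups == "retired", ] != 2))
  expect_true(all(run$log[run$groups == "commuter", ] != 4))
})

test_that("footfall counting is additive over agents", {
  inp <- demo_inputs(fixture_spec(n_commuters = 60, n_retired = 60,
                                  seed = 12))
  run <- run_simulation(inp$town, inp$population, inp$params,
                        run_config(n_days = 3), replicate_seed = 5)
  # total counts equal the attributed event tally, and any agent partition
  # sums to the partition totals
  expect_equal(sum(run$footfall), nrow(run$events))
  half <- run$events$agent <= 60
  tab <- function(ev) {
    out <- hourly_totals(data.frame(sensor_id = ev$sensor_id,
                                    time_min = ev$step * 5),
                         rownames(run$footfall))
    out
  }
  expect_equal(tab(run$events[half, ]) + tab(run$events[!half, ]),
               tab(run$events))
  expect_equal(unname(tab(run$events)), unname(run$footfall + 0L),
               ignore_attr = TRUE)
})

test_that("noise-off runs reach a day-periodic equilibrium", {
  town <- toy_line_town()
  pop <- toy_population(town)
  p <- daily_shop_params()
  short <- run_simulation(town, pop, p, run_config(n_days = 3),
                          replicate_seed = 10)
  lng <- run_simulation(town, pop, p, run_config(n_days = 4),
                        replicate_seed = 10)
  expect_equal(short$log, lng$log)      # day 3 equals day 4
  expect_equal(short$footfall, lng$footfall)
})

test_that("replicate aggregation: means, CI nesting and degenerate CIs", {
  set.seed(31)
  per <- array(rpois(2 * 24 * 6, 20), dim = c(2, 24, 6))
  agg99 <- aggregate_replicates(per, ci_level = 0.99, boot_seed = 9)
  agg95 <- aggregate_replicates(per, ci_level = 0.95, boot_seed = 9)
  expect_equal(agg99$mean, apply(per, c(1, 2), mean))
  expect_true(all(agg95$ci_lo >= agg99$ci_lo - 1e-12))
  expect_true(all(agg95$ci_hi <= agg99$ci_hi + 1e-12))
  expect_true(all(agg99$ci_lo <= agg99$mean & agg99$mean <= agg99$ci_hi))

  # identical replicates: zero-width intervals
  flat <- array(rep(per[, , 1], 5), dim = c(2, 24, 5))
  aggc <- aggregate_replicates(flat, boot_seed = 2)
  expect_equal(aggc$ci_lo, aggc$mean)
  expect_equal(aggc$ci_hi, aggc$mean)
})

test_that("run_replicates aggregates independent seeded replicates", {
  inp <- demo_inputs(fixture_spec(n_commuters = 30, n_retired = 30,
                                  seed = 13))
  agg <- run_replicates(inp$town, inp$population, inp$params,
                        run_config(n_days = 3, n_replicates = 3, seed = 50))
  expect_equal(dim(agg$per_replicate), c(8, 24, 3))
  expect_equal(agg$mean, apply(agg$per_replicate, c(1, 2), mean))
  # replicates differ (independent streams)
  expect_false(identical(agg$per_replicate[, , 1], agg$per_replicate[, , 2]))
  # rerunning reproduces the aggregate exactly
  agg2 <- run_replicates(inp$town, inp$population, inp$params,
                         run_config(n_days = 3, n_replicates = 3, seed = 50))
  expect_equal(agg$mean, agg2$mean)
})
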