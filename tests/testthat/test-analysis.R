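# Helper: wrap a hand-written log matrix as a surf_run.
fake_run <- function(log, groups) {
  structure(list(log = log, groups = groups,
                 footfall = matrix(0L, 1, 24,
                                   dimnames = list("S1",
                                                   sprintf("h%02d", 0:23))),
                 events = data.frame()),
            class = "surf_run")
}

test_that("schedule statistics match a hand tally on scripted logs", {
  # agent 1 (commuter): one 6-step shop episode (09:00-09:30) within home
  # agent 2 (commuter): never shops
  lg <- matrix(1L, 2, 288)
  lg[1, 109:114] <- 3L
  st <- schedule_stats(list(fake_run(lg, c("commuter", "commuter"))))
  row <- stat_row(st, "commuter", "shop_food")
  expect_equal(row$participation, 50)
  expect_equal(row$mean_duration, 30)
  expect_equal(row$median_duration, 30)
  expect_equal(row$n_episodes, 1)
  # start and end hour histograms
  hs <- attr(st, "start_hist")[["commuter.shop_food"]]
  expect_equal(which(hs == 1) - 1, 9)
  expect_equal(sum(hs), row$n_episodes)

  # travel steps break runs and are excluded from durations
  lg2 <- matrix(1L, 1, 288)
  lg2[1, 100:120] <- 3L
  lg2[1, 110] <- 0L                  # interleaved travel step
  st2 <- schedule_stats(list(fake_run(lg2, "retired")))
  row2 <- stat_row(st2, "retired", "shop_food")
  expect_equal(row2$n_episodes, 2)
  expect_equal(row2$mean_duration, 50)      # (10 + 10 runs) * 5 / 2
  # richer scripted tally: 100 agents, agent i shops i %% 4 times 4 steps
  set.seed(5)
  lg3 <- matrix(1L, 100, 288)
  expected <- integer(100)
  for (i in 1:100) {
    k <- i %% 4
    expected[i] <- k
    if (k > 0) for (j in seq_len(k))
      lg3[i, (20 * j):(20 * j + 3)] <- 7L
  }
  st3 <- schedule_stats(list(fake_run(lg3, rep("retired", 100))))
  row3 <- stat_row(st3, "retired", "sports")
  expect_equal(row3$n_episodes, sum(expected))
  expect_equal(row3$participation, mean(expected > 0) * 100)
  expect_equal(row3$mean_duration, 20)
})

test_that("participation averages over replicates", {
  lg_yes <- matrix(1L, 1, 288); lg_yes[1, 150:160] <- 3L
  lg_no <- matrix(1L, 1, 288)
  st <- schedule_stats(list(fake_run(lg_yes, "commuter"),
                            fake_run(lg_no, "commuter")))
  expect_equal(stat_row(st, "commuter", "shop_food")$participation, 50)
  expect_error(schedule_stats(list()), "logs")
})

test_that("target evaluation flags deviations beyond tolerance", {
  targets <- data.frame(
    group = c("commuter", "commuter"), activity = c("shop_food", "shop_food"),
    metric = c("participation", "mean_duration"),
    value = c(27, 41), tolerance = c(3, 0.15),
    tolerance_type = c("pp", "rel"))
  stats <- data.frame(group = "commuter", activity = "shop_food",
                      participation = 27, mean_duration = 41,
                      median_duration = 30)
  ev <- evaluate_targets(stats, targets)
  expect_equal(nrow(ev), nrow(targets))
  expect_true(all(ev$pass))
  expect_equal(ev$abs_dev, c(0, 0))

  stats$participation <- 33    # off by twice the tolerance
  ev2 <- evaluate_targets(stats, targets)
  expect_false(ev2$pass[1])
  expect_true(ev2$pass[2])
  expect_error(evaluate_targets(stats[0, ], targets), "no simulated")
})

test_that("pooled curves average sensors; single sensor is identity", {
  m <- matrix(rpois(24, 10), 1, 24,
              dimnames = list("S1", sprintf("h%02d", 0:23)))
  expect_equal(unname(pooled_hourly_curve(m)), as.vector(m))
  m2 <- rbind(S1 = rep(2, 24), S2 = rep(4, 24))
  expect_equal(unname(pooled_hourly_curve(m2)), rep(3, 24))
  m3 <- matrix(runif(96), 4, 24)
  expect_equal(unname(pooled_hourly_curve(m3)), colMeans(m3))
})

test_that("zscore uses the population sd and rejects constants", {
  expect_equal(zscore(c(1, 2, 3)),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  x <- rnorm(24)
  z <- zscore(x)
  expect_equal(mean(z), 0)
  expect_equal(sqrt(mean(z^2)), 1)
  expect_error(zscore(rep(5, 24)), "constant")
  # invariance under positive affine transforms
  expect_equal(zscore(3 * x + 7), z)
})

test_that("the smoother preserves constants and straight lines", {
  expect_equal(smooth_curve(rep(4, 24)), rep(4, 24))
  lin <- seq(0, 46, by = 2)
  expect_equal(smooth_curve(lin), lin)
  expect_error(smooth_curve(lin, bandwidth = 0), "bandwidth")
  # noise around a sinusoid is reduced
  set.seed(8)
  truth <- sin(2 * pi * (0:23) / 24)
  noisy <- truth + rnorm(24, 0, 0.3)
  sm <- smooth_curve(noisy)
  expect_lt(mean((sm - truth)^2), mean((noisy - truth)^2))
})

test_that("curve comparison matches direct formulas", {
  x <- c(5, 8, 2, 9, 4)
  cmp <- compare_curves(x, x)
  expect_equal(cmp$rmse, 0)
  expect_equal(cmp$pearson_r, 1)
  # opposite curve on the Z scale
  cmp2 <- compare_curves(x, -2 * x + 3)
  expect_equal(cmp2$pearson_r, -1)
  expect_equal(cmp2$residual, -2 * zscore(x))
  # random pair against the direct formula
  set.seed(9)
  a <- rnorm(24); b <- rnorm(24)
  cmp3 <- compare_curves(a, b)
  za <- (a - mean(a)) / sqrt(mean((a - mean(a))^2))
  zb <- (b - mean(b)) / sqrt(mean((b - mean(b))^2))
  expect_equal(cmp3$rmse, sqrt(mean((zb - za)^2)))
  expect_equal(cmp3$pearson_r, stats::cor(a, b))
  expect_error(compare_curves(a, b[1:23]), "mismatch")
})
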