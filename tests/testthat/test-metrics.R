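test_that("time in range uses inclusive bounds so the bins partition", {
  expect_equal(time_in_range(rep(100, 10), 63, 140), 100)
  expect_equal(time_in_range(c(rep(150, 5), rep(100, 5)), 63, 140), 50)
  expect_equal(time_in_range(rep(63, 4), 63, 140), 100)   # boundary in-range
  expect_equal(time_in_range(rep(140, 4), 63, 140), 100)
  expect_error(time_in_range(numeric(), 63, 140), "empty")
})

test_that("bin partitions are exact for real trajectories", {
  s <- test_subject()
  for (id in c("A.1", "D.2")) {
    m <- glycemic_metrics(run_closed_loop(s, load_scenario(id),
      controller_preset("baseline"), seed = 21))
    expect_equal(m$below_63 + m$tir_63_140 + m$above_140, 100,
                 tolerance = 1e-9)
    expect_equal(m$below_70 + m$tir_70_180 + m$above_180, 100,
                 tolerance = 1e-9)
    expect_true(all(unlist(m[c("below_54", "below_63", "tir_63_140",
                               "above_140", "below_70", "tir_70_180",
                               "above_180", "above_250")]) >= 0))
  }
})

test_that("fasting glucose averages the day-2 06:00-07:00 window", {
  traj <- fake_trajectory(90)
  expect_equal(fasting_glucose(traj), 90)
  # linear ramp across the window averages to its midpoint
  traj2 <- fake_trajectory(90)
  w <- traj2$time >= 1380 & traj2$time < 1440
  traj2$cgm[w] <- seq(80, 100, length.out = sum(w))
  expect_equal(fasting_glucose(traj2), 90)
  short <- fake_trajectory(90, hours = 20)
  expect_error(fasting_glucose(short), "fasting window")
})

test_that("postprandial windows are (t, t+120] and flag truncation", {
  traj <- fake_trajectory(120)
  pp <- postprandial_tir(traj)
  expect_equal(pp$pooled, 100)
  expect_equal(nrow(pp$per_meal), 3)
  expect_false(any(pp$per_meal$truncated))
  traj$cgm[traj$time > 60 & traj$time <= 180] <- 150
  pp <- postprandial_tir(traj)
  expect_equal(pp$per_meal$tir, c(0, 100, 100))
  # meal 23 h in: window runs past the end of the run
  late <- postprandial_tir(traj, meal_times = 1400)
  expect_true(late$per_meal$truncated)
  expect_equal(late$per_meal$tir, 100)
  # the window excludes the meal instant itself
  traj2 <- fake_trajectory(120)
  traj2$cgm[traj2$time == 360] <- 300
  expect_equal(postprandial_tir(traj2)$pooled, 100)
})

test_that("consensus check applies the four pregnancy thresholds", {
  ok <- consensus_check(list(tir_63_140 = 80.8, above_140 = 18.3,
                             below_63 = 3.5, below_54 = 0.5))
  expect_true(ok$pass)
  bad54 <- consensus_check(list(tir_63_140 = 88.9, above_140 = 4.4,
                                below_63 = 3.9, below_54 = 3.2))
  expect_false(bad54$pass)
  expect_false(bad54$tbr54_max_1)
  expect_true(bad54$tar_under_25)
  hyper <- consensus_check(list(tir_63_140 = 55.5, above_140 = 44.5,
                                below_63 = 0, below_54 = 0))
  expect_false(hyper$pass)
  expect_false(hyper$tar_under_25)
  # boundary: exactly 1% below 54 still passes; exactly 70 TIR does not
  expect_true(consensus_check(list(tir_63_140 = 71, above_140 = 24,
                                   below_63 = 3, below_54 = 1))$pass)
  expect_false(consensus_check(list(tir_63_140 = 70, above_140 = 24,
                                    below_63 = 3, below_54 = 1))$pass)
})

test_that("paired comparison matches the closed-form t statistic", {
  a <- c(2, 4, 6); b <- c(1, 2, 3)
  pc <- paired_compare(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(pc$t, t_hand)
  expect_equal(pc$df, 2)
  expect_equal(pc$p, 2 * pt(-abs(t_hand), 2))
  flip <- paired_compare(b, a)
  expect_equal(flip$p, pc$p)
  expect_equal(flip$mean_diff, -pc$mean_diff)
  expect_error(paired_compare(a, a), "zero variance")
  expect_error(paired_compare(1:3, 1:4), "equal length")
})

test_that("zone grid search enumerates valid pairs and marks the rest NA", {
  coh <- test_cohort(1)
  grid <- zone_grid_search(c(70, 80, 90), seq(80, 130, by = 10), 10, "A.1",
                           coh, controller_preset("pregnancy"), seed = 3,
                           cgm = quiet_cgm())
  expect_equal(nrow(grid), 18)
  expect_equal(sum(grid$valid), 15)
  expect_equal(sum(!grid$valid), 3)
  expect_true(all(is.na(grid$tir_63_140[!grid$valid])))
  expect_true(all(!is.na(grid$tir_63_140[grid$valid])))
  single <- zone_grid_search(80, 110, 10, "A.1", coh,
                             controller_preset("pregnancy"), seed = 3,
                             cgm = quiet_cgm())
  expect_equal(nrow(single), 1)
  expect_true(single$valid)
  none <- zone_grid_search(100, 80, 10, "A.1", coh,
                           controller_preset("pregnancy"), seed = 3)
  expect_false(any(none$valid))
  expect_error(zone_grid_search(c(90, 70), 100, 10, "A.1", coh), "sorted")
})
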