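test_that("a closed-loop run is reproducible and well-formed", {
  s <- test_subject()
  traj <- run_closed_loop(s, load_scenario("A.1"), controller_preset("pregnancy"),
                          seed = 3)
  expect_s3_class(traj, "ap_trajectory")
  expect_equal(nrow(traj), 300)                       # 25 h at 5-min steps
  expect_equal(diff(traj$time[1:3]), c(5, 5))
  expect_true(all(traj$u >= 0))
  expect_true(all(traj$cgm >= 39 & traj$cgm <= 400))
  expect_identical(traj,
    run_closed_loop(s, load_scenario("A.1"), controller_preset("pregnancy"),
                    seed = 3))
  traj2 <- run_closed_loop(s, load_scenario("A.1"), controller_preset("pregnancy"),
                           seed = 4)
  expect_false(identical(traj$cgm, traj2$cgm))        # different noise stream
  expect_identical(traj$u[traj$time < 60], rep(traj$u_basal[1], 12))
})

test_that("every commanded delivery satisfies the active bound", {
  s <- test_subject()
  for (id in c("A.1", "C.1", "D.2")) {
    traj <- run_closed_loop(s, load_scenario(id), controller_preset("pregnancy"),
                            seed = 5)
    cl <- !is.na(traj$bound)
    expect_true(all(traj$u[cl] <= traj$bound[cl] + 1e-9))
    expect_true(all(traj$u[cl] >= 0))
    # pump limit: never above max(4 x basal, night cap)
    expect_true(all(traj$u[cl] <= pmax(4 * traj$u_basal[cl], 1) + 1e-9))
  }
})

test_that("user boluses are never closer than the 120-min lockout", {
  s <- test_subject()
  for (id in c("A.2", "B.3.b")) {
    traj <- run_closed_loop(s, load_scenario(id), controller_preset("pregnancy"),
                            seed = 6)
    doses <- attr(traj, "doses")
    ut <- doses$time[doses$kind == "user"]
    if (length(ut) > 1) expect_true(all(diff(sort(ut)) >= 120))
  }
})

test_that("meals and boluses follow the scenario meal plan", {
  s <- test_subject()
  # advance bolusing: boluses 30 min before the 08:00/13:00/19:00 meals
  ta <- run_closed_loop(s, load_scenario("A.2"), controller_preset("pregnancy"),
                        seed = 2, cgm = quiet_cgm())
  expect_equal(ta$time[ta$meal > 0], c(60, 360, 720))
  expect_equal(ta$time[ta$bolus > 0], c(30, 330, 690))
  # delayed first meal in B.3.b
  tb <- run_closed_loop(s, load_scenario("B.3.b"), controller_preset("pregnancy"),
                        seed = 2, cgm = quiet_cgm())
  expect_equal(tb$time[tb$meal > 0], c(120, 360, 720))
  expect_equal(tb$time[tb$bolus > 0], c(120, 360, 720))
  expect_equal(tb$cgm[1], 170, tolerance = 1)         # scenario initial glucose
})

test_that("the hypoglycemia-prone extreme scenario uses less insulin than its base", {
  s <- test_subject()
  td <- function(id) glycemic_metrics(run_closed_loop(s, load_scenario(id),
    controller_preset("pregnancy"), seed = 9, cgm = quiet_cgm()))$tdi
  expect_lte(td("D.1"), td("A.1"))
})

test_that("the experiment grid derives seeds and aggregates metrics", {
  coh <- test_cohort(2)
  res <- run_experiment("A.1", "pregnancy", coh, replicates = 2, seed = 77)
  expect_equal(nrow(res), 4)
  expect_equal(length(unique(res$seed)), 4)
  res2 <- run_experiment("A.1", "pregnancy", coh, replicates = 2, seed = 77)
  expect_identical(res, res2)
  expect_true(all(c("tir_63_140", "above_140", "tdi") %in% names(res)))
  expect_error(run_experiment("A.1", "pregnancy", coh, replicates = 0), ">= 1")
})

test_that("trajectory CSV round trip preserves data and metadata", {
  s <- test_subject()
  traj <- run_closed_loop(s, load_scenario("A.1"), controller_preset("baseline"),
                          seed = 8)
  f <- tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  back <- read_trajectory(f)
  expect_equal(back$G, traj$G, tolerance = 1e-12)
  expect_equal(back$u, traj$u, tolerance = 1e-12)
  m <- attr(back, "meta")
  expect_equal(m$subject, "T01")
  expect_equal(m$scenario, "A.1")
  expect_equal(m$basal_h, attr(traj, "meta")$basal_h)
  expect_error(read_trajectory(f2 <- {
    writeLines("time,G", tmp <- tempfile()); tmp
  }), "not an")
})
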