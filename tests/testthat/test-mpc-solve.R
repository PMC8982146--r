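test_that("delivery bounds combine the pump limit and the IOB limit", {
  cfg <- controller_config()   # gref 110, day window 06:00-22:00
  expect_equal(insulin_bounds(720, 0.1, 400, 0, 45, cfg), 0.4)
  expect_equal(insulin_bounds(120, 0.1, 400, 0, 45, cfg), 1)
  # IOB_required = (G - Gref)/CF caps stacking
  zcfg <- controller_preset("zone_adjusted")$controller  # gref 90
  expect_equal((190 - zcfg$gref) / 50, 2)
  expect_equal(insulin_bounds(720, 0.6, 190, 0, 50, zcfg), 2.4)   # pump limit
  expect_equal(insulin_bounds(120, 0.6, 190, 0, 50, zcfg), 1)     # night cap
  expect_equal(insulin_bounds(720, 0.6, 190, 2.5, 50, zcfg), 0.6) # IOB met -> basal
  expect_equal(insulin_bounds(720, 0.6, 190, 1, 50, zcfg), 1.6)   # partial headroom
  expect_error(insulin_bounds(720, 0.1, 100, 0, 0, cfg), "positive")
})

small_config <- function() controller_config(np = 4, nu = 2)

test_that("solver equals exhaustive plan enumeration on small horizons", {
  cfg <- small_config()
  m <- build_prediction_model(40)
  basal <- 0.1
  lb <- rep(-basal, 2)
  set.seed(29)
  worst <- 0
  for (i in 1:20) {
    g <- runif(1, 40, 260)
    xh <- c(g, g, g) - cfg$gref + rnorm(3, 0, 8)
    Gk <- xh[3] + cfg$gref
    Gkm1 <- Gk + rnorm(1, 0, 5)
    v <- (Gk - (Gkm1 - rnorm(1, 0, 5))) / 10
    iob <- runif(1, 0, 2)
    iob_req <- (Gk - cfg$gref) / 45
    bound <- runif(1, 0.2, 0.5)
    ub <- rep(bound - basal, 2)
    sol <- mpc_solve(xh, basal, bound, cfg, m, clock = 720,
                     G_recent = c(Gkm1, Gk), v_now = v, iob = iob,
                     iob_required = iob_req)
    bf <- brute_force_cost(xh, m, cfg, lb, ub, clock = 720,
                           G_recent = c(Gkm1, Gk), v_now = v, iob = iob,
                           iob_required = iob_req)
    rel <- abs(sol$cost - bf$cost) / max(bf$cost, 1e-8)
    if (bf$cost < 1e-10) rel <- abs(sol$cost - bf$cost)
    worst <- max(worst, rel)
    expect_lt(rel, 1e-4)
  }
})

test_that("command equals basal exactly when predictions sit inside the zone", {
  cfg <- controller_config()
  m <- build_prediction_model(40)
  set.seed(5)
  # at or above the reference the free response decays: no rising-velocity
  # penalty, zero deviations, and the input cost pins the plan at basal
  for (i in 1:20) {
    g <- runif(1, cfg$gref, cfg$zone_day[2] - 3)
    xh <- rep(g - cfg$gref, 3)
    basal <- runif(1, 0.05, 0.3)
    sol <- mpc_solve(xh, basal, 4 * basal, cfg, m, clock = 720,
                     G_recent = c(g, g), v_now = 0, iob = 0,
                     iob_required = Inf)
    expect_identical(sol$command, basal)
    expect_identical(sol$plan, rep(0, cfg$nu))
  }
  # below the reference the free response creeps up toward it; the one-sided
  # velocity term then admits only a vanishing departure from basal
  for (g in c(93, 100, 107)) {
    xh <- rep(g - cfg$gref, 3)
    sol <- mpc_solve(xh, 0.1, 0.4, cfg, m, clock = 720,
                     G_recent = c(g, g), v_now = 0, iob = 0,
                     iob_required = Inf)
    expect_equal(sol$command, 0.1, tolerance = 1e-6)
  }
})

test_that("commanded insulin responds monotonically to glucose level", {
  cfg <- controller_config()
  m <- build_prediction_model(40)
  set.seed(8)
  for (i in 1:20) {
    xh <- rnorm(3, 40, 50)
    cmd <- vapply(c(0, 15, 30), function(shift) {
      g <- xh[3] + shift + cfg$gref
      mpc_solve(xh + shift, 0.1, 0.4, cfg, m, clock = 720,
                G_recent = c(g, g), v_now = 0, iob = 0,
                iob_required = Inf)$command
    }, 0)
    expect_true(all(diff(cmd) >= -1e-9))
  }
})

test_that("deep falling hypoglycemia commands full suspension", {
  cfg <- controller_config()
  m <- build_prediction_model(40)
  xh <- c(40, 45, 50) - cfg$gref
  sol <- mpc_solve(xh, 0.1, 0.4, cfg, m, clock = 720, G_recent = c(55, 50))
  expect_equal(sol$command, 0, tolerance = 1e-9)
  # brute force agrees on a reduced-horizon version of the same state
  scfg <- small_config()
  sol2 <- mpc_solve(xh, 0.1, 0.4, scfg, m, clock = 720, G_recent = c(55, 50))
  bf <- brute_force_cost(xh, m, scfg, rep(-0.1, 2), rep(0.3, 2), clock = 720,
                         G_recent = c(55, 50))
  expect_equal(sol2$cost, bf$cost, tolerance = 1e-4 * max(1, bf$cost))
  expect_lt(bf$u[1], 0)   # enumeration also reduces below basal
})

test_that("hyperglycemia saturates at the active bound, never above", {
  cfg <- controller_config()
  m <- build_prediction_model(40)
  set.seed(13)
  for (i in 1:20) {
    g <- runif(1, 150, 400)
    xh <- rep(g - cfg$gref, 3)
    bound <- insulin_bounds(720, 0.1, g, 0, 45, cfg)
    sol <- mpc_solve(xh, 0.1, bound, cfg, m, clock = 720,
                     G_recent = c(g, g), v_now = 0, iob = 0,
                     iob_required = (g - cfg$gref) / 45)
    expect_gte(sol$command, 0)
    expect_lte(sol$command, bound + 1e-12)
  }
  # extreme hyperglycemia drives the command to the bound itself
  xh <- rep(400 - cfg$gref, 3)
  sol <- mpc_solve(xh, 0.1, 0.4, cfg, m, clock = 720, G_recent = c(400, 400),
                   v_now = 0, iob = 0, iob_required = (400 - cfg$gref) / 45)
  expect_equal(sol$command, 0.4, tolerance = 1e-9)
})
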