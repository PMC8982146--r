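test_that("endogenous glucose production follows the clamped linear form", {
  p <- plant_params()
  expect_equal(egp_rate(0, 0, 0, p), p[["kp1"]])
  # large liver action drives the linear form negative -> clamped at 0
  expect_equal(egp_rate(0, 1e6, 0, p), 0)
  # hand evaluation of the linear form
  ph <- plant_params(kp1 = 3, kp2 = 0.01, kp3 = 0.005)
  expect_equal(egp_rate(150, 40, 0, ph), 3 - 0.01 * 150 - 0.005 * 40)
  expect_equal(egp_rate(150, 40, 0, ph), 1.3)
})

test_that("insulin-dependent utilization is Michaelis-Menten in tissue glucose", {
  p <- plant_params()
  gt <- 130
  expect_equal(uid_rate(0, gt, 57, p), p[["Vm0"]] * gt / (p[["Km0"]] + gt))
  expect_equal(uid_rate(5, 0, 0, p), 0)
  ph <- plant_params(Vm0 = 2, Vmx = 0.05, r1 = 0)
  expect_equal(uid_rate(10, ph[["Km0"]], 0, ph), (2 + 0.5) * 0.5)
  expect_error(uid_rate(0, -1, 0, p), "non-negative")
})

test_that("hypoglycemia risk is one-sided and monotone below its reference", {
  expect_equal(risk_value(180), 0)
  expect_equal(risk_value(115), 0)
  expect_gt(risk_value(60), risk_value(80))
  expect_gt(risk_value(80), 0)
  g <- seq(40, 110, by = 5)
  expect_true(all(diff(risk_value(g)) < 0))
  expect_error(risk_value(0), "positive")
  expect_error(risk_value(-5), "positive")
})

test_that("R and compiled derivatives agree on random states", {
  p <- plant_params()
  set.seed(3)
  for (i in 1:25) {
    s <- plant_state(Gp = runif(1, 50, 700), Gt = runif(1, 20, 400),
                     X = rnorm(1, 0, 30), XL = rnorm(1, 0, 30),
                     Isc1 = runif(1, 0, 5000), Isc2 = runif(1, 0, 5000),
                     Ip = runif(1, 0, 500), Qsto1 = runif(1, 0, 4e4),
                     Qsto2 = runif(1, 0, 4e4), Qgut = runif(1, 0, 4e4))
    u <- runif(1, 0, 0.1); g <- runif(1, 0, 2)
    expect_equal(unname(plant_derivatives(s, u, g, p)),
                 as.numeric(apzone:::cpp_plant_deriv(as.numeric(s), u, g,
                                                     as.numeric(p))),
                 tolerance = 1e-12)
  }
})

test_that("the titrated-basal steady state is an equilibrium of the ODE", {
  s <- test_subject()
  eq <- plant_equilibrium(s$params, 1.2)
  d <- plant_derivatives(eq, 1.2 / 60, 0, s$params)
  expect_lt(max(abs(d)), 1e-7)
  # and the constructed subject sits exactly at its nominal fasting value
  expect_equal(plasma_glucose(eq, s$params), s$fasting, tolerance = 1e-6)
})

test_that("insulin PK chain conserves delivered insulin", {
  s <- test_subject()
  B <- 4  # units
  st <- plant_state(Gp = 200, Gt = 150, Isc1 = 1000 * B)
  out <- plant_step(st, 0, 0, s$params, 10 * 60, 1)
  remaining <- (out[["Isc1"]] + out[["Isc2"]]) / 1000
  expect_lt(remaining / B, 0.01)  # all but <1% has appeared in plasma by 10 h
})

test_that("gut chain conserves ingested carbohydrate", {
  s <- test_subject()
  M <- 40  # grams
  st <- plant_state(Gp = 200, Gt = 150, Qsto1 = 1000 * M)
  out <- plant_step(st, 0, 0, s$params, 10 * 60, 1)
  remaining <- (out[["Qsto1"]] + out[["Qsto2"]] + out[["Qgut"]]) / 1000
  expect_lt(remaining / M, 0.01)  # appeared in plasma to within 1% at 10 h
})

test_that("fixed-step integration is accurate and guards its inputs", {
  s <- test_subject()
  eq <- plant_equilibrium(s$params, 1.2)
  # a 5-min step at equilibrium leaves the state unchanged
  out <- plant_step(eq, 1.2 / 60, 0, s$params, 5, 1)
  expect_equal(as.numeric(out), as.numeric(eq), tolerance = 1e-9)
  # step-size refinement: halving h changes the 25-h endpoint by < 0.5 mg/dL
  st <- eq; st[["Qsto1"]] <- 40000  # a meal makes the trajectory non-trivial
  e1 <- plant_step(st, 1.2 / 60, 0, s$params, 25 * 60, 1)
  e2 <- plant_step(st, 1.2 / 60, 0, s$params, 25 * 60, 0.5)
  expect_lt(abs(plasma_glucose(e1, s$params) - plasma_glucose(e2, s$params)),
            0.5)
  expect_error(plant_step(eq, 0.1, 0, s$params, -5), "positive")
  expect_error(plant_step(eq, -0.1, 0, s$params, 5), "non-negative")
  expect_error(plant_derivatives(eq, 0, -1, s$params), "non-negative")
})

test_that("without insulin, glucose is eventually non-decreasing", {
  s <- test_subject()
  eq <- plant_equilibrium(s$params, 1.2)
  run <- apzone:::cpp_plant_run(as.numeric(eq), 0, 0, as.numeric(s$params),
                                12 * 60, 1, 5)
  late <- run$G[73:length(run$G)]   # after 6 h of washout
  expect_true(all(diff(late) > -1e-6))
})

test_that("reduced insulin sensitivity never lowers open-loop mean glucose", {
  for (sub in test_cohort(3)) {
    eq <- plant_equilibrium(sub$params, basal_at(sub$treatment, 0))
    mod <- apply_sensitivity_modifiers(sub, -0.4, -0.4)
    # same state, same insulin delivery, weaker action
    g_nom <- apzone:::cpp_plant_run(as.numeric(eq),
      basal_at(sub$treatment, 0) / 60, 0, as.numeric(sub$params), 24 * 60, 1, 5)
    g_mod <- apzone:::cpp_plant_run(as.numeric(eq),
      basal_at(sub$treatment, 0) / 60, 0, as.numeric(mod$params), 24 * 60, 1, 5)
    expect_gte(mean(g_mod$G), mean(g_nom$G))
  }
})
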