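# shared fixtures, built once per test run

# deterministic default subject (no sampling involved)
test_subject <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_subject("T01")
    cache
  }
})

# small seeded cohort for cohort-level checks
test_cohort <- local({
  cache <- NULL
  function(n = 3) {
    if (is.null(cache) || length(cache) < n)
      cache <<- generate_cohort(n, seed = 11)
    structure(cache[seq_len(n)], class = "ap_cohort")
  }
})

quiet_cgm <- function() cgm_config(noise = "off")

# exhaustive plan enumeration over the box [lb, ub]^nu on a coarse grid,
# refined locally; the independent oracle for the MPC solver. Predictions
# are generated with predict_glucose() and scored with evaluate_cost() --
# the R reference path, not the compiled solver.
brute_force_cost <- function(xhat, model, config, lb, ub, clock = 720,
                             G_recent = NULL, v_now = 0, iob = 0,
                             iob_required = Inf, step = 0.01,
                             refine = 5e-4) {
  nu <- config$nu
  stopifnot(nu == 2)
  if (is.null(G_recent)) {
    Gk <- xhat[3] + config$gref
    G_recent <- c(Gk, Gk)
  }
  cost_of <- function(u1, u2) {
    pred <- predict_glucose(model, xhat, c(u1, u2), config$np, config$gref)
    evaluate_cost(c(u1, u2), pred, iob, config, clock, G_recent = G_recent,
                  v_now = v_now, iob_required = iob_required)
  }
  best <- Inf; best_u <- c(0, 0)
  for (u1 in seq(lb[1], ub[1], by = step)) for (u2 in seq(lb[2], ub[2], by = step)) {
    J <- cost_of(u1, u2)
    if (J < best) { best <- J; best_u <- c(u1, u2) }
  }
  g1 <- seq(max(lb[1], best_u[1] - step), min(ub[1], best_u[1] + step), by = refine)
  g2 <- seq(max(lb[2], best_u[2] - step), min(ub[2], best_u[2] + step), by = refine)
  for (u1 in g1) for (u2 in g2) {
    J <- cost_of(u1, u2)
    if (J < best) { best <- J; best_u <- c(u1, u2) }
  }
  list(cost = best, u = best_u)
}

# synthetic trajectory for metric tests: constant or supplied glucose
fake_trajectory <- function(cgm, hours = 25, start_clock = 420,
                            meals_at = c(60, 360, 720)) {
  n <- hours * 12
  times <- (seq_len(n) - 1) * 5
  cgm <- rep_len(cgm, n)
  meal <- numeric(n)
  meal[times %in% meals_at] <- 40
  traj <- data.frame(time = times, clock = start_clock + times, G = cgm,
                     cgm = cgm, u = 0.1, u_basal = 0.1, bound = NA_real_,
                     bolus = 0, meal = meal)
  attr(traj, "meta") <- list(subject = "F01", scenario = "fake",
                             preset = "fake", seed = 0, start_clock = start_clock,
                             closed_start = 60, noise = "off")
  class(traj) <- c("ap_trajectory", "data.frame")
  traj
}
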