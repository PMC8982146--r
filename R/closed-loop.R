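#' Run one 25-hour closed-loop experiment
#'
#' Simulates a subject under a scenario with a controller preset: the first
#' hour runs open loop at the scenario basal, then the zone-MPC closes the
#' loop at 5-minute steps for 24 hours. Meals follow the scenario's meal
#' plan; meal (and conditional correction) boluses are user events computed
#' from the CGM reading at bolus time; no rescue carbohydrates are given.
#' The simulation clock starts at 07:00 so the day contains the 08:00,
#' 13:00 and 19:00 meals and a next-morning 06:00--07:00 fasting window.
#'
#' @param subject a `virtual_subject`.
#' @param scenario an `ap_scenario` (see [load_scenario()]).
#' @param preset a [controller_preset()] (or a list with `controller` and
#'   `bolus` entries).
#' @param seed integer seed controlling CGM noise.
#' @param cgm a [cgm_config()].
#' @param hours simulation duration (default 25).
#' @param start_clock clock time at simulation start, minutes after
#'   midnight (default 07:00).
#' @return an `ap_trajectory`: data.frame with one row per 5-min step
#'   (`time` sim minutes, `clock`, `G` plasma mg/dL, `cgm`, `u` commanded
#'   insulin U/step, `u_basal` U/step, `bound` the active delivery bound (NA
#'   during the open-loop hour), `bolus` U, `meal` grams) with the dose
#'   history and run metadata as attributes.
#' @export
run_closed_loop <- function(subject, scenario, preset, seed = 1,
                            cgm = cgm_config(), hours = 25,
                            start_clock = 420) {
  with_seed(seed, run_closed_loop_impl(subject, scenario, preset, cgm,
                                       hours, start_clock, seed))
}

run_closed_loop_impl <- function(subject, scenario, preset, cgm, hours,
                                 start_clock, seed) {
  ctl <- preset$controller
  bol <- preset$bolus
  mod <- apply_sensitivity_modifiers(subject, scenario$dvmx, scenario$dkp3)
  params <- mod$params

  basal_h <- switch(scenario$basal_mode,
    nominal = basal_at(subject$treatment, 0),
    scaled = basal_at(subject$treatment, 0) * scenario$basal_scale,
    b90 = titrate_basal(subject, 90, params = subject$params),
    b170 = titrate_basal(subject, 170, params = subject$params),
    stop("unknown basal mode: ", scenario$basal_mode))
  cr <- subject$treatment$CR * scenario$cr_scale
  cf <- subject$treatment$CF * scenario$cf_scale
  basal_step <- basal_h * 5 / 60

  state <- plant_equilibrium(params, basal_h)
  if (!is.na(scenario$g0)) {
    Gp <- scenario$g0 * params[["VG"]]
    f <- function(Gt) params[["k1"]] * Gp - params[["k2"]] * Gt -
      uid_rate(state[["X"]], Gt, risk_value(max(scenario$g0, 1)), params)
    hi <- max(params[["k1"]] * Gp / params[["k2"]], 1) + 1
    Gt <- if (f(hi) < 0) uniroot(f, c(0, hi), tol = 1e-8)$root else hi
    state[["Gp"]] <- Gp
    state[["Gt"]] <- Gt
  }

  model <- build_prediction_model(subject$tdi, 5)

  n <- as.integer(hours * 12)
  times <- (seq_len(n) - 1L) * 5
  meals_t <- scenario$meals$times - start_clock
  meals_t <- ifelse(meals_t < 0, meals_t + 1440, meals_t)
  if (length(meals_t)) meals_t[1] <- meals_t[1] + scenario$meals$first_meal_delay
  bolus_t <- meals_t - scenario$meals$advance_bolus
  grams <- scenario$meals$grams

  # dose history (preallocated)
  max_d <- n + length(bolus_t)
  d_time <- numeric(max_d); d_amt <- numeric(max_d); d_user <- logical(max_d)
  nd <- 0L
  curves <- lapply(setNames(ctl$mu_hours, ctl$mu_hours), decay_curve,
                   shape = ctl$curve_shape)
  lambda_curve <- decay_curve(ctl$lambda_hours, ctl$curve_shape)
  iob_at <- function(now, G) {
    if (!nd) return(0)
    idx <- seq_len(nd)
    el <- now - d_time[idx]
    us <- d_user[idx]
    tot <- 0
    if (any(us))
      tot <- tot + sum(d_amt[idx][us] * fraction_remaining(lambda_curve, el[us]))
    if (any(!us)) {
      cm <- curves[[as.character(micro_curve_length(G, ctl))]]
      tot <- tot + sum(d_amt[idx][!us] * fraction_remaining(cm, el[!us]))
    }
    tot
  }

  G_out <- numeric(n); cgm_out <- numeric(n); u_out <- numeric(n)
  bol_out <- numeric(n); meal_out <- numeric(n); bound_out <- rep(NA_real_, n)
  noise <- 0
  xhat <- NULL
  last_user <- -Inf
  closed_start <- 60

  for (k in seq_len(n)) {
    t <- times[k]
    clock <- start_clock + t
    G <- state[["Gp"]] / params[["VG"]]
    G_out[k] <- G

    mi <- which(meals_t == t)
    if (length(mi)) {
      state[["Qsto1"]] <- state[["Qsto1"]] + 1000 * sum(grams[mi])
      meal_out[k] <- sum(grams[mi])
    }

    sm <- cgm_sample(G, noise, cgm)
    noise <- sm$noise
    y_cgm <- sm$reading
    cgm_out[k] <- y_cgm

    bi <- which(bolus_t == t)
    if (length(bi)) {
      amt <- total_user_bolus(sum(grams[bi]), cr, cf, y_cgm, t, last_user, bol)
      if (amt > 0) {
        state[["Isc1"]] <- state[["Isc1"]] + 1000 * amt
        nd <- nd + 1L
        d_time[nd] <- t; d_amt[nd] <- amt; d_user[nd] <- TRUE
        last_user <- t
        bol_out[k] <- amt
      }
    }

    if (t >= closed_start) {
      y <- y_cgm - ctl$gref
      if (is.null(xhat)) xhat <- rep(y, 3)
      iob <- iob_at(t, y_cgm)
      iob_req <- (y_cgm - ctl$gref) / cf
      bound <- insulin_bounds(clock, basal_step, y_cgm, iob, cf, ctl)
      bound_out[k] <- bound
      Gm2 <- if (k > 2) cgm_out[k - 2] else y_cgm
      Gm1 <- if (k > 1) cgm_out[k - 1] else y_cgm
      v_now <- (y_cgm - Gm2) / 10
      sol <- mpc_solve(xhat, basal_step, bound, ctl, model, clock,
                       G_recent = c(Gm1, y_cgm), v_now = v_now,
                       iob = iob, iob_required = iob_req)
      u <- sol$command
      xhat <- observe(xhat, u - basal_step, y, model)
      nd <- nd + 1L
      d_time[nd] <- t; d_amt[nd] <- u - basal_step; d_user[nd] <- FALSE
    } else {
      u <- basal_step
    }
    u_out[k] <- u
    state <- plant_step(state, u / 5, 0, params, 5, 1)
  }

  traj <- data.frame(time = times, clock = start_clock + times,
                     G = G_out, cgm = cgm_out, u = u_out,
                     u_basal = basal_step, bound = bound_out,
                     bolus = bol_out, meal = meal_out)
  idx <- seq_len(nd)
  attr(traj, "doses") <- dose_records(d_time[idx], d_amt[idx],
                                      ifelse(d_user[idx], "user", "micro"))
  attr(traj, "meta") <- list(subject = subject$id, scenario = scenario$id,
                             preset = preset$name, seed = seed,
                             basal_h = basal_h, cr = cr, cf = cf,
                             tdi_nominal = subject$tdi,
                             start_clock = start_clock,
                             closed_start = closed_start,
                             noise = cgm$noise)
  class(traj) <- c("ap_trajectory", "data.frame")
  traj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a replicated experiment grid
#'
#' Cartesian product of scenarios, presets, subjects and replicates; each
#' cell gets a seed derived deterministically from the master seed, so a
#' rerun is bit-identical. By default only the per-run glycemic metrics are
#' kept; trajectories can be streamed to a directory as CSV.
#'
#' @param scenarios character vector of scenario ids, or list of
#'   `ap_scenario`.
#' @param presets character vector of preset names, or list of presets.
#' @param cohort an `ap_cohort` (or list of subjects).
#' @param replicates replicate count per cell, `>= 1`.
#' @param seed master seed.
#' @param cgm a [cgm_config()].
#' @param out_dir optional directory to stream trajectory CSVs into.
#' @return data.frame of class `ap_results`: one row per run with the
#'   metrics of [glycemic_metrics()].
#' @export
run_experiment <- function(scenarios, presets, cohort, replicates = 1,
                           seed = 1, cgm = cgm_config(), out_dir = NULL) {
  if (replicates < 1) stop("replicates must be >= 1")
  if (is.character(scenarios)) scenarios <- lapply(scenarios, load_scenario)
  if (is.character(presets)) presets <- lapply(presets, controller_preset)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- list()
  r <- 0L
  for (si in seq_along(scenarios)) for (pi in seq_along(presets))
    for (ci in seq_along(cohort)) for (rep in seq_len(replicates)) {
      rs <- derive_seed(seed, si, pi, ci, rep)
      traj <- run_closed_loop(cohort[[ci]], scenarios[[si]], presets[[pi]],
                              seed = rs, cgm = cgm)
      m <- glycemic_metrics(traj)
      meta <- attr(traj, "meta")
      r <- r + 1L
      rows[[r]] <- cbind(data.frame(subject = meta$subject,
                                    scenario = meta$scenario,
                                    preset = meta$preset,
                                    replicate = rep, seed = rs,
                                    stringsAsFactors = FALSE),
                         as.data.frame(unclass(m)))
      if (!is.null(out_dir))
        write_trajectory(traj, file.path(out_dir,
          sprintf("%s_%s_%s_r%02d.csv", meta$scenario, meta$preset,
                  meta$subject, rep)))
    }
  out <- do.call(rbind, rows)
  class(out) <- c("ap_results", "data.frame")
  out
}
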