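#' Per-step insulin delivery upper bound
#'
#' Combines the pump limit -- four times the per-step basal inside the
#' daytime delivery window, 1 U otherwise -- with the insulin-on-board
#' limit: delivery may exceed basal only while the on-board insulin is below
#' `IOB_required = (G - Gref)/CF`, the amount estimated to bring glucose back
#' to the reference.
#'
#' @param clock time of day, minutes after midnight.
#' @param basal_step basal amount per 5-min step, U.
#' @param G current glucose, mg/dL.
#' @param iob insulin on board, U.
#' @param cf correction factor, mg/dL per U, `> 0`.
#' @param config a [controller_config()].
#' @return upper bound on total delivery this step, U (`>= 0`).
#' @export
#' @examples
#' cfg <- controller_config()
#' insulin_bounds(720, 0.1, 400, 0, 45, cfg)   # 0.4 (4 x basal, daytime)
#' insulin_bounds(120, 0.1, 400, 0, 45, cfg)   # 1 (night-time pump limit)
insulin_bounds <- function(clock, basal_step, G, iob, cf, config) {
  if (cf <= 0) stop("cf must be positive")
  if (basal_step < 0) stop("basal_step must be non-negative")
  tau <- clock %% 1440
  u_ub <- if (tau > config$delivery_window[1] && tau < config$delivery_window[2])
    4 * basal_step else 1
  iob_req <- (G - config$gref) / cf
  u_iob <- if (iob_req > iob) iob_req - iob + basal_step else basal_step
  max(0, min(u_ub, u_iob))
}

#' Solve one zone-MPC step
#'
#' Minimizes [evaluate_cost()] over the differential insulin plan subject to
#' the prediction-model dynamics, per-step total delivery in `[0, bounds]`,
#' and zero input beyond the control horizon. The cost is convex and
#' piecewise quadratic; it is minimized by a deterministic two-metric
#' projected Newton method (compiled), and only the first planned input is
#' applied.
#'
#' @param xhat 3-vector state estimate (differential glucose, mg/dL).
#' @param basal basal amounts per step over the control horizon, U
#'   (scalar recycled).
#' @param bounds per-step total delivery upper bounds, U (scalar recycled).
#' @param config a [controller_config()].
#' @param model a [build_prediction_model()].
#' @param clock time of day, minutes after midnight.
#' @param G_recent `c(G(k-1), G(k))` measured glucose history; defaults to
#'   the flat extension of the current estimate.
#' @param v_now current measured velocity, mg/dL/min.
#' @param iob insulin on board, U.
#' @param iob_required insulin required to reach the reference, U.
#' @return list with `plan` (differential, U per step), `command`
#'   (`plan[1] + basal[1]`, total U this step) and `cost`.
#' @export
mpc_solve <- function(xhat, basal, bounds, config, model, clock = 720,
                      G_recent = NULL, v_now = 0, iob = 0,
                      iob_required = Inf) {
  nu <- config$nu
  basal <- rep_len(basal, nu)
  bounds <- rep_len(bounds, nu)
  if (any(bounds < 0)) stop("bounds must be non-negative")
  if (is.null(G_recent)) {
    Gk <- xhat[3] + config$gref
    G_recent <- c(Gk, Gk)
  }
  zone <- active_zone(config, clock)
  Qw <- q_weight(v_now, iob, iob_required, config)
  Dh <- dhat(G_recent[2], config)
  lb <- -basal
  ub <- pmax(bounds - basal, lb)    # infeasible-free: ub >= lb always
  sol <- cpp_mpc_solve(as.numeric(xhat), model$a[1], model$a[2], model$a[3],
                       model$b, config$gref, config$np, nu,
                       zone[1], zone[2], Qw, Dh,
                       config$r_plus, config$r_minus,
                       G_recent[2], G_recent[1], lb, ub)
  list(plan = sol$u, command = sol$u[1] + basal[1], cost = sol$cost)
}
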