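#' One-sided seminorm
#'
#' `max(0, x)` -- the building block of the asymmetric zone cost: squared, it
#' penalizes only deviations of one sign.
#'
#' @param x numeric.
#' @return `pmax(0, x)`.
#' @export
seminorm <- function(x) pmax(0, x)

#' Two-step glucose velocity
#'
#' Glucose change over two 5-minute steps, in mg/dL per minute.
#'
#' @param G_next2 glucose two steps ahead, mg/dL.
#' @param G_now current glucose, mg/dL.
#' @return `(G_next2 - G_now) / 10`.
#' @export
velocity <- function(G_next2, G_now) (G_next2 - G_now) / 10

#' Velocity penalty multiplier
#'
#' Returns `D` when glucose lies inside the velocity band `[G-v, G+v]`, else
#' 1: rising glucose is penalized more heavily inside the band, while above
#' it the zone cost already dominates.
#'
#' @param G current glucose, mg/dL.
#' @param config a [controller_config()].
#' @return `D` or 1.
#' @export
dhat <- function(G, config) {
  if (!is.finite(G)) stop("G must be finite")
  if (G >= config$vel_band[1] && G <= config$vel_band[2]) config$D else 1
}

#' Above-zone weight table Q(v, IOB)
#'
#' Persistent hyperglycemia -- glucose drifting rather than spiking, with
#' less insulin on board than the correction the current glucose calls for --
#' receives the large weight `q_high`; otherwise the above-zone weight is 1.
#' This shaping is shared by all presets.
#'
#' @param v current glucose velocity, mg/dL per min.
#' @param iob insulin on board, U.
#' @param iob_required insulin required to return to reference, U
#'   (`(G - Gref)/CF`); `Inf` disables the IOB condition.
#' @param config a [controller_config()].
#' @return scalar weight.
#' @export
q_weight <- function(v, iob, iob_required, config) {
  if (abs(v) <= config$q_vel_thresh && iob < iob_required) config$q_high else 1
}

#' Zone-MPC stage cost
#'
#' `J = J1 + J2 + J3`: squared one-sided zone deviations (above-zone term
#' weighted by the Q table), the one-sided rising-velocity penalty weighted
#' by [dhat()], and asymmetric input deviations from basal
#' (`R+ seminorm(u)^2 + R- seminorm(-u)^2`). The zone is the day or night
#' pair active at `clock`.
#'
#' @param plan differential insulin plan, U per step, length `nu`.
#' @param predictions predicted glucose sequence over the prediction horizon,
#'   mg/dL, length `np`.
#' @param iob current insulin on board, U.
#' @param config a [controller_config()].
#' @param clock time of day, minutes after midnight.
#' @param G_recent `c(G(k-1), G(k))`, the last two measured glucose values
#'   used by the first velocity terms; defaults to a flat extension of the
#'   first prediction.
#' @param v_now current measured glucose velocity (mg/dL/min) for the Q
#'   table.
#' @param iob_required insulin required to reach the reference, U.
#' @return scalar cost.
#' @export
#' @examples
#' cfg <- controller_config()
#' flat <- rep(100, cfg$np)  # inside the day zone
#' evaluate_cost(c(1, 0, 0, 0, 0), flat, 0, cfg, 720)   # 6500
#' evaluate_cost(c(-1, 0, 0, 0, 0), flat, 0, cfg, 720)  # 100
evaluate_cost <- function(plan, predictions, iob, config, clock,
                          G_recent = NULL, v_now = 0, iob_required = Inf) {
  if (length(plan) != config$nu) stop("plan must have length nu")
  if (length(predictions) != config$np) stop("predictions must have length np")
  if (is.null(G_recent)) G_recent <- rep(predictions[1], 2)
  zone <- active_zone(config, clock)
  Qw <- q_weight(v_now, iob, iob_required, config)
  Dh <- dhat(G_recent[2], config)

  J1 <- sum(seminorm(zone[1] - predictions)^2) +
    Qw * sum(seminorm(predictions - zone[2])^2)
  ext <- c(G_recent, predictions)              # indices j-2 via offset 2
  vel <- (predictions - ext[seq_along(predictions)]) / 10
  J2 <- Dh * sum(seminorm(vel)^2)
  J3 <- config$r_plus * sum(seminorm(plan)^2) +
    config$r_minus * sum(seminorm(-plan)^2)
  J1 + J2 + J3
}

#' Open-loop glucose predictions of the controller model
#'
#' Rolls the prediction model forward from a state estimate under a
#' differential insulin plan (zero beyond the control horizon) and returns
#' the predicted glucose at steps 1..np.
#'
#' @param model a [build_prediction_model()].
#' @param xhat 3-vector state estimate (differential glucose).
#' @param plan differential insulin plan, U per step.
#' @param np prediction horizon.
#' @param gref reference glucose, mg/dL.
#' @return numeric vector of length `np`, mg/dL.
#' @export
predict_glucose <- function(model, xhat, plan, np, gref) {
  x <- as.numeric(xhat)
  out <- numeric(np)
  for (j in seq_len(np)) {
    u <- if (j <= length(plan)) plan[j] else 0
    x <- as.numeric(model$A %*% x) + as.numeric(model$B) * u
    out[j] <- x[3] + gref
  }
  out
}
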