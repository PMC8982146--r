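#' Build the controller's third-order prediction model
#'
#' Discrete transfer model from differential insulin (U per step, relative to
#' basal) to differential glucose (mg/dL, relative to the reference), with
#' fixed stable poles (0.96, 0.93, 0.93 per 5-min step) and a steady-state
#' gain of `-1800/tdi` mg/dL per U -- the 1800 rule, so the unit-insulin
#' glucose drop scales inversely with total daily insulin. The state is the
#' three-step window of differential glucose values
#' `x(k) = (G(k+2), G(k+1), G(k)) - Gref` in companion form; the output map C
#' selects the current value. The observer gain L places the observer poles
#' at 0.5 (Ackermann), giving a stable Luenberger estimator.
#'
#' @param tdi total daily insulin, U/day, `> 0`.
#' @param ts sampling interval in minutes (default 5).
#' @param poles the three plant poles per step (first applied once, second
#'   twice), all in (0, 1).
#' @param obs_poles desired observer poles, magnitudes < 1.
#' @return object of class `prediction_model`: list with `A`, `B`, `C`, `L`,
#'   `Ts`, the companion coefficients `a`, input gain `b` and `gain`
#'   (steady-state mg/dL per U).
#' @export
#' @examples
#' m40 <- build_prediction_model(40)
#' m80 <- build_prediction_model(80)
#' m40$gain / m80$gain  # 2: inverse-TDI scaling
build_prediction_model <- function(tdi, ts = 5, poles = c(0.96, 0.93),
                                   obs_poles = rep(0.5, 3)) {
  if (!is.numeric(tdi) || tdi <= 0) stop("tdi must be positive")
  stopifnot(all(poles > 0), all(poles < 1), all(abs(obs_poles) < 1))
  p1 <- poles[1]; p2 <- poles[2]
  a1 <- p1 + 2 * p2
  a2 <- -(2 * p1 * p2 + p2^2)
  a3 <- p1 * p2^2
  gain <- -1800 / tdi
  b <- gain * (1 - p1) * (1 - p2)^2
  A <- rbind(c(a1, a2, a3), c(1, 0, 0), c(0, 1, 0))
  B <- matrix(c(b, 0, 0), 3, 1)
  C <- matrix(c(0, 0, 1), 1, 3)
  L <- place_observer(A, C, obs_poles)
  structure(list(A = A, B = B, C = C, L = L, Ts = ts,
                 a = c(a1, a2, a3), b = b, gain = gain),
            class = "prediction_model")
}

## Ackermann pole placement for the observer gain
place_observer <- function(A, C, poles) {
  qA <- diag(3)
  for (p in poles) qA <- qA %*% (A - p * diag(3))
  M <- rbind(C, C %*% A, C %*% A %*% A)
  L <- qA %*% solve(M) %*% c(0, 0, 1)
  L
}

#' Luenberger observer update
#'
#' `xhat(k+1) = A xhat(k) + B u(k) + L (y(k) - C xhat(k))`.
#'
#' @param xhat current 3-vector state estimate (differential glucose).
#' @param u applied differential insulin input, U per step.
#' @param y measured differential glucose (CGM reading minus Gref).
#' @param model a [build_prediction_model()].
#' @return updated state estimate.
#' @export
observe <- function(xhat, u, y, model) {
  if (any(!is.finite(c(xhat, u, y)))) stop("observer inputs must be finite")
  as.numeric(model$A %*% xhat + model$B * u + model$L %*% (y - model$C %*% xhat))
}
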