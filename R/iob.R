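#' Insulin decay curve
#'
#' Fraction of a dose still active as a function of time since delivery:
#' 1 at time zero, 0 at the end of the curve, monotone non-increasing in
#' between. Two shapes are provided: `"linear"` (the default) and `"biexp"`,
#' a curvilinear two-parameter shape `(1 + t/tau) * exp(-t/tau)` rescaled to
#' reach zero at the stated duration.
#'
#' @param duration_hours curve length, hours, `> 0`.
#' @param shape `"linear"` or `"biexp"`.
#' @return object of class `decay_curve`.
#' @export
decay_curve <- function(duration_hours, shape = c("linear", "biexp")) {
  shape <- match.arg(shape)
  if (duration_hours <= 0) stop("duration must be positive")
  structure(list(duration = duration_hours * 60, shape = shape),
            class = "decay_curve")
}

#' Fraction of a dose remaining
#'
#' @param curve a [decay_curve()].
#' @param elapsed minutes since delivery, `>= 0`.
#' @return fraction in `[0, 1]`; 0 beyond the curve duration.
#' @export
#' @examples
#' fraction_remaining(decay_curve(4), 120)  # 0.5 on the linear curve
fraction_remaining <- function(curve, elapsed) {
  if (any(elapsed < 0)) stop("elapsed must be non-negative")
  d <- curve$duration
  frac <- switch(curve$shape,
    linear = pmax(0, 1 - elapsed / d),
    biexp = {
      tau <- d / 5                     # (1 + 5) e^-5 ~ 0.04 at the end
      raw <- (1 + elapsed / tau) * exp(-elapsed / tau)
      tail_v <- (1 + d / tau) * exp(-d / tau)
      pmax(0, (raw - tail_v) / (1 - tail_v))
    })
  ifelse(elapsed >= d, 0, frac)
}

#' Micro-bolus IOB curve length as a function of glucose
#'
#' The controller forgets its own micro-boluses faster when glucose is high
#' (shorter memory allows more assertive dosing) and slower when glucose is
#' low. The mapping is a non-increasing step table over glucose, bounded in
#' [2, 6] hours by the default breakpoints: `< 120 -> 6 h`,
#' `120--180 -> 4 h`, `>= 180 -> 2 h`.
#'
#' @param G glucose, mg/dL, `> 0`.
#' @param config a [controller_config()].
#' @return curve length in hours.
#' @export
micro_curve_length <- function(G, config) {
  if (G <= 0) stop("G must be positive")
  idx <- findInterval(G, config$mu_breaks) + 1L
  config$mu_hours[idx]
}

#' Dose history records
#'
#' @param time delivery times, minutes.
#' @param amount dose amounts, U: non-negative for user boluses; micro-bolus
#'   amounts are relative to basal and may be negative (suspensions).
#' @param kind `"user"` or `"micro"`.
#' @return data.frame of class `dose_records`.
#' @export
dose_records <- function(time = numeric(), amount = numeric(),
                         kind = character()) {
  stopifnot(length(time) == length(amount), length(time) == length(kind),
            all(kind %in% c("user", "micro")))
  if (any(amount[kind == "user"] < 0)) stop("user boluses must be non-negative")
  structure(data.frame(time = time, amount = amount, kind = kind,
                       stringsAsFactors = FALSE),
            class = c("dose_records", "data.frame"))
}

#' Insulin on board
#'
#' Sum of the undecayed fractions of past user boluses (fixed-length
#' `lambda` curve) and of past controller micro-boluses relative to basal
#' (glucose-dependent `mu` curve, evaluated at the glucose at calculation
#' time). Because micro-doses are relative to basal, sustained suspensions
#' can make the micro component -- and thus the total -- negative; the
#' user-bolus component is always non-negative.
#'
#' @param history a [dose_records()] with times `<= now`.
#' @param now current time, minutes.
#' @param G current glucose, mg/dL (selects the micro-curve length).
#' @param config a [controller_config()].
#' @return insulin on board, U.
#' @export
#' @examples
#' h <- dose_records(0, 4, "user")
#' compute_iob(h, 0, 120, controller_config())                   # 4
#' compute_iob(h, 4 * 60, 120, controller_config())              # 0
compute_iob <- function(history, now, G, config) {
  if (!nrow(history)) return(0)
  if (any(history$time > now + 1e-9)) stop("dose history contains future-dated records")
  elapsed <- now - history$time
  user <- history$kind == "user"
  iob <- 0
  if (any(user)) {
    cu <- decay_curve(config$lambda_hours, config$curve_shape)
    iob <- iob + sum(history$amount[user] * fraction_remaining(cu, elapsed[user]))
  }
  if (any(!user)) {
    cm <- decay_curve(micro_curve_length(G, config), config$curve_shape)
    iob <- iob + sum(history$amount[!user] * fraction_remaining(cm, elapsed[!user]))
  }
  iob
}
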