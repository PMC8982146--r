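#' Feed-forward meal bolus
#'
#' Carbohydrates over the carbohydrate ratio, reduced by the factor `alpha`
#' when meal-time glucose is at or below the full-bolus threshold `Gm` (the
#' full-bolus branch requires strictly `G > Gm`).
#'
#' @param M carbohydrate amount, grams, `>= 0`.
#' @param cr carbohydrate ratio, g/U, `> 0`.
#' @param G glucose at bolus time, mg/dL.
#' @param config a [bolus_config()].
#' @return bolus in U.
#' @export
#' @examples
#' meal_bolus(40, 10, 150, bolus_config())  # 4
#' meal_bolus(40, 10, 120, bolus_config())  # 3.2: boundary takes the reduced branch
meal_bolus <- function(M, cr, G, config) {
  if (cr <= 0) stop("cr must be positive")
  if (M < 0) stop("M must be non-negative")
  if (G > config$gm) M / cr else config$alpha * M / cr
}

#' Conditional correction bolus
#'
#' `min(cap, (G - Gref_corr)/CF)` when glucose is at or above the correction
#' threshold `tau_c` and more than `delta_min` minutes have passed since the
#' last user-requested bolus; otherwise zero. Never negative (the
#' configuration enforces `Gref_corr <= tau_c`).
#'
#' @param G glucose, mg/dL.
#' @param cf correction factor, mg/dL per U, `> 0`.
#' @param t current time, minutes.
#' @param last_user_bolus_time time of the previous user bolus, minutes
#'   (`-Inf` if none).
#' @param config a [bolus_config()].
#' @return correction bolus in U.
#' @export
#' @examples
#' correction_bolus(400, 30, 300, 0, bolus_config())  # 2: capped
#' correction_bolus(400, 30, 119, 0, bolus_config())  # 0: within the lockout
correction_bolus <- function(G, cf, t, last_user_bolus_time, config) {
  if (cf <= 0) stop("cf must be positive")
  eligible <- G >= config$tau_c && (t - last_user_bolus_time) > config$delta_min
  if (!eligible) return(0)
  max(0, min(config$cap, (G - config$gref_corr) / cf))
}

#' Total user-requested bolus
#'
#' Meal bolus plus the conditional correction bolus.
#'
#' @inheritParams meal_bolus
#' @inheritParams correction_bolus
#' @param last_time time of the previous user bolus, minutes.
#' @return total bolus in U.
#' @export
total_user_bolus <- function(M, cr, cf, G, t, last_time, config) {
  meal_bolus(M, cr, G, config) + correction_bolus(G, cf, t, last_time, config)
}
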