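#' Zone-MPC controller configuration
#'
#' All tunable feedback parameters of the zone controller. Defaults are the
#' baseline (non-pregnancy) design; see [controller_preset()] for the three
#' shipped presets.
#'
#' @param np prediction horizon in steps (default 9, i.e. 45 min).
#' @param nu control horizon in steps (default 5, i.e. 25 min).
#' @param zone_day,zone_night target zones `c(GZL, GZH)` in mg/dL.
#' @param zone_window clock window `c(T1, T2)` in minutes after midnight
#'   during which the daytime zone applies (default 06:00--22:00).
#' @param delivery_window clock window for the 4x-basal pump limit; outside
#'   it the per-step limit is 1 U (default equal to `zone_window`).
#' @param gref reference glucose, mg/dL.
#' @param vel_band glucose band `c(G-v, G+v)` in which rising glucose incurs
#'   the extra velocity penalty `D`.
#' @param D velocity penalty multiplier, `>= 1`.
#' @param r_plus,r_minus input-deviation weights above/below basal
#'   (6500 / 100).
#' @param q_high above-zone weight applied when hyperglycemia is persistent:
#'   small current velocity magnitude (`<= q_vel_thresh`) with insulin on
#'   board below the required amount; otherwise the weight is 1. Kept
#'   identical across presets.
#' @param q_vel_thresh velocity-magnitude threshold (mg/dL per min) for
#'   "persistent" hyperglycemia in the Q table.
#' @param lambda_hours user-bolus IOB decay-curve length, h.
#' @param mu_breaks,mu_hours glucose breakpoints (mg/dL) and curve lengths
#'   (h) for the glucose-dependent micro-bolus IOB curve; `mu_hours` has one
#'   more entry than `mu_breaks` and must be non-increasing.
#' @param curve_shape IOB decay-curve shape, `"linear"` or `"biexp"`.
#' @param name label for reports.
#' @return object of class `controller_config`.
#' @export
controller_config <- function(np = 9, nu = 5,
                              zone_day = c(90, 120), zone_night = c(100, 120),
                              zone_window = c(360, 1320),
                              delivery_window = zone_window,
                              gref = 110, vel_band = c(140, 180), D = 10,
                              r_plus = 6500, r_minus = 100,
                              q_high = 500, q_vel_thresh = 1,
                              lambda_hours = 4,
                              mu_breaks = c(120, 180), mu_hours = c(6, 4, 2),
                              curve_shape = c("linear", "biexp"),
                              name = "baseline") {
  curve_shape <- match.arg(curve_shape)
  stopifnot(nu <= np, np >= 1, nu >= 1,
            zone_day[1] < zone_day[2], zone_night[1] < zone_night[2],
            vel_band[1] < vel_band[2], D >= 1,
            r_plus > 0, r_minus > 0, q_high >= 1, lambda_hours > 0,
            length(mu_hours) == length(mu_breaks) + 1,
            !is.unsorted(mu_breaks), all(diff(mu_hours) <= 0))
  structure(list(np = as.integer(np), nu = as.integer(nu),
                 zone_day = zone_day, zone_night = zone_night,
                 zone_window = zone_window, delivery_window = delivery_window,
                 gref = gref, vel_band = vel_band, D = D,
                 r_plus = r_plus, r_minus = r_minus,
                 q_high = q_high, q_vel_thresh = q_vel_thresh,
                 lambda_hours = lambda_hours,
                 mu_breaks = mu_breaks, mu_hours = mu_hours,
                 curve_shape = curve_shape, name = name),
            class = "controller_config")
}

#' Active target zone at a clock time
#' @param config a [controller_config()].
#' @param clock_min minutes after midnight.
#' @return `c(GZL, GZH)` for the day or night window.
#' @export
active_zone <- function(config, clock_min) {
  tau <- clock_min %% 1440
  if (tau > config$zone_window[1] && tau < config$zone_window[2])
    config$zone_day else config$zone_night
}

#' Meal and correction bolus configuration
#'
#' @param gm full-bolus glucose threshold, mg/dL: at or below it the meal
#'   bolus is reduced by `alpha`.
#' @param alpha bolus reduction factor in (0, 1].
#' @param tau_c glucose threshold for adding a correction bolus, mg/dL.
#' @param gref_corr correction target glucose, mg/dL (must be `<= tau_c`).
#' @param cap correction bolus cap, U (default 2).
#' @param delta_min minimum interval between user-requested boluses, minutes
#'   (default 120).
#' @return object of class `bolus_config`.
#' @export
bolus_config <- function(gm = 120, alpha = 0.8, tau_c = 150,
                         gref_corr = 150, cap = 2, delta_min = 120) {
  stopifnot(alpha > 0, alpha <= 1, tau_c > 0, cap > 0, delta_min >= 0,
            gref_corr <= tau_c)
  structure(list(gm = gm, alpha = alpha, tau_c = tau_c,
                 gref_corr = gref_corr, cap = cap, delta_min = delta_min),
            class = "bolus_config")
}

#' The three shipped controller presets
#'
#' * `baseline`: the standard adult zone-MPC design (day zone 90--120,
#'   night 100--120, Gref 110, velocity band 140--180, user-bolus IOB curve
#'   4 h, full-bolus threshold 120, correction threshold 150 toward 150).
#' * `zone_adjusted`: baseline with only the zones and reference lowered to
#'   pregnancy targets (day 80--110, night 80--100, Gref 90).
#' * `pregnancy`: the pregnancy-specific design -- zone-adjusted targets plus
#'   velocity band lowered to 120--180, user-bolus IOB curve 3 h, full-bolus
#'   threshold 70, correction threshold 100 toward 90.
#'
#' @param name preset name.
#' @return list with `controller` ([controller_config()]), `bolus`
#'   ([bolus_config()]) and `name`, of class `controller_preset`.
#' @export
#' @examples
#' controller_preset("pregnancy")$controller$zone_day
controller_preset <- function(name = c("baseline", "zone_adjusted", "pregnancy")) {
  name <- match.arg(name)
  preset <- switch(name,
    baseline = list(
      controller = controller_config(name = "baseline"),
      bolus = bolus_config()),
    zone_adjusted = list(
      controller = controller_config(zone_day = c(80, 110),
                                     zone_night = c(80, 100), gref = 90,
                                     name = "zone_adjusted"),
      bolus = bolus_config()),
    pregnancy = list(
      controller = controller_config(zone_day = c(80, 110),
                                     zone_night = c(80, 100), gref = 90,
                                     vel_band = c(120, 180),
                                     lambda_hours = 3, name = "pregnancy"),
      bolus = bolus_config(gm = 70, tau_c = 100, gref_corr = 90))
  )
  structure(c(preset, list(name = name)), class = "controller_preset")
}

#' Serialize / load a controller preset as YAML
#' @param preset a [controller_preset()] (or compatible list).
#' @param file path.
#' @export
write_preset <- function(preset, file) {
  doc <- list(name = preset$name,
              controller = unclass(preset$controller),
              bolus = unclass(preset$bolus))
  writeLines(yaml::as.yaml(doc, precision = 22), file)
  invisible(file)
}

#' @rdname write_preset
#' @export
read_preset <- function(file) {
  doc <- yaml::read_yaml(file)
  ctl <- do.call(controller_config, doc$controller)
  bol <- do.call(bolus_config, doc$bolus)
  structure(list(controller = ctl, bolus = bol, name = doc$name),
            class = "controller_preset")
}
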