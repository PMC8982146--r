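#' Percent time in a glucose range
#'
#' Inclusive at both endpoints; the matching below-range bin uses `G < lo`
#' and the above-range bin `G > hi`, so the three bins always partition.
#'
#' @param trace glucose series, mg/dL, non-empty.
#' @param lo,hi range bounds, mg/dL.
#' @return percent of samples with `lo <= G <= hi`.
#' @export
time_in_range <- function(trace, lo, hi) {
  if (!length(trace)) stop("empty glucose trace")
  100 * mean(trace >= lo & trace <= hi)
}

## metrics window: the closed-loop portion of the trajectory
.cl_window <- function(traj) {
  meta <- attr(traj, "meta")
  traj$time >= (meta$closed_start %||% 60)
}

#' Glycemic metrics report for one trajectory
#'
#' CGM-based metrics over the closed-loop portion of the run: the pregnancy
#' set (% time < 54, < 63, 63--140, > 140 mg/dL), the standard set (< 70,
#' 70--180, > 180, > 250), mean glucose, total daily insulin (all commanded
#' insulin in the closed-loop window plus user boluses), the overnight
#' fasting glucose (06:00--07:00 of day 2, `NA` when the run does not reach
#' it) and the pooled two-hour postprandial time in 63--140.
#'
#' @param traj an `ap_trajectory`.
#' @return list of class `metrics_report`.
#' @export
glycemic_metrics <- function(traj) {
  sel <- .cl_window(traj)
  g <- traj$cgm[sel]
  m <- list(
    below_54 = 100 * mean(g < 54),
    below_63 = 100 * mean(g < 63),
    tir_63_140 = time_in_range(g, 63, 140),
    above_140 = 100 * mean(g > 140),
    below_70 = 100 * mean(g < 70),
    tir_70_180 = time_in_range(g, 70, 180),
    above_180 = 100 * mean(g > 180),
    above_250 = 100 * mean(g > 250),
    mean_glucose = mean(g),
    tdi = sum(traj$u[sel]) + sum(traj$bolus),
    fasting = tryCatch(fasting_glucose(traj), error = function(e) NA_real_),
    pp_tir = postprandial_tir(traj)$pooled
  )
  structure(m, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("pregnancy set: <54 %.2f%% | <63 %.2f%% | 63-140 %.2f%% | >140 %.2f%%\n",
              x$below_54, x$below_63, x$tir_63_140, x$above_140))
  cat(sprintf("standard set:  <70 %.2f%% | 70-180 %.2f%% | >180 %.2f%% | >250 %.2f%%\n",
              x$below_70, x$tir_70_180, x$above_180, x$above_250))
  cat(sprintf("mean glucose %.1f mg/dL | fasting %.1f | postprandial TIR %.1f%% | TDI %.1f U\n",
              x$mean_glucose, x$fasting, x$pp_tir, x$tdi))
  invisible(x)
}

#' Overnight fasting glucose
#'
#' Mean CGM over the 06:00--07:00 window following the closed-loop night
#' (no food intake after the 19:00 dinner).
#'
#' @param traj an `ap_trajectory` covering that window.
#' @return fasting glucose, mg/dL.
#' @export
fasting_glucose <- function(traj) {
  meta <- attr(traj, "meta")
  start <- (24 * 60 - meta$start_clock) + 6 * 60
  sel <- traj$time >= start & traj$time < start + 60
  if (!any(sel)) stop("trajectory does not cover the day-2 06:00-07:00 fasting window")
  mean(traj$cgm[sel])
}

#' Two-hour postprandial time in range
#'
#' Time in 63--140 mg/dL over the window `(t_meal, t_meal + 120]` after each
#' meal, per meal and pooled. A window truncated by the end of the
#' trajectory is computed over the available samples and flagged.
#'
#' @param traj an `ap_trajectory`.
#' @param meal_times optional meal times (sim minutes); defaults to the
#'   meals recorded in the trajectory.
#' @return list with `per_meal` (data.frame: `meal_time`, `tir`,
#'   `truncated`) and `pooled` (percent over all windows).
#' @export
postprandial_tir <- function(traj, meal_times = NULL) {
  if (is.null(meal_times)) meal_times <- traj$time[traj$meal > 0]
  if (!length(meal_times))
    return(list(per_meal = data.frame(), pooled = NA_real_))
  res <- lapply(meal_times, function(tm) {
    sel <- traj$time > tm & traj$time <= tm + 120
    data.frame(meal_time = tm,
               tir = if (any(sel)) time_in_range(traj$cgm[sel], 63, 140) else NA_real_,
               truncated = max(traj$time) < tm + 120)
  })
  per <- do.call(rbind, res)
  all_sel <- Reduce(`|`, lapply(meal_times, function(tm)
    traj$time > tm & traj$time <= tm + 120))
  list(per_meal = per,
       pooled = if (any(all_sel)) time_in_range(traj$cgm[all_sel], 63, 140)
                else NA_real_)
}

#' Pregnancy consensus-target check
#'
#' The four consensus criteria for pregnancy: more than 70% of time in
#' 63--140 mg/dL, less than 25% above it, less than 4% below 63 mg/dL, and
#' at most 1% below 54 mg/dL.
#'
#' @param m a `metrics_report` (or list with the pregnancy-set fields).
#' @return list with the four logical flags and `pass`, their conjunction.
#' @export
#' @examples
#' consensus_check(list(tir_63_140 = 80.8, above_140 = 18.3,
#'                      below_63 = 3.5, below_54 = 0.5))$pass  # TRUE
consensus_check <- function(m) {
  flags <- list(
    tir_over_70 = m$tir_63_140 > 70,
    tar_under_25 = m$above_140 < 25,
    tbr63_under_4 = m$below_63 < 4,
    tbr54_max_1 = m$below_54 <= 1
  )
  c(flags, list(pass = all(unlist(flags))))
}

#' Paired comparison of per-unit outcomes
#'
#' Classical paired t test (two-sided) on equal-length outcome vectors, one
#' entry per experimental unit (subject or scenario). Degenerate inputs with
#' zero-variance differences are an error rather than a silent p value.
#'
#' @param a,b numeric outcome vectors of equal length `>= 2`.
#' @return list with `mean_diff` (`mean(a - b)`), `t`, `df`, `p`.
#' @export
paired_compare <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("paired outcomes must have equal length >= 2")
  d <- a - b
  if (sd(d) == 0)
    stop("degenerate paired comparison: differences have zero variance")
  tt <- t.test(a, b, paired = TRUE)
  list(mean_diff = mean(d), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}

#' Grid search over target-zone bounds
#'
#' Evaluates every `(GZL, GZH)` pair with `GZH >= GZL + min_gap` by running
#' the scenario once per subject with the base preset's zones replaced by
#' the candidate zone (night zone set equal to the day zone) and averaging
#' the pregnancy metrics across subjects. Invalid pairs are reported as
#' `NA`.
#'
#' @param gzl_values,gzh_values candidate bounds, mg/dL, sorted ascending.
#' @param min_gap minimum zone width, mg/dL (default 10).
#' @param scenario an `ap_scenario` or scenario id.
#' @param cohort an `ap_cohort`.
#' @param preset_base a [controller_preset()] providing all non-zone
#'   parameters.
#' @param seed master seed.
#' @param cgm a [cgm_config()].
#' @return data.frame of class `zone_grid`: one row per pair with `gzl`,
#'   `gzh`, `valid`, `tir_63_140`, `below_63`, `above_140`.
#' @export
zone_grid_search <- function(gzl_values, gzh_values, min_gap = 10, scenario,
                             cohort, preset_base = controller_preset("pregnancy"),
                             seed = 1, cgm = cgm_config()) {
  if (is.unsorted(gzl_values) || is.unsorted(gzh_values))
    stop("grid values must be sorted ascending")
  if (is.character(scenario)) scenario <- load_scenario(scenario)
  rows <- list(); r <- 0L
  for (lo in gzl_values) for (hi in gzh_values) {
    r <- r + 1L
    if (hi < lo + min_gap) {
      rows[[r]] <- data.frame(gzl = lo, gzh = hi, valid = FALSE,
                              tir_63_140 = NA_real_, below_63 = NA_real_,
                              above_140 = NA_real_)
      next
    }
    ctl <- preset_base$controller
    ctl$zone_day <- c(lo, hi)
    ctl$zone_night <- c(lo, hi)
    preset <- structure(list(controller = ctl, bolus = preset_base$bolus,
                             name = sprintf("%s_z%g_%g", preset_base$name, lo, hi)),
                        class = "controller_preset")
    res <- run_experiment(list(scenario), list(preset), cohort,
                          replicates = 1, seed = derive_seed(seed, lo, hi),
                          cgm = cgm)
    rows[[r]] <- data.frame(gzl = lo, gzh = hi, valid = TRUE,
                            tir_63_140 = mean(res$tir_63_140),
                            below_63 = mean(res$below_63),
                            above_140 = mean(res$above_140))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("zone_grid", "data.frame")
  out
}
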