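#' Meal plan
#'
#' @param times meal clock times, minutes after midnight (default 08:00,
#'   13:00, 19:00).
#' @param grams carbohydrate grams per meal (default 40 each).
#' @param advance_bolus minutes by which meal boluses precede meals (0 or
#'   30).
#' @param first_meal_delay minutes the first meal is delayed (0 or 60).
#' @return object of class `meal_plan`.
#' @export
meal_plan <- function(times = c(480, 780, 1140), grams = 40,
                      advance_bolus = 0, first_meal_delay = 0) {
  grams <- rep_len(grams, length(times))
  stopifnot(all(grams >= 0), advance_bolus >= 0, first_meal_delay >= 0)
  structure(list(times = times, grams = grams,
                 advance_bolus = advance_bolus,
                 first_meal_delay = first_meal_delay),
            class = "meal_plan")
}

## the 13-scenario verification protocol, one row per scenario:
## sensitivity modifiers, initial glucose (NA = open-loop equilibrium),
## basal mode, treatment scalings, meal behavior
.scenario_table <- list(
  list(id = "A.1",   dvmx = 0,     dkp3 = 0,     g0 = 90,  basal = "b90",
       basal_scale = 1,   cr_scale = 1,   cf_scale = 1,    adv = 0,  delay = 0),
  list(id = "A.2",   dvmx = 0,     dkp3 = 0,     g0 = 90,  basal = "b90",
       basal_scale = 1,   cr_scale = 1,   cf_scale = 1,    adv = 30, delay = 0),
  list(id = "B.1.a", dvmx = 0,     dkp3 = 0,     g0 = NA,  basal = "nominal",
       basal_scale = 1,   cr_scale = 1.1, cf_scale = 1.1,  adv = 0,  delay = 0),
  list(id = "B.1.b", dvmx = 0,     dkp3 = 0,     g0 = NA,  basal = "nominal",
       basal_scale = 1,   cr_scale = 1.1, cf_scale = 1.1,  adv = 30, delay = 0),
  list(id = "B.2.a", dvmx = -0.25, dkp3 = -0.25, g0 = NA,  basal = "nominal",
       basal_scale = 1,   cr_scale = 1.1, cf_scale = 1.1,  adv = 0,  delay = 0),
  list(id = "B.2.b", dvmx = -0.25, dkp3 = -0.25, g0 = NA,  basal = "nominal",
       basal_scale = 1,   cr_scale = 1.1, cf_scale = 1.1,  adv = 30, delay = 0),
  list(id = "B.3.a", dvmx = 0,     dkp3 = 0,     g0 = 60,  basal = "nominal",
       basal_scale = 1,   cr_scale = 1.1, cf_scale = 1.1,  adv = 0,  delay = 0),
  list(id = "B.3.b", dvmx = 0,     dkp3 = 0,     g0 = 170, basal = "nominal",
       basal_scale = 1,   cr_scale = 1.1, cf_scale = 1.1,  adv = 0,  delay = 60),
  list(id = "C.1",   dvmx = -0.67, dkp3 = -0.67, g0 = NA,  basal = "scaled",
       basal_scale = 1.5, cr_scale = 0.5, cf_scale = 0.67, adv = 0,  delay = 0),
  list(id = "C.2",   dvmx = -0.67, dkp3 = -0.67, g0 = NA,  basal = "scaled",
       basal_scale = 1.5, cr_scale = 1,   cf_scale = 0.67, adv = 30, delay = 0),
  list(id = "D.1",   dvmx = 0.25,  dkp3 = 0.25,  g0 = 60,  basal = "b90",
       basal_scale = 1,   cr_scale = 0.9, cf_scale = 0.9,  adv = 0,  delay = 0),
  list(id = "D.2",   dvmx = -0.25, dkp3 = -0.25, g0 = 170, basal = "b170",
       basal_scale = 1,   cr_scale = 1.1, cf_scale = 1.1,  adv = 0,  delay = 0),
  list(id = "D.3",   dvmx = -0.67, dkp3 = -0.67, g0 = NA,  basal = "scaled",
       basal_scale = 1.5, cr_scale = 1,   cf_scale = 0.67, adv = 0,  delay = 0)
)

#' Scenario identifiers of the verification protocol
#' @return character vector of the 13 scenario ids.
#' @export
scenario_ids <- function() vapply(.scenario_table, `[[`, "", "id")

#' Load a verification scenario
#'
#' Declarative description of one cell of the in-silico verification
#' protocol: insulin-sensitivity modifiers on `Vmx`/`kp3`, initial glucose
#' (or the open-loop equilibrium when unset), the basal mode (`nominal`, a
#' fasting-titrated `b(90)`/`b(170)`, or a percentage scaling), carbohydrate
#' ratio and correction factor scalings, and the meal plan.
#'
#' @param identifier one of [scenario_ids()].
#' @return object of class `ap_scenario`.
#' @export
#' @examples
#' load_scenario("C.1")$cr_scale  # 0.5
load_scenario <- function(identifier) {
  hit <- Filter(function(s) s$id == identifier, .scenario_table)
  if (!length(hit)) stop("unknown scenario id: ", identifier)
  s <- hit[[1]]
  structure(list(
    id = s$id, dvmx = s$dvmx, dkp3 = s$dkp3, g0 = as.numeric(s$g0),
    basal_mode = s$basal, basal_scale = s$basal_scale,
    cr_scale = s$cr_scale, cf_scale = s$cf_scale,
    meals = meal_plan(advance_bolus = s$adv, first_meal_delay = s$delay)
  ), class = "ap_scenario")
}

#' Serialize / load a scenario as YAML
#' @param scenario an `ap_scenario`.
#' @param file path.
#' @export
write_scenario <- function(scenario, file) {
  doc <- list(id = scenario$id, dvmx = scenario$dvmx, dkp3 = scenario$dkp3,
              g0 = if (is.na(scenario$g0)) NULL else scenario$g0,
              basal_mode = scenario$basal_mode,
              basal_scale = scenario$basal_scale,
              cr_scale = scenario$cr_scale, cf_scale = scenario$cf_scale,
              meals = unclass(scenario$meals))
  writeLines(yaml::as.yaml(doc, precision = 22), file)
  invisible(file)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(file) {
  doc <- yaml::read_yaml(file)
  structure(list(
    id = doc$id, dvmx = doc$dvmx, dkp3 = doc$dkp3,
    g0 = if (is.null(doc$g0)) NA_real_ else doc$g0,
    basal_mode = doc$basal_mode, basal_scale = doc$basal_scale,
    cr_scale = doc$cr_scale, cf_scale = doc$cf_scale,
    meals = do.call(meal_plan, doc$meals)
  ), class = "ap_scenario")
}

#' @export
print.ap_scenario <- function(x, ...) {
  g0 <- if (is.na(x$g0)) "equilibrium" else sprintf("%g mg/dL", x$g0)
  cat(sprintf("scenario %s: dVmx %+.0f%%, dkp3 %+.0f%%, G0 %s, basal %s x%.2g, CR x%.2g, CF x%.2g, advance %g min, first-meal delay %g min\n",
              x$id, 100 * x$dvmx, 100 * x$dkp3, g0, x$basal_mode,
              x$basal_scale, x$cr_scale, x$cf_scale,
              x$meals$advance_bolus, x$meals$first_meal_delay))
  invisible(x)
}
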