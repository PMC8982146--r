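#' Construct a virtual subject consistent with a fasting equilibrium
#'
#' Completes a plant parameter set into a virtual subject: the basal plasma
#' insulin `Ib` is derived from the subject's nominal basal rate, and the
#' EGP intercept `kp1` is chosen so that the plant is exactly at steady state
#' at the stated fasting glucose under that basal. The nominal treatment
#' profile uses the 500 rule for the carbohydrate ratio and the 1800 rule for
#' the correction factor, both driven by an estimated total daily insulin.
#'
#' @param id subject identifier string.
#' @param params a `plant_params` (its `Ib`/`kp1` entries are overwritten).
#' @param basal nominal basal rate, U/h.
#' @param fasting nominal open-loop fasting glucose under `basal`, mg/dL.
#' @return an object of class `virtual_subject`: list with `id`, `params`,
#'   `treatment` (a [treatment_profile()]), `tdi` (U/day) and `fasting`.
#' @export
make_subject <- function(id, params = plant_params(), basal = 1.2, fasting = 120) {
  p <- params
  u <- 1000 * basal / 60
  Isc1 <- u / (p[["kd"]] + p[["ka1"]])
  Isc2 <- p[["kd"]] * Isc1 / p[["ka2"]]
  Ip <- (p[["ka1"]] * Isc1 + p[["ka2"]] * Isc2) / p[["ke"]]
  p[["Ib"]] <- Ip / (p[["Vi"]] * p[["BW"]])

  Gp <- fasting * p[["VG"]]
  f <- function(Gt) p[["k1"]] * Gp - p[["k2"]] * Gt - uid_rate(0, Gt, 0, p)
  Gt <- uniroot(f, c(0, max(p[["k1"]] * Gp / p[["k2"]], 1) + 1), tol = 1e-10)$root
  E <- p[["ke1"]] * max(0, Gp - p[["ke2"]])
  p[["kp1"]] <- p[["Fsnc"]] + E + p[["k1"]] * Gp - p[["k2"]] * Gt + p[["kp2"]] * Gp
  validate_plant_params(p)

  # meals covered by the 500-rule CR make TDI self-consistent with
  # three 40 g meals/day: tdi = 24*basal + 120/CR, CR = 500/tdi
  tdi <- 24 * basal / (1 - 120 / 500)
  structure(list(
    id = as.character(id),
    params = structure(p, class = "plant_params"),
    treatment = treatment_profile(basal = basal, CR = 500 / tdi, CF = 1800 / tdi),
    tdi = tdi,
    fasting = fasting
  ), class = "virtual_subject")
}

#' Prescribed insulin treatment parameters
#'
#' @param basal basal rate beta(t), U/h; either a single value or a vector of
#'   24 hourly values.
#' @param CR carbohydrate ratio, g/U.
#' @param CF correction factor, mg/dL per U.
#' @return an object of class `treatment_profile`.
#' @export
treatment_profile <- function(basal, CR, CF) {
  if (any(basal < 0)) stop("basal must be non-negative")
  if (!length(basal) %in% c(1L, 24L)) stop("basal must be scalar or 24 hourly values")
  if (CR <= 0 || CF <= 0) stop("CR and CF must be positive")
  structure(list(basal = unname(basal), CR = unname(CR), CF = unname(CF)),
            class = "treatment_profile")
}

#' Basal rate at a clock time
#' @param profile a [treatment_profile()].
#' @param clock_min minutes after midnight.
#' @return basal rate in U/h.
#' @export
basal_at <- function(profile, clock_min) {
  b <- profile$basal
  if (length(b) == 1L) return(b)
  b[(floor((clock_min %% 1440) / 60) %% 24) + 1L]
}

#' Scale a subject's insulin sensitivity
#'
#' Returns a copy of the subject with `Vmx <- Vmx*(1+delta_vmx)` and
#' `kp3 <- kp3*(1+delta_kp3)`; the original is untouched. This is how
#' pregnancy-induced insulin-resistance (negative deltas) or increased
#' sensitivity (positive deltas) scenarios perturb the plant.
#'
#' @param subject a `virtual_subject`.
#' @param delta_vmx,delta_kp3 fractional changes, `>= -1`.
#' @return the modified `virtual_subject`.
#' @export
#' @examples
#' s <- make_subject("s1")
#' s2 <- apply_sensitivity_modifiers(s, -0.67, -0.67)
#' s2$params[["Vmx"]] / s$params[["Vmx"]]  # 0.33
apply_sensitivity_modifiers <- function(subject, delta_vmx, delta_kp3) {
  if (delta_vmx < -1 || delta_kp3 < -1) stop("sensitivity modifiers must be >= -1")
  out <- subject
  out$params[["Vmx"]] <- subject$params[["Vmx"]] * (1 + delta_vmx)
  out$params[["kp3"]] <- subject$params[["kp3"]] * (1 + delta_kp3)
  out
}

#' Titrate the basal rate to an open-loop fasting target
#'
#' Deterministic bisection on a constant basal in [0, 5] U/h: starting from
#' the subject's nominal equilibrium, the plant runs open loop for a 12-hour
#' warm-up, then the mean plasma glucose over the following 2 hours is read
#' as the fasting value. The titrated basal reproduces the target within
#' +/- 2 mg/dL or an error is thrown.
#'
#' @param subject a `virtual_subject`.
#' @param target_fasting target fasting glucose in [60, 200] mg/dL.
#' @param params optional plant parameters to titrate against (defaults to
#'   the subject's own; scenarios titrate against default physiology).
#' @return constant basal rate, U/h.
#' @export
titrate_basal <- function(subject, target_fasting, params = subject$params) {
  if (target_fasting < 60 || target_fasting > 200)
    stop("target fasting must be in [60, 200] mg/dL")
  init <- plant_equilibrium(params, basal_at(subject$treatment, 0))
  fasting_at <- function(basal) {
    run <- cpp_plant_run(as.numeric(init), basal / 60, 0, as.numeric(params),
                         14 * 60, 1, 5)
    mean(tail(run$G, 24))   # mean over the 2 h after the 12 h warm-up
  }
  lo <- 0; hi <- 5
  g_lo <- fasting_at(lo); g_hi <- fasting_at(hi)
  if (g_lo < target_fasting - 2 || g_hi > target_fasting + 2)
    stop(sprintf("titration failure: target %g mg/dL not attainable in [0, 5] U/h (range %.1f..%.1f)",
                 target_fasting, g_hi, g_lo))
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    g <- fasting_at(mid)
    if (g > target_fasting) lo <- mid else hi <- mid
    if (hi - lo < 2e-4) break
  }
  mid <- (lo + hi) / 2
  g <- fasting_at(mid)
  if (abs(g - target_fasting) > 2)
    stop(sprintf("titration failure: best fasting %.2f for target %g", g, target_fasting))
  mid
}

#' Generate a synthetic virtual-patient cohort
#'
#' Draws `n` adult T1D subjects by log-normal jitter around the default plant
#' parameters, each completed by [make_subject()] so that its nominal basal
#' reproduces its nominal fasting glucose (around 120 mg/dL) exactly. Every
#' subject is verified to be titratable to both 90 and 170 mg/dL fasting
#' targets; draws that are not are rejected and redrawn, so the generator is
#' deterministic under `seed`. This cohort is a synthetic stand-in for
#' licensed simulator subjects: parameters are sampled, not published
#' subject sets.
#'
#' @param n number of subjects, `>= 1`.
#' @param seed integer seed.
#' @return list of `virtual_subject` of class `ap_cohort`.
#' @export
generate_cohort <- function(n = 10, seed = 1) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  out <- vector("list", n)
  kept <- 0L
  with_seed(seed, {
    attempts <- 0L
    while (kept < n) {
      attempts <- attempts + 1L
      if (attempts > 50L * n) stop("cohort generation failed to produce titratable subjects")
      cand <- random_subject(sprintf("S%02d", kept + 1L))
      ok <- tryCatch({
        titrate_basal(cand, 90)
        titrate_basal(cand, 170)
        TRUE
      }, error = function(e) FALSE)
      if (ok) {
        kept <- kept + 1L
        out[[kept]] <- cand
      }
    }
  })
  structure(out, class = "ap_cohort")
}

random_subject <- function(id) {
  jit <- function(cv) rlnorm(1, -cv^2 / 2, cv)
  p <- plant_params(
    BW = 70 * jit(0.12), k1 = 0.065 * jit(0.10), k2 = 0.079 * jit(0.10),
    kp2 = 0.008 * jit(0.15), kp3 = 0.09 * jit(0.20),
    Vm0 = 2.5 * jit(0.10), Vmx = 0.16 * jit(0.20), Km0 = 120 * jit(0.10),
    p2u = 0.05 * jit(0.15), ki = 0.012 * jit(0.15),
    kd = 0.04 * jit(0.10), ka1 = 0.004 * jit(0.10), ka2 = 0.04 * jit(0.10),
    ke = 0.14 * jit(0.10), Vi = 0.12 * jit(0.10),
    kgri = 0.08 * jit(0.15), kempt = 0.035 * jit(0.15), kabs = 0.08 * jit(0.15)
  )
  basal <- 1.2 * jit(0.20)
  fasting <- min(max(rnorm(1, 120, 8), 105), 140)
  make_subject(id, p, basal = basal, fasting = fasting)
}

## run `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

## small deterministic seed-stream derivation (kept below 2^31)
derive_seed <- function(master, ...) {
  idx <- c(...)
  x <- as.double(master) %% 2147483647
  for (k in idx) {
    x <- (x * 48271 + as.double(k) * 8191 + 12345) %% 2147483647
  }
  as.integer(x)
}

#' @export
print.virtual_subject <- function(x, ...) {
  cat(sprintf("virtual subject %s: BW %.1f kg, basal %.2f U/h, CR %.1f g/U, CF %.1f mg/dL/U, TDI %.1f U, fasting %.0f mg/dL\n",
              x$id, x$params[["BW"]], basal_at(x$treatment, 0),
              x$treatment$CR, x$treatment$CF, x$tdi, x$fasting))
  invisible(x)
}

#' @export
print.ap_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort of %d subjects\n", length(x)))
  for (s in x) print(s)
  invisible(x)
}

#' Write / read virtual subjects as flat YAML
#'
#' One subject per file; keys mirror the plant parameter names plus the
#' treatment profile. Numeric precision is preserved so that a round trip is
#' bit-exact.
#'
#' @param subject a `virtual_subject`.
#' @param file path to write / read.
#' @return `read_subject` returns a `virtual_subject`.
#' @export
write_subject <- function(subject, file) {
  doc <- list(
    id = subject$id,
    tdi = subject$tdi,
    fasting = subject$fasting,
    basal = subject$treatment$basal,
    CR = subject$treatment$CR,
    CF = subject$treatment$CF,
    params = as.list(setNames(as.numeric(subject$params), .plant_par_names))
  )
  writeLines(yaml::as.yaml(doc, precision = 22), file)
  invisible(file)
}

#' @rdname write_subject
#' @export
read_subject <- function(file) {
  doc <- yaml::read_yaml(file)
  p <- structure(unlist(doc$params)[.plant_par_names], class = "plant_params")
  structure(list(
    id = doc$id,
    params = p,
    treatment = treatment_profile(doc$basal, doc$CR, doc$CF),
    tdi = doc$tdi,
    fasting = doc$fasting
  ), class = "virtual_subject")
}

#' @rdname write_subject
#' @param cohort an `ap_cohort`.
#' @param dir directory for one YAML file per subject.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in cohort) write_subject(s, file.path(dir, paste0(s$id, ".yaml")))
  invisible(dir)
}

#' @rdname write_subject
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.ya?ml$", full.names = TRUE))
  if (!length(files)) stop("no subject files in ", dir)
  structure(lapply(files, read_subject), class = "ap_cohort")
}
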