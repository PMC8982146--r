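#' @useDynLib apzone, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats uniroot rnorm rlnorm runif sd t.test setNames aggregate reshape
#' @importFrom utils read.csv write.csv modifyList tail
NULL

## field order is shared with the compiled kernel -- do not reorder
.plant_par_names <- c(
  "BW", "VG", "k1", "k2", "kp1", "kp2", "kp3", "xi", "Vm0", "Vmx", "Km0",
  "r1", "p2u", "ki", "kd", "ka1", "ka2", "ke", "Vi", "Ib", "kgri", "kempt",
  "kabs", "fcarb", "Fsnc", "ke1", "ke2"
)

.plant_state_names <- c(
  "Gp", "Gt", "X", "XL", "XH", "Isc1", "Isc2", "Ip", "Qsto1", "Qsto2", "Qgut"
)

#' Plant parameter set for one virtual subject
#'
#' Builds the parameter vector of the glucose--insulin--meal plant: endogenous
#' glucose production (intercept `kp1`, plasma-glucose feedback `kp2`, liver
#' insulin-action gain `kp3`, glucagon responsivity `xi`), insulin-dependent
#' glucose utilization (`Vm0`, `Vmx`, Michaelis constant `Km0`, risk
#' amplification `r1`), glucose kinetics (`VG`, `k1`, `k2`), insulin action
#' dynamics (`p2u`, `ki`), a two-compartment subcutaneous insulin depot
#' (`kd`, `ka1`, `ka2`) with plasma clearance `ke` and distribution volume
#' `Vi`, a three-compartment gut absorption chain (`kgri`, `kempt`, `kabs`,
#' bioavailability `fcarb`), insulin-independent utilization `Fsnc`, and
#' threshold-linear renal excretion (`ke1`, `ke2`).
#'
#' Defaults are literature-plausible adult type 1 diabetes values for this
#' model structure; they are package defaults, not parameters of any licensed
#' simulator subject. `Ib` (basal plasma insulin, mU/L) and `kp1` are usually
#' derived from a fasting equilibrium via [make_subject()] rather than set
#' directly.
#'
#' @param ... named overrides of any parameter.
#' @return a named numeric vector of class `plant_params`.
#' @export
#' @examples
#' p <- plant_params(BW = 65)
#' p[["BW"]]
plant_params <- function(...) {
  p <- c(
    BW = 70, VG = 1.88, k1 = 0.065, k2 = 0.079,
    kp1 = 2.6, kp2 = 0.008, kp3 = 0.09, xi = 0,
    Vm0 = 2.5, Vmx = 0.16, Km0 = 120, r1 = 0,
    p2u = 0.05, ki = 0.012,
    kd = 0.04, ka1 = 0.004, ka2 = 0.04, ke = 0.14, Vi = 0.12, Ib = 17,
    kgri = 0.08, kempt = 0.035, kabs = 0.08, fcarb = 1,
    Fsnc = 1, ke1 = 0.01, ke2 = 339
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown plant parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- unlist(over)
  }
  validate_plant_params(p)
  structure(p[.plant_par_names], class = "plant_params")
}

validate_plant_params <- function(p) {
  pos <- c("BW", "VG", "k1", "k2", "Vm0", "Km0", "p2u", "ki", "kd", "ka1",
           "ka2", "ke", "Vi", "kgri", "kempt", "kabs", "fcarb")
  if (any(!is.finite(p))) stop("plant parameters must be finite")
  if (any(p[pos] <= 0)) stop("rates and volumes must be strictly positive")
  if (p[["Vmx"]] < 0 || p[["kp3"]] < 0) stop("Vmx and kp3 must be non-negative")
  if (p[["kp1"]] < 0) stop("basal endogenous glucose production must be non-negative")
  invisible(p)
}

#' Plant state vector
#'
#' @param ... named overrides of state components (`Gp`, `Gt` glucose masses
#'   in mg/kg; `X`, `XL` insulin actions as deviations from basal in mU/L;
#'   `XH` glucagon action; `Isc1`, `Isc2`, `Ip` insulin masses in mU;
#'   `Qsto1`, `Qsto2`, `Qgut` gut carbohydrate masses in mg).
#' @return named numeric vector of class `plant_state`.
#' @export
plant_state <- function(...) {
  s <- setNames(numeric(length(.plant_state_names)), .plant_state_names)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(s))
    if (length(bad)) stop("unknown state component(s): ", paste(bad, collapse = ", "))
    s[names(over)] <- unlist(over)
  }
  masses <- setdiff(.plant_state_names, c("X", "XL", "XH"))
  if (any(s[masses] < 0)) stop("compartment masses must be non-negative")
  structure(s, class = "plant_state")
}

#' Measurable plasma glucose concentration of a state
#'
#' @param state a `plant_state`.
#' @param params a `plant_params`.
#' @return plasma glucose in mg/dL.
#' @export
plasma_glucose <- function(state, params) {
  unname(state[["Gp"]] / params[["VG"]])
}

#' Endogenous glucose production rate
#'
#' `EGP = max(0, kp1 - kp2*Gp - kp3*XL + xi*XH)`: hepatic output falls with
#' plasma glucose mass and liver insulin action and rises with glucagon
#' action; the rate is clamped at zero (a liver cannot consume glucose through
#' this pathway).
#'
#' @param Gp plasma glucose mass (mg/kg).
#' @param XL liver insulin action.
#' @param XH delayed glucagon action.
#' @param params a `plant_params`.
#' @return production rate in mg/kg/min.
#' @export
#' @examples
#' egp_rate(0, 0, 0, plant_params())  # == kp1
egp_rate <- function(Gp, XL, XH, params) {
  validate_plant_params(params)
  pmax(0, params[["kp1"]] - params[["kp2"]] * Gp - params[["kp3"]] * XL +
         params[["xi"]] * XH)
}

#' Insulin-dependent glucose utilization rate
#'
#' `Uid = [Vm0 + Vmx*X*(1 + r1*risk)] * Gt / (Km0 + Gt)`, a Michaelis--Menten
#' uptake whose capacity grows with insulin action `X`, optionally amplified
#' by the hypoglycemia risk signal. The capacity bracket is clamped at zero so
#' utilization never becomes negative when `X` is far below basal.
#'
#' @param X insulin action on utilization.
#' @param Gt tissue glucose mass (mg/kg), non-negative.
#' @param risk non-negative glycemic risk value (see [risk_value()]).
#' @param params a `plant_params`.
#' @return utilization rate in mg/kg/min.
#' @export
uid_rate <- function(X, Gt, risk, params) {
  if (any(Gt < 0)) stop("Gt must be non-negative")
  if (any(risk < 0)) stop("risk must be non-negative")
  cap <- pmax(0, params[["Vm0"]] + params[["Vmx"]] * X * (1 + params[["r1"]] * risk))
  cap * Gt / (params[["Km0"]] + Gt)
}

#' One-sided hypoglycemia risk
#'
#' A log-power risk index that is zero at and above its reference glucose
#' (about 112.5 mg/dL, where the log-power term changes sign) and increases
#' monotonically as glucose falls below it. This package default stands in
#' for the clinical risk index family used with this model class; the exact
#' published curve is not reproduced here.
#'
#' @param G glucose concentration in mg/dL, strictly positive.
#' @return dimensionless risk, `>= 0`.
#' @export
#' @examples
#' risk_value(180)  # 0: one-sided
#' risk_value(60) > risk_value(80)
risk_value <- function(G) {
  if (any(!is.finite(G)) || any(G <= 0)) stop("glucose must be positive and finite")
  f <- 1.509 * (log(pmax(G, 1)) ^ 1.084 - 5.381)
  ifelse(f < 0, f^2, 0)
}

#' Plant time-derivative
#'
#' Full right-hand side of the metabolic ODE combining endogenous production,
#' utilization, renal excretion, the subcutaneous insulin chain and the gut
#' chain. This is the R reference implementation; the integrator uses an
#' identical compiled version (their agreement is tested).
#'
#' @param state a `plant_state`.
#' @param u_ins insulin infusion, U/min, `>= 0`.
#' @param u_glucose carbohydrate intake, g/min, `>= 0`.
#' @param params a `plant_params`.
#' @return derivative vector (per minute) with the state's layout.
#' @export
plant_derivatives <- function(state, u_ins, u_glucose, params) {
  if (u_ins < 0 || u_glucose < 0) stop("inputs must be non-negative")
  s <- as.numeric(state)
  names(s) <- .plant_state_names
  G <- s[["Gp"]] / params[["VG"]]
  EGP <- egp_rate(s[["Gp"]], s[["XL"]], s[["XH"]], params)
  Uid <- uid_rate(s[["X"]], s[["Gt"]], risk_value(max(G, 1)), params)
  Ra <- params[["fcarb"]] * params[["kabs"]] * s[["Qgut"]] / params[["BW"]]
  E <- params[["ke1"]] * max(0, s[["Gp"]] - params[["ke2"]])
  I <- s[["Ip"]] / (params[["Vi"]] * params[["BW"]])
  Idev <- I - params[["Ib"]]
  d <- c(
    Gp = EGP + Ra - params[["Fsnc"]] - E - params[["k1"]] * s[["Gp"]] +
      params[["k2"]] * s[["Gt"]],
    Gt = -Uid + params[["k1"]] * s[["Gp"]] - params[["k2"]] * s[["Gt"]],
    X = -params[["p2u"]] * s[["X"]] + params[["p2u"]] * Idev,
    XL = -params[["ki"]] * (s[["XL"]] - Idev),
    XH = 0,
    Isc1 = -(params[["kd"]] + params[["ka1"]]) * s[["Isc1"]] + 1000 * u_ins,
    Isc2 = params[["kd"]] * s[["Isc1"]] - params[["ka2"]] * s[["Isc2"]],
    Ip = params[["ka1"]] * s[["Isc1"]] + params[["ka2"]] * s[["Isc2"]] -
      params[["ke"]] * s[["Ip"]],
    Qsto1 = -params[["kgri"]] * s[["Qsto1"]] + 1000 * u_glucose,
    Qsto2 = params[["kgri"]] * s[["Qsto1"]] - params[["kempt"]] * s[["Qsto2"]],
    Qgut = params[["kempt"]] * s[["Qsto2"]] - params[["kabs"]] * s[["Qgut"]]
  )
  d
}

#' Advance the plant by a fixed time step
#'
#' Explicit fourth-order Runge--Kutta with a fixed internal step (default
#' 1 minute), matching the 5-minute control sampling of the closed loop.
#' Compartment masses are clamped at zero after each internal step.
#'
#' @param state a `plant_state`.
#' @param u_ins insulin infusion, U/min.
#' @param u_glucose carbohydrate intake, g/min.
#' @param params a `plant_params`.
#' @param dt minutes to advance, `> 0`.
#' @param h internal integrator step in minutes (default 1).
#' @return the advanced `plant_state`.
#' @export
plant_step <- function(state, u_ins, u_glucose, params, dt, h = 1) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  if (u_ins < 0 || u_glucose < 0) stop("inputs must be non-negative")
  out <- cpp_plant_step(as.numeric(state), u_ins, u_glucose,
                        as.numeric(params), dt, h)
  structure(setNames(out, .plant_state_names), class = "plant_state")
}

#' Open-loop fasting equilibrium of the plant
#'
#' Solves the steady state reached under a constant basal infusion and no
#' meals. The insulin subsystem is linear (closed form); the glucose
#' subsystem is reduced to a scalar root-finding problem in plasma glucose
#' mass.
#'
#' @param params a `plant_params`.
#' @param basal basal rate in U/h.
#' @return a `plant_state` at equilibrium.
#' @export
plant_equilibrium <- function(params, basal) {
  p <- params
  u <- 1000 * basal / 60                      # mU/min
  Isc1 <- u / (p[["kd"]] + p[["ka1"]])
  Isc2 <- p[["kd"]] * Isc1 / p[["ka2"]]
  Ip <- (p[["ka1"]] * Isc1 + p[["ka2"]] * Isc2) / p[["ke"]]
  I <- Ip / (p[["Vi"]] * p[["BW"]])
  Idev <- I - p[["Ib"]]
  X <- Idev; XL <- Idev

  gt_of_gp <- function(Gp) {
    G <- Gp / p[["VG"]]
    f <- function(Gt) p[["k1"]] * Gp - p[["k2"]] * Gt -
      uid_rate(X, Gt, risk_value(max(G, 1)), p)
    upper <- max(p[["k1"]] * Gp / p[["k2"]], 1)
    uniroot(f, c(0, upper + 1), tol = 1e-10)$root
  }
  net <- function(Gp) {
    Gt <- gt_of_gp(Gp)
    egp_rate(Gp, XL, 0, p) - p[["Fsnc"]] -
      p[["ke1"]] * max(0, Gp - p[["ke2"]]) -
      p[["k1"]] * Gp + p[["k2"]] * Gt
  }
  lo <- 1; hi <- 2000
  if (net(lo) < 0) stop("no fasting equilibrium above 1 mg/kg (basal too high)")
  while (net(hi) > 0 && hi < 1e5) hi <- hi * 2
  Gp <- uniroot(net, c(lo, hi), tol = 1e-8)$root
  Gt <- gt_of_gp(Gp)
  plant_state(Gp = Gp, Gt = Gt, X = X, XL = XL,
              Isc1 = Isc1, Isc2 = Isc2, Ip = Ip)
}
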