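#include <Rcpp.h>
using namespace Rcpp;

// Glucose-insulin-meal plant kernel.
//
// State layout (all masses per kg of body weight where noted):
//   0 Gp    plasma glucose mass (mg/kg)
//   1 Gt    tissue glucose mass (mg/kg)
//   2 X     insulin action on utilization, deviation from basal (mU/L)
//   3 XL    delayed insulin action on the liver, deviation from basal (mU/L)
//   4 XH    delayed glucagon action (unused by default, kept for structure)
//   5 Isc1  first subcutaneous insulin depot (mU)
//   6 Isc2  second subcutaneous insulin depot (mU)
//   7 Ip    plasma insulin mass (mU)
//   8 Qsto1 stomach, first compartment (mg carbohydrate)
//   9 Qsto2 stomach, second compartment (mg)
//  10 Qgut  gut compartment (mg)
//
// Parameter vector is accessed positionally; the R side guarantees the order
// (see plant_params()).

struct Par {
  double BW, VG, k1, k2, kp1, kp2, kp3, xi, Vm0, Vmx, Km0, r1,
         p2u, ki, kd, ka1, ka2, ke, Vi, Ib, kgri, kempt, kabs, fcarb,
         Fsnc, ke1, ke2;
};

static Par unpack(const NumericVector& p) {
  Par q;
  q.BW = p[0];  q.VG = p[1];  q.k1 = p[2];  q.k2 = p[3];
  q.kp1 = p[4]; q.kp2 = p[5]; q.kp3 = p[6]; q.xi = p[7];
  q.Vm0 = p[8]; q.Vmx = p[9]; q.Km0 = p[10]; q.r1 = p[11];
  q.p2u = p[12]; q.ki = p[13]; q.kd = p[14]; q.ka1 = p[15];
  q.ka2 = p[16]; q.ke = p[17]; q.Vi = p[18]; q.Ib = p[19];
  q.kgri = p[20]; q.kempt = p[21]; q.kabs = p[22]; q.fcarb = p[23];
  q.Fsnc = p[24]; q.ke1 = p[25]; q.ke2 = p[26];
  return q;
}

// One-sided hypoglycemia risk: zero at/above ~112.5 mg/dL, increasing below.
static double risk_fun(double G) {
  if (G < 1.0) G = 1.0;
  double f = 1.509 * (std::pow(std::log(G), 1.084) - 5.381);
  return (f < 0.0) ? f * f : 0.0;
}

static void deriv(const double* s, double u_ins, double u_glu,
                  const Par& p, double* ds) {
  double G = s[0] / p.VG;                       // mg/dL
  double risk = risk_fun(G);
  double EGP = p.kp1 - p.kp2 * s[0] - p.kp3 * s[3] + p.xi * s[4];
  if (EGP < 0.0) EGP = 0.0;
  double Vm = p.Vm0 + p.Vmx * s[2] * (1.0 + p.r1 * risk);
  if (Vm < 0.0) Vm = 0.0;
  double Uid = Vm * s[1] / (p.Km0 + s[1]);
  double Ra = p.fcarb * p.kabs * s[10] / p.BW;  // mg/kg/min
  double E = p.ke1 * std::max(0.0, s[0] - p.ke2);
  double I = s[7] / (p.Vi * p.BW);              // mU/L
  double Idev = I - p.Ib;

  ds[0] = EGP + Ra - p.Fsnc - E - p.k1 * s[0] + p.k2 * s[1];
  ds[1] = -Uid + p.k1 * s[0] - p.k2 * s[1];
  ds[2] = -p.p2u * s[2] + p.p2u * Idev;
  ds[3] = -p.ki * (s[3] - Idev);
  ds[4] = 0.0;
  ds[5] = -(p.kd + p.ka1) * s[5] + 1000.0 * u_ins;
  ds[6] = p.kd * s[5] - p.ka2 * s[6];
  ds[7] = p.ka1 * s[5] + p.ka2 * s[6] - p.ke * s[7];
  ds[8] = -p.kgri * s[8] + 1000.0 * u_glu;
  ds[9] = p.kgri * s[8] - p.kempt * s[9];
  ds[10] = p.kempt * s[9] - p.kabs * s[10];
}

static const int NS = 11;

// [[Rcpp::export]]
NumericVector cpp_plant_deriv(NumericVector state, double u_ins, double u_glu,
                              NumericVector params) {
  Par p = unpack(params);
  NumericVector out(NS);
  deriv(REAL(state), u_ins, u_glu, p, REAL(out));
  return out;
}

static void rk4_advance(double* s, double u_ins, double u_glu,
                        const Par& p, double minutes, double h) {
  double k1v[NS], k2v[NS], k3v[NS], k4v[NS], tmp[NS];
  double t = 0.0;
  while (t < minutes - 1e-12) {
    double hh = std::min(h, minutes - t);
    deriv(s, u_ins, u_glu, p, k1v);
    for (int i = 0; i < NS; ++i) tmp[i] = s[i] + 0.5 * hh * k1v[i];
    deriv(tmp, u_ins, u_glu, p, k2v);
    for (int i = 0; i < NS; ++i) tmp[i] = s[i] + 0.5 * hh * k2v[i];
    deriv(tmp, u_ins, u_glu, p, k3v);
    for (int i = 0; i < NS; ++i) tmp[i] = s[i] + hh * k3v[i];
    deriv(tmp, u_ins, u_glu, p, k4v);
    for (int i = 0; i < NS; ++i)
      s[i] += hh / 6.0 * (k1v[i] + 2.0 * k2v[i] + 2.0 * k3v[i] + k4v[i]);
    // physical compartments cannot go negative (actions X/XL/XH may)
    for (int i = 0; i < NS; ++i)
      if (i != 2 && i != 3 && i != 4 && s[i] < 0.0) s[i] = 0.0;
    t += hh;
  }
}

// [[Rcpp::export]]
NumericVector cpp_plant_step(NumericVector state, double u_ins, double u_glu,
                             NumericVector params, double minutes, double h) {
  Par p = unpack(params);
  NumericVector out = clone(state);
  rk4_advance(REAL(out), u_ins, u_glu, p, minutes, h);
  for (int i = 0; i < NS; ++i)
    if (!R_finite(out[i]))
      stop("plant integration diverged (state component %d is not finite)", i + 1);
  return out;
}

// Constant-input open-loop run; returns plasma glucose (mg/dL) sampled every
// `record_every` minutes (t = record_every, 2*record_every, ...) plus the
// final state. Used by basal titration and equilibrium checks.
// [[Rcpp::export]]
List cpp_plant_run(NumericVector state, double u_ins, double u_glu,
                   NumericVector params, double minutes, double h,
                   double record_every) {
  Par p = unpack(params);
  NumericVector cur = clone(state);
  int n = (int)std::floor(minutes / record_every + 1e-9);
  NumericVector G(n);
  for (int j = 0; j < n; ++j) {
    rk4_advance(REAL(cur), u_ins, u_glu, p, record_every, h);
    G[j] = cur[0] / p.VG;
    if (!R_finite(G[j])) stop("plant integration diverged during open-loop run");
  }
  return List::create(_["G"] = G, _["state"] = cur);
}
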