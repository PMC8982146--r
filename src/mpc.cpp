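#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Zone-MPC stage cost and solver.
//
// The prediction model is the third-order companion form
//   x1(i+1) = a1*x1 + a2*x2 + a3*x3 + b*u(i),  x2(i+1) = x1,  x3(i+1) = x2,
// with x3 the current differential glucose, so the predicted glucose at step
// j is Gref + x3(j). The cost is a sum of weighted squared one-sided terms
//   J = sum_t w_t * max(0, c_t' u + d_t)^2
// covering below-zone deviations (weight 1), above-zone deviations (weight
// Q), one-sided rising two-step velocity (weight Dhat), and input deviations
// from basal (R+ above, R- below). It is convex and C1 in the plan u, and is
// minimized over the box [lb, ub] by a two-metric projected Newton method.

struct Terms {
  arma::mat C;     // nterm x Nu
  arma::vec d;     // nterm
  arma::vec w;     // nterm
};

static void build_predictions(const arma::vec& xhat, double a1, double a2,
                              double a3, double b, int Np, int Nu,
                              arma::vec& g0, arma::mat& S) {
  // free response of x3 and sensitivity of x3(j) to u_m, j = 1..Np
  g0.set_size(Np);
  S.zeros(Np, Nu);
  arma::vec x = xhat;             // (x1, x2, x3)
  std::vector<arma::vec> xs(Np + 1);
  xs[0] = x;
  for (int j = 1; j <= Np; ++j) {
    arma::vec xn(3);
    xn[0] = a1 * x[0] + a2 * x[1] + a3 * x[2];
    xn[1] = x[0];
    xn[2] = x[1];
    x = xn;
    xs[j] = x;
    g0[j - 1] = x[2];
  }
  // impulse response of x3 to a unit input at step 0: h(j)
  arma::vec z(3, arma::fill::zeros);
  std::vector<double> h(Np + 1, 0.0);
  for (int j = 1; j <= Np; ++j) {
    arma::vec zn(3);
    zn[0] = a1 * z[0] + a2 * z[1] + a3 * z[2] + (j == 1 ? b : 0.0);
    zn[1] = z[0];
    zn[2] = z[1];
    z = zn;
    h[j] = z[2];
  }
  for (int j = 1; j <= Np; ++j)
    for (int m = 0; m < Nu; ++m)
      if (j - m >= 1) S(j - 1, m) = h[j - m];
}

static Terms build_terms(const arma::vec& g0, const arma::mat& S, double Gref,
                         double lo, double hi, double Qw, double Dhat,
                         double Rplus, double Rminus, double Gk, double Gkm1,
                         int Np, int Nu) {
  int nt = 2 * Np + Np + 2 * Nu;
  Terms T;
  T.C.zeros(nt, Nu);
  T.d.set_size(nt);
  T.w.set_size(nt);
  int r = 0;
  for (int j = 0; j < Np; ++j) {           // below zone: lo - G_j
    T.C.row(r) = -S.row(j);
    T.d[r] = lo - (Gref + g0[j]);
    T.w[r] = 1.0;
    ++r;
  }
  for (int j = 0; j < Np; ++j) {           // above zone: G_j - hi
    T.C.row(r) = S.row(j);
    T.d[r] = (Gref + g0[j]) - hi;
    T.w[r] = Qw;
    ++r;
  }
  for (int j = 0; j < Np; ++j) {           // rising velocity (G_j - G_{j-2})/10
    arma::rowvec cj = S.row(j);
    double prev;
    if (j - 2 >= 0) { cj -= S.row(j - 2); prev = Gref + g0[j - 2]; }
    else if (j - 2 == -2) prev = Gkm1;
    else prev = Gk;                        // j - 2 == -1
    T.C.row(r) = cj / 10.0;
    T.d[r] = ((Gref + g0[j]) - prev) / 10.0;
    T.w[r] = Dhat;
    ++r;
  }
  for (int m = 0; m < Nu; ++m) {           // input above basal
    T.C.row(r).zeros(); T.C(r, m) = 1.0; T.d[r] = 0.0; T.w[r] = Rplus; ++r;
  }
  for (int m = 0; m < Nu; ++m) {           // input below basal
    T.C.row(r).zeros(); T.C(r, m) = -1.0; T.d[r] = 0.0; T.w[r] = Rminus; ++r;
  }
  return T;
}

static arma::vec clip_box(const arma::vec& x, const arma::vec& l,
                          const arma::vec& h) {
  return arma::min(arma::max(x, l), h);
}

static double cost_of(const Terms& T, const arma::vec& u, arma::vec* grad) {
  arma::vec a = T.C * u + T.d;
  double J = 0.0;
  if (grad) grad->zeros(u.n_elem);
  for (arma::uword t = 0; t < a.n_elem; ++t) {
    if (a[t] > 0.0) {
      J += T.w[t] * a[t] * a[t];
      if (grad) *grad += 2.0 * T.w[t] * a[t] * T.C.row(t).t();
    }
  }
  return J;
}

// [[Rcpp::export]]
double cpp_mpc_plan_cost(NumericVector xhat, double a1, double a2, double a3,
                         double b, double Gref, int Np, int Nu, double lo,
                         double hi, double Qw, double Dhat, double Rplus,
                         double Rminus, double Gk, double Gkm1,
                         NumericVector plan) {
  arma::vec x0(xhat.begin(), 3);
  arma::vec g0; arma::mat S;
  build_predictions(x0, a1, a2, a3, b, Np, Nu, g0, S);
  Terms T = build_terms(g0, S, Gref, lo, hi, Qw, Dhat, Rplus, Rminus,
                        Gk, Gkm1, Np, Nu);
  arma::vec u(plan.begin(), Nu);
  return cost_of(T, u, nullptr);
}

// [[Rcpp::export]]
List cpp_mpc_solve(NumericVector xhat, double a1, double a2, double a3,
                   double b, double Gref, int Np, int Nu, double lo,
                   double hi, double Qw, double Dhat, double Rplus,
                   double Rminus, double Gk, double Gkm1,
                   NumericVector lb, NumericVector ub) {
  arma::vec x0(xhat.begin(), 3);
  arma::vec g0; arma::mat S;
  build_predictions(x0, a1, a2, a3, b, Np, Nu, g0, S);
  Terms T = build_terms(g0, S, Gref, lo, hi, Qw, Dhat, Rplus, Rminus,
                        Gk, Gkm1, Np, Nu);
  arma::vec l(lb.begin(), Nu), h(ub.begin(), Nu);
  arma::vec u = clip_box(arma::zeros(Nu), l, h);   // start at basal
  arma::vec g(Nu);
  double J = cost_of(T, u, &g);
  const double eps = 1e-9;

  for (int it = 0; it < 200; ++it) {
    // binding set: at a bound with the gradient pushing outward
    std::vector<int> freeIdx;
    for (int m = 0; m < Nu; ++m) {
      bool bindLo = (u[m] <= l[m] + eps) && (g[m] > 0.0);
      bool bindHi = (u[m] >= h[m] - eps) && (g[m] < 0.0);
      if (!(bindLo || bindHi)) freeIdx.push_back(m);
    }
    arma::vec dir(Nu, arma::fill::zeros);
    // scaled gradient on binding coordinates (clipped away anyway)
    for (int m = 0; m < Nu; ++m) dir[m] = g[m] / (2.0 * Rminus);
    if (!freeIdx.empty()) {
      arma::uvec F(freeIdx.size());
      for (size_t i = 0; i < freeIdx.size(); ++i) F[i] = freeIdx[i];
      arma::mat H(F.n_elem, F.n_elem, arma::fill::zeros);
      arma::vec a = T.C * u + T.d;
      for (arma::uword t = 0; t < a.n_elem; ++t) {
        if (a[t] > 0.0) {
          arma::rowvec cF = T.C.row(t);
          arma::vec cf(F.n_elem);
          for (arma::uword i = 0; i < F.n_elem; ++i) cf[i] = cF[F[i]];
          H += 2.0 * T.w[t] * (cf * cf.t());
        }
      }
      H.diag() += 2.0 * Rminus;   // guaranteed input-cost curvature
      arma::vec gF(F.n_elem);
      for (arma::uword i = 0; i < F.n_elem; ++i) gF[i] = g[F[i]];
      arma::vec dF = arma::solve(H, gF, arma::solve_opts::likely_sympd);
      for (arma::uword i = 0; i < F.n_elem; ++i) dir[F[i]] = dF[i];
    }
    // backtracking Armijo line search along the projection arc
    double alpha = 1.0, Jnew = J;
    arma::vec unew = u;
    bool accepted = false;
    for (int ls = 0; ls < 40; ++ls) {
      unew = clip_box(u - alpha * dir, l, h);
      Jnew = cost_of(T, unew, nullptr);
      double decr = arma::dot(g, u - unew);
      if (Jnew <= J - 1e-4 * decr && Jnew <= J) { accepted = true; break; }
      alpha *= 0.5;
    }
    if (!accepted) break;
    double move = arma::abs(unew - u).max();
    bool tiny = (J - Jnew) < 1e-13 * (1.0 + std::abs(J));
    u = unew;
    J = cost_of(T, u, &g);
    if (move < 1e-11 || tiny) break;
  }
  if (!u.is_finite())
    stop("MPC solver produced a non-finite plan");
  return List::create(_["u"] = NumericVector(u.begin(), u.end()),
                      _["cost"] = J);
}
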