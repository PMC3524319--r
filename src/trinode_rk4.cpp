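#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Three-node motif dynamics, fixed-step classical RK4.
//
// dx_i/dt = k_i * A_i * (1 - x_i) - g_i * (1 + I_i) * x_i
// A_i = b_i + sum_{act j->i} w * H(u_j), I_i = sum_{inh j->i} w * H(u_j)
// H(u; K, n) = u^n / (K^n + u^n), u indexed as (S, x1, x2, x3).
//
// The step size is chosen conservatively from the fastest possible
// relaxation rate (k_i * A_i^max + g_i * (1 + I_i^max)) so the explicit
// scheme stays stable for any parameter set within the search bounds.

static inline double hillf(double u, double K, double n) {
  if (u <= 0.0) return 0.0;
  double un = std::pow(u, n), Kn = std::pow(K, n);
  return un / (Kn + un);
}

struct TriSys {
  int ne;
  std::vector<int> efrom, eto, esign;
  std::vector<double> ew, eK;
  double k[3], g[3], b[3], n;

  void rhs(double S, const double* x, double* dx) const {
    double u[4] = {S, x[0], x[1], x[2]};
    double A[3] = {b[0], b[1], b[2]};
    double I[3] = {0.0, 0.0, 0.0};
    for (int e = 0; e < ne; ++e) {
      double h = ew[e] * hillf(u[efrom[e]], eK[e], n);
      if (esign[e] > 0) A[eto[e]] += h; else I[eto[e]] += h;
    }
    for (int i = 0; i < 3; ++i)
      dx[i] = k[i] * A[i] * (1.0 - x[i]) - g[i] * (1.0 + I[i]) * x[i];
  }

  double max_rate() const {
    double Amax[3] = {b[0], b[1], b[2]};
    double Imax[3] = {0.0, 0.0, 0.0};
    for (int e = 0; e < ne; ++e) {
      if (esign[e] > 0) Amax[eto[e]] += ew[e]; else Imax[eto[e]] += ew[e];
    }
    double m = 0.0;
    for (int i = 0; i < 3; ++i) {
      double r = k[i] * Amax[i] + g[i] * (1.0 + Imax[i]);
      if (r > m) m = r;
    }
    return m;
  }

  void rk4_step(double S, double* x, double h) const {
    double k1[3], k2[3], k3[3], k4[3], xt[3];
    rhs(S, x, k1);
    for (int i = 0; i < 3; ++i) xt[i] = x[i] + 0.5 * h * k1[i];
    rhs(S, xt, k2);
    for (int i = 0; i < 3; ++i) xt[i] = x[i] + 0.5 * h * k2[i];
    rhs(S, xt, k3);
    for (int i = 0; i < 3; ++i) xt[i] = x[i] + h * k3[i];
    rhs(S, xt, k4);
    for (int i = 0; i < 3; ++i) {
      x[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (x[i] < 0.0) x[i] = 0.0;
      if (x[i] > 1.0) x[i] = 1.0;
    }
  }
};

static TriSys make_sys(IntegerVector efrom, IntegerVector eto, IntegerVector esign,
                       NumericVector ew, NumericVector eK, NumericVector k,
                       NumericVector g, NumericVector b, double n) {
  TriSys s;
  s.ne = efrom.size();
  s.efrom.assign(efrom.begin(), efrom.end());
  s.eto.assign(eto.begin(), eto.end());
  s.esign.assign(esign.begin(), esign.end());
  s.ew.assign(ew.begin(), ew.end());
  s.eK.assign(eK.begin(), eK.end());
  for (int i = 0; i < 3; ++i) { s.k[i] = k[i]; s.g[i] = g[i]; s.b[i] = b[i]; }
  s.n = n;
  return s;
}

static double stable_step(const TriSys& s, double h_max) {
  double h = 0.5 / s.max_rate();
  if (h > h_max) h = h_max;
  if (h < 1e-5) h = 1e-5;
  return h;
}

// [[Rcpp::export]]
List trinode_rk4_cpp(NumericVector x0, IntegerVector efrom, IntegerVector eto,
                     IntegerVector esign, NumericVector ew, NumericVector eK,
                     NumericVector k, NumericVector g, NumericVector b, double n,
                     NumericVector durations, NumericVector doses,
                     double dt_out, double h_max) {
  TriSys s = make_sys(efrom, eto, esign, ew, eK, k, g, b, n);
  double h = stable_step(s, h_max);
  // output grid: union of per-segment grids with segment-end points
  std::vector<double> times;
  times.push_back(0.0);
  double t0 = 0.0;
  for (int seg = 0; seg < durations.size(); ++seg) {
    double tend = t0 + durations[seg];
    for (double t = t0 + dt_out; t < tend - 1e-12; t += dt_out) times.push_back(t);
    times.push_back(tend);
    t0 = tend;
  }
  int np = times.size();
  NumericMatrix out(np, 3);
  double x[3] = {x0[0], x0[1], x0[2]};
  out(0, 0) = x[0]; out(0, 1) = x[1]; out(0, 2) = x[2];
  int ip = 1;
  t0 = 0.0;
  for (int seg = 0; seg < durations.size(); ++seg) {
    double tend = t0 + durations[seg];
    double S = doses[seg];
    double t = t0;
    while (ip < np && times[ip] <= tend + 1e-12) {
      double target = times[ip];
      while (t < target - 1e-12) {
        double step = h;
        if (t + step > target) step = target - t;
        s.rk4_step(S, x, step);
        t += step;
      }
      out(ip, 0) = x[0]; out(ip, 1) = x[1]; out(ip, 2) = x[2];
      ++ip;
      if (ip <= np - 1 && times[ip] > tend + 1e-12) break;
    }
    t0 = tend;
  }
  return List::create(_["times"] = wrap(times), _["states"] = out);
}

// [[Rcpp::export]]
NumericVector trinode_relax_cpp(NumericVector x0, IntegerVector efrom,
                                IntegerVector eto, IntegerVector esign,
                                NumericVector ew, NumericVector eK,
                                NumericVector k, NumericVector g, NumericVector b,
                                double n, double S, double tol, double t_max) {
  TriSys s = make_sys(efrom, eto, esign, ew, eK, k, g, b, n);
  double h = stable_step(s, 0.05);
  double x[3] = {x0[0], x0[1], x0[2]};
  double dx[3];
  double t = 0.0;
  int check_every = 200;
  int it = 0;
  while (t < t_max) {
    s.rk4_step(S, x, h);
    t += h;
    if (++it % check_every == 0) {
      s.rhs(S, x, dx);
      double m = std::max(std::fabs(dx[0]), std::max(std::fabs(dx[1]), std::fabs(dx[2])));
      if (m < tol) break;
    }
  }
  NumericVector res(3);
  res[0] = x[0]; res[1] = x[1]; res[2] = x[2];
  return res;
}
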