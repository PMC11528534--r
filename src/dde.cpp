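// Delayed Hill-logic gene-regulatory network integrator.
//
// State layout: (u, v, R_1..R_na, z_1..z_na) where (u, v) are the cytokine
// inputs (Lotka-Volterra oscillator or frozen constants), R_a the regulation
// response and z_a the concentration of regulated agent a. Each agent's
// regulation stage is
//   dR_a/dt = eps_a * sum_lit 1/(1 + arg^e) - R_a
// with e = n for activating literals, -n for negated ones, and arg the
// (scaled) source value, delayed through a history ring buffer for the two
// delayed literals. The response stage is dz_a/dt = 1/(1 + R_a^m) - z_a.
// Classical RK4; delayed arguments are read by cubic Hermite interpolation
// on stored nodes at t - tau, t + dt/2 - tau, t + dt - tau. Before t0 the
// history is the constant vector hist0. If tau < dt (delay ablation) the
// delayed read falls back to the current stage value, which is exact at
// tau = 0.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

inline double hill(double x, double e) {
  if (x < 0.0) x = 0.0;
  if (x == 0.0) return (e < 0.0) ? 0.0 : (e > 0.0 ? 1.0 : 0.5);
  if (e == 0.0) return 0.5;
  return 1.0 / (1.0 + std::pow(x, e));
}

struct Net {
  int na;
  std::vector<int> ptr, src, sgn, del; // CSR rule structure
  std::vector<double> eps;
  double n_exp, m_exp, tau1, tau2, zscale, alpha;
  bool cyto_frozen;
};

struct Hist {
  // uniform-step ring buffer of z values and derivatives
  int na, cap;
  double t0, dt;
  long filled; // nodes 0..filled stored (value); deriv may lag on newest
  std::vector<double> zv, zd;
  std::vector<double> hist0;
  void init(int na_, int cap_, double t0_, double dt_,
            const std::vector<double> &h0) {
    na = na_; cap = cap_; t0 = t0_; dt = dt_; filled = -1;
    zv.assign((size_t)cap * na, 0.0);
    zd.assign((size_t)cap * na, 0.0);
    hist0 = h0;
  }
  double *val(long k) { return &zv[(size_t)(k % cap) * na]; }
  double *der(long k) { return &zd[(size_t)(k % cap) * na]; }
  double lookup(double tq, int a) {
    // the constant pre-history applies strictly before t0; at t0 the
    // initial state itself is the value of the solution
    if (tq <= t0) {
      if (tq == t0 && filled >= 0) return val(0)[a];
      return hist0[a];
    }
    double s = (tq - t0) / dt;
    long k = (long)std::floor(s);
    if (k >= filled) k = filled - 1;
    if (k < 0) return hist0[a];
    double u = s - (double)k;
    if (u < 0.0) u = 0.0;
    if (u > 1.0) u = 1.0;
    double y0 = val(k)[a], y1 = val(k + 1)[a];
    double d0 = der(k)[a] * dt, d1 = der(k + 1)[a] * dt;
    double u2 = u * u, u3 = u2 * u;
    return (2 * u3 - 3 * u2 + 1) * y0 + (u3 - 2 * u2 + u) * d0 +
           (-2 * u3 + 3 * u2) * y1 + (u3 - u2) * d1;
  }
};

// y: full state (2 + 2*na); t_node: time of the last stored node
void rhs(const Net &net, Hist &hist, double t, double t_node,
         const double *y, double *dy) {
  int na = net.na;
  const double *R = y + 2, *z = y + 2 + na;
  double *dR = dy + 2, *dz = dy + 2 + na;
  if (net.cyto_frozen) {
    dy[0] = 0.0; dy[1] = 0.0;
  } else {
    dy[0] = net.alpha * y[0] * (1.0 - y[1]);
    dy[1] = net.alpha * y[1] * (y[0] - 1.0);
  }
  for (int a = 0; a < na; ++a) {
    int k0 = net.ptr[a], k1 = net.ptr[a + 1];
    if (k1 == k0) { // constitutive: no regulators
      dR[a] = -R[a];
      dz[a] = 0.5 - z[a];
      continue;
    }
    double S = 0.0;
    for (int k = k0; k < k1; ++k) {
      int s = net.src[k];
      double val;
      if (s < 2) {
        val = y[s];
      } else {
        int a2 = s - 2;
        if (net.del[k] == 0) {
          val = net.zscale * z[a2];
        } else {
          double tau = (net.del[k] == 1) ? net.tau1 : net.tau2;
          double tq = t - tau;
          if (tq > t_node) // tau below the step (ablation): current value
            val = net.zscale * z[a2];
          else
            val = net.zscale * hist.lookup(tq, a2);
        }
      }
      double e = (net.sgn[k] > 0) ? net.n_exp : -net.n_exp;
      S += hill(val, e);
    }
    dR[a] = net.eps[a] * S - R[a];
    dz[a] = hill(R[a], net.m_exp) - z[a];
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_dde_integrate(NumericVector state0, double alpha, bool cyto_frozen,
                       IntegerVector rule_ptr, IntegerVector lit_src,
                       IntegerVector lit_sign, IntegerVector lit_delay,
                       NumericVector eps, double n_exp, double m_exp,
                       double tau1, double tau2, NumericVector hist0,
                       double zscale, double t0, double t_end, double dt,
                       int stride) {
  Net net;
  net.na = eps.size();
  net.ptr.assign(rule_ptr.begin(), rule_ptr.end());
  net.src.assign(lit_src.begin(), lit_src.end());
  net.sgn.assign(lit_sign.begin(), lit_sign.end());
  net.del.assign(lit_delay.begin(), lit_delay.end());
  net.eps.assign(eps.begin(), eps.end());
  net.n_exp = n_exp; net.m_exp = m_exp;
  net.tau1 = tau1; net.tau2 = tau2;
  net.zscale = zscale; net.alpha = alpha; net.cyto_frozen = cyto_frozen;
  const int na = net.na, dim = 2 + 2 * na;
  if (state0.size() != dim) stop("state vector has wrong length");
  if (dt <= 0 || t_end <= t0) stop("need dt > 0 and t_end > t0");

  long nsteps = (long)std::ceil((t_end - t0) / dt - 1e-9);
  double max_tau = std::max(std::max(tau1, tau2), 0.0);
  // the ring never needs more nodes than the run has steps (delays beyond
  // the run read the constant pre-history)
  double need = std::min(std::ceil(max_tau / dt), (double)nsteps);
  int cap = (int)need + 8;

  std::vector<double> h0(hist0.begin(), hist0.end());
  Hist hist;
  hist.init(na, cap, t0, dt, h0);

  std::vector<double> y(state0.begin(), state0.end());
  std::vector<double> k1(dim), k2(dim), k3(dim), k4(dim), yt(dim);

  long nsamp = nsteps / stride + 2;
  NumericMatrix out(nsamp, 1 + dim);
  long row = 0;
  auto emit = [&](double t) {
    out(row, 0) = t;
    for (int c = 0; c < dim; ++c) out(row, c + 1) = y[c];
    ++row;
  };

  // node 0
  for (int a = 0; a < na; ++a) hist.val(0)[a] = y[2 + na + a];
  hist.filled = 0;
  emit(t0);

  for (long s = 0; s < nsteps; ++s) {
    double t = t0 + (double)s * dt;
    double tn = t; // last stored node time
    rhs(net, hist, t, tn, y.data(), k1.data());
    for (int a = 0; a < na; ++a) hist.der(s)[a] = k1[2 + na + a];
    for (int c = 0; c < dim; ++c) yt[c] = y[c] + 0.5 * dt * k1[c];
    rhs(net, hist, t + 0.5 * dt, tn, yt.data(), k2.data());
    for (int c = 0; c < dim; ++c) yt[c] = y[c] + 0.5 * dt * k2[c];
    rhs(net, hist, t + 0.5 * dt, tn, yt.data(), k3.data());
    for (int c = 0; c < dim; ++c) yt[c] = y[c] + dt * k3[c];
    rhs(net, hist, t + dt, tn, yt.data(), k4.data());
    for (int c = 0; c < dim; ++c)
      y[c] += dt / 6.0 * (k1[c] + 2.0 * k2[c] + 2.0 * k3[c] + k4[c]);
    long sn = s + 1;
    for (int a = 0; a < na; ++a) hist.val(sn)[a] = y[2 + na + a];
    // derivative at node sn is filled at the start of the next step; seed it
    // with k4 so lookups between the final step and emit stay defined
    for (int a = 0; a < na; ++a) hist.der(sn)[a] = k4[2 + na + a];
    hist.filled = sn;
    if ((s & 255) == 0 && !std::isfinite(y[2 + na])) {
      stop("non-finite state at t = %f", t + dt);
    }
    if (sn % stride == 0 && sn != nsteps) emit(t0 + (double)sn * dt);
  }
  emit(t0 + (double)nsteps * dt);
  NumericMatrix res(row, 1 + dim);
  for (long r = 0; r < row; ++r)
    for (int c = 0; c <= dim; ++c) res(r, c) = out(r, c);
  NumericVector fin(y.begin(), y.end());
  return List::create(_["samples"] = res, _["final"] = fin);
}

// [[Rcpp::export]]
double cpp_lv_period(double u0, double v0, double dt) {
  // parameter-free Lotka-Volterra du = u(1-v), dv = v(u-1); period of the
  // orbit through (u0, v0) via the Poincare section u = 1, du/dt > 0
  double u = u0, v = v0;
  auto f = [](double u, double v, double &du, double &dv) {
    du = u * (1.0 - v); dv = v * (u - 1.0);
  };
  double tprev = -1.0, t = 0.0, first = -1.0;
  double pu = u;
  for (long s = 0; s < (long)(200.0 / dt); ++s) {
    double k1u, k1v, k2u, k2v, k3u, k3v, k4u, k4v;
    f(u, v, k1u, k1v);
    f(u + 0.5 * dt * k1u, v + 0.5 * dt * k1v, k2u, k2v);
    f(u + 0.5 * dt * k2u, v + 0.5 * dt * k2v, k3u, k3v);
    f(u + dt * k3u, v + dt * k3v, k4u, k4v);
    double un = u + dt / 6.0 * (k1u + 2 * k2u + 2 * k3u + k4u);
    double vn = v + dt / 6.0 * (k1v + 2 * k2v + 2 * k3v + k4v);
    double tn = t + dt;
    if (pu <= 1.0 && un > 1.0 && v < 1.0) { // upward crossing of u = 1
      double frac = (1.0 - pu) / (un - pu);
      double tc = t + frac * dt;
      if (first < 0) first = tc;
      else return tc - first;
      tprev = tc;
    }
    pu = un; u = un; v = vn; t = tn;
  }
  (void)tprev;
  stop("no period found");
}
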