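// Core numerics for the hybrid spiking neuron model:
//  - planar flow: vdot = v(a-v)(v-1) - u + I, udot = alpha*(sigma((v-beta)/eps) - u)
//  - after-spike reset (v -> v_r, u -> u + d) located by bisection on the
//    upward crossing of v = v_peak
//  - joint integration of the 2x2 variational (state-transition) matrix with
//    saltation-matrix corrections at each reset
//  - Lyapunov spectrum via periodic Gram-Schmidt renormalisation
// Explicit Dormand-Prince 5(4) with adaptive steps; the flow is non-stiff
// (all Jacobian entries are O(1) at the default parameters).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

struct Pars {
  double a, alpha, beta, eps, I, v_peak, v_r, d;
};

static Pars as_pars(const List& p) {
  Pars q;
  q.a = as<double>(p["a"]);
  q.alpha = as<double>(p["alpha"]);
  q.beta = as<double>(p["beta"]);
  q.eps = as<double>(p["eps"]);
  q.I = as<double>(p["I"]);
  q.v_peak = as<double>(p["v_peak"]);
  q.v_r = as<double>(p["v_r"]);
  q.d = as<double>(p["d"]);
  return q;
}

// numerically safe logistic
static inline double logistic(double x) {
  if (x >= 0.0) {
    double e = std::exp(-x);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

static inline void field(const Pars& p, double v, double u,
                         double& dv, double& du) {
  dv = v * (p.a - v) * (v - 1.0) - u + p.I;
  du = p.alpha * (logistic((v - p.beta) / p.eps) - u);
}

// row-major 2x2 Jacobian of the flow
static inline void jac22(const Pars& p, double v, double J[4]) {
  J[0] = -3.0 * v * v + 2.0 * (p.a + 1.0) * v - p.a;
  J[1] = -1.0;
  double s = logistic((v - p.beta) / p.eps);
  J[2] = (p.alpha / p.eps) * s * (1.0 - s);
  J[3] = -p.alpha;
}

// RHS: y[0]=v, y[1]=u; if n==6, y[2..5] = Phi column-major (p11,p21,p12,p22)
static inline void rhs(const Pars& p, const double* y, double* f, int n) {
  field(p, y[0], y[1], f[0], f[1]);
  if (n == 6) {
    double J[4];
    jac22(p, y[0], J);
    // Phi' = J * Phi, columns independently
    f[2] = J[0] * y[2] + J[1] * y[3];
    f[3] = J[2] * y[2] + J[3] * y[3];
    f[4] = J[0] * y[4] + J[1] * y[5];
    f[5] = J[2] * y[4] + J[3] * y[5];
  }
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                    e3 = 500.0 / 1113 - 7571.0 / 16695,
                    e4 = 125.0 / 192 - 393.0 / 640,
                    e5 = -2187.0 / 6784 + 92097.0 / 339200,
                    e6 = 11.0 / 84 - 187.0 / 2100,
                    e7 = -1.0 / 40;

// One 5th-order trial step of size h from (t,y); fills y5 (solution) and
// returns the scaled error norm (err <= 1 means acceptable).
// k1 must hold rhs at (t,y) on entry. fnew gets rhs at (t+h, y5).
static double dp_step(const Pars& p, int n, const double* y, double h,
                      const double* k1, double* y5, double* fnew,
                      double rtol, double atol) {
  double k2[6], k3[6], k4[6], k5[6], k6[6], yt[6];
  for (int i = 0; i < n; i++) yt[i] = y[i] + h * a21 * k1[i];
  rhs(p, yt, k2, n);
  for (int i = 0; i < n; i++) yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
  rhs(p, yt, k3, n);
  for (int i = 0; i < n; i++)
    yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
  rhs(p, yt, k4, n);
  for (int i = 0; i < n; i++)
    yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
  rhs(p, yt, k5, n);
  for (int i = 0; i < n; i++)
    yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                        a64 * k4[i] + a65 * k5[i]);
  rhs(p, yt, k6, n);
  for (int i = 0; i < n; i++)
    y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] +
                        b6 * k6[i]);
  rhs(p, y5, fnew, n); // FSAL stage k7
  double err = 0.0;
  for (int i = 0; i < n; i++) {
    double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                     e6 * k6[i] + e7 * fnew[i]);
    double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
    double r = ei / sc;
    err += r * r;
  }
  return std::sqrt(err / n);
}

// saltation matrix (row-major) at a crossing state (v_peak, u_minus)
static void saltation(const Pars& p, double u_minus, double S[4]) {
  double dvm, dum, dvp, dup;
  field(p, p.v_peak, u_minus, dvm, dum);
  field(p, p.v_r, u_minus + p.d, dvp, dup);
  S[0] = dvp / dvm;
  S[1] = 0.0;
  S[2] = (dup - dum) / dvm;
  S[3] = 1.0;
}

struct CrossRec {
  double t, u;
};

// ---------------------------------------------------------------------------
// shared hybrid integration engine
// ---------------------------------------------------------------------------
struct Engine {
  Pars p;
  int n;                 // 2 or 6
  double y[6];
  double t;
  bool reset_on;
  bool stop_before_terminal_reset; // leave state_minus at final crossing
  int max_crossings;     // <0: unlimited
  double t_end;
  double rtol, atol, hmax;
  double dt_sample;      // <=0: no dense output
  double quiesce_tol;    // <=0: disabled
  // Lyapunov bookkeeping (n==6 and renorm>0)
  double renorm;         // <=0: disabled
  double transient_end;  // accumulate logs for t >= transient_end
  double sum1, sum2, t_accum0;
  long n_renorm;
  std::vector<double> trace_t, trace_l1, trace_l2;
  int trace_max;

  std::vector<double> out_t, out_v, out_u;
  std::vector<int> out_spk;
  std::vector<CrossRec> crossings;
  double f_minus[2];     // flow at the final crossing (state_minus)
  std::string reason;
  long n_steps, max_steps;

  Engine() : stop_before_terminal_reset(false), max_crossings(-1),
             rtol(1e-12), atol(1e-12), hmax(0.02), dt_sample(-1.0),
             quiesce_tol(-1.0), renorm(-1.0), transient_end(0.0),
             sum1(0.0), sum2(0.0), t_accum0(0.0), n_renorm(0),
             trace_max(512), n_steps(0), max_steps(200000000L) {
    f_minus[0] = NA_REAL; f_minus[1] = NA_REAL;
  }

  void sample(double tt, double vv, double uu, int spk) {
    out_t.push_back(tt); out_v.push_back(vv); out_u.push_back(uu);
    out_spk.push_back(spk);
  }

  // cubic Hermite interpolation of component i at s in [0,1] over step [t,t+h]
  static double hermite(double s, double h, double y0, double f0,
                        double y1, double f1) {
    double s2 = s * s, s3 = s2 * s;
    return (2 * s3 - 3 * s2 + 1) * y0 + (s3 - 2 * s2 + s) * h * f0 +
           (-2 * s3 + 3 * s2) * y1 + (s3 - s2) * h * f1;
  }

  void gram_schmidt(double tt) {
    // columns l1 = (y[2],y[3]), l2 = (y[4],y[5])
    double n1 = std::sqrt(y[2] * y[2] + y[3] * y[3]);
    y[2] /= n1; y[3] /= n1;
    double dot = y[2] * y[4] + y[3] * y[5];
    y[4] -= dot * y[2]; y[5] -= dot * y[3];
    double n2 = std::sqrt(y[4] * y[4] + y[5] * y[5]);
    y[4] /= n2; y[5] /= n2;
    if (tt >= transient_end - 1e-12) {
      if (n_renorm == 0) t_accum0 = tt - renorm; // first accumulated interval
      sum1 += std::log(n1);
      sum2 += std::log(n2);
      n_renorm++;
      double T = tt - t_accum0;
      if ((long)trace_t.size() < trace_max &&
          n_renorm % std::max(1L, (long)((t_end - transient_end) /
                                         (renorm * trace_max))) == 0) {
        trace_t.push_back(tt);
        trace_l1.push_back(sum1 / T);
        trace_l2.push_back(sum2 / T);
      }
    }
  }

  void run() {
    double f0[6], y5[6], fnew[6];
    reason = "horizon";
    rhs(p, y, f0, n);
    double h = std::min(hmax, 1e-4);
    double next_sample = t;
    double next_renorm = (renorm > 0) ? t + renorm : R_PosInf;
    double quiet_since = -1.0;
    bool armed = (y[0] < p.v_peak - 1e-9);
    const double margin = 1e-9;

    if (dt_sample > 0) { sample(t, y[0], y[1], 0); next_sample = t + dt_sample; }

    while (t < t_end - 1e-13) {
      if (++n_steps > max_steps) { reason = "step_limit"; return; }
      double stop_t = std::min(t_end, next_renorm);
      if (h > stop_t - t) h = stop_t - t;
      if (h < 1e-14) h = 1e-14;
      double err = dp_step(p, n, y, h, f0, y5, fnew, rtol, atol);
      if (!std::isfinite(err) || !std::isfinite(y5[0]) || !std::isfinite(y5[1])) {
        reason = "step_failure"; return;
      }
      if (err > 1.0) {
        h *= std::max(0.2, 0.9 * std::pow(err, -0.2));
        continue;
      }
      double h_used = h;
      // step-size suggestion for the next step
      double fac = (err > 1e-30) ? 0.9 * std::pow(err, -0.2) : 5.0;
      double h_next = h * std::min(5.0, std::max(0.2, fac));
      if (h_next > hmax) h_next = hmax;

      // re-arm event detection once below the section
      if (!armed && y[0] < p.v_peak - margin) armed = true;

      bool crossed = armed && (y[0] < p.v_peak) && (y5[0] >= p.v_peak);
      if (crossed) {
        // bisect the sub-step length s in (0, h_used] with g(s) = v(s)-v_peak
        double lo = 0.0, hi = h_used, ge[6], fe[6];
        for (int it = 0; it < 80; it++) {
          double mid = 0.5 * (lo + hi);
          dp_step(p, n, y, mid, f0, ge, fe, rtol, atol);
          double g = ge[0] - p.v_peak;
          if (g >= 0.0) hi = mid; else lo = mid;
          if (hi - lo < 1e-15 * std::max(1.0, std::fabs(t))) break;
        }
        dp_step(p, n, y, hi, f0, ge, fe, rtol, atol);
        double t_ev = t + hi;
        // dense samples up to the event
        if (dt_sample > 0) {
          while (next_sample < t_ev) {
            double s = (next_sample - t) / h_used;
            sample(next_sample,
                   hermite(s, h_used, y[0], f0[0], y5[0], fnew[0]),
                   hermite(s, h_used, y[1], f0[1], y5[1], fnew[1]), 0);
            next_sample += dt_sample;
          }
          sample(t_ev, ge[0], ge[1], 1);
        }
        for (int i = 0; i < n; i++) y[i] = ge[i];
        t = t_ev;
        double u_minus = y[1];
        crossings.push_back({t_ev, u_minus});
        field(p, p.v_peak, u_minus, f_minus[0], f_minus[1]);
        bool terminal = (max_crossings >= 0 &&
                         (int)crossings.size() >= max_crossings);
        if (terminal && stop_before_terminal_reset) {
          reason = "crossings_done";
          return;
        }
        if (reset_on) {
          if (n == 6) {
            double S[4];
            saltation(p, u_minus, S);
            // Phi <- S * Phi (Phi column-major in y[2..5])
            double a0 = y[2], a1 = y[3], b0 = y[4], b1v = y[5];
            y[2] = S[0] * a0 + S[1] * a1;
            y[3] = S[2] * a0 + S[3] * a1;
            y[4] = S[0] * b0 + S[1] * b1v;
            y[5] = S[2] * b0 + S[3] * b1v;
          }
          y[0] = p.v_r;
          y[1] = u_minus + p.d;
          if (dt_sample > 0) sample(t_ev, y[0], y[1], 0);
        } else {
          armed = false; // wait until the orbit falls below the section again
        }
        if (terminal) { reason = "crossings_done"; return; }
        rhs(p, y, f0, n);
        h = std::min(h_next, hmax);
        continue;
      }

      // plain accepted step
      if (dt_sample > 0) {
        while (next_sample <= t + h_used + 1e-15) {
          if (next_sample > t_end + 1e-12) break;
          double s = (next_sample - t) / h_used;
          sample(next_sample,
                 hermite(s, h_used, y[0], f0[0], y5[0], fnew[0]),
                 hermite(s, h_used, y[1], f0[1], y5[1], fnew[1]), 0);
          next_sample += dt_sample;
        }
      }
      t += h_used;
      for (int i = 0; i < n; i++) { y[i] = y5[i]; f0[i] = fnew[i]; }
      h = h_next;

      if (renorm > 0 && t >= next_renorm - 1e-12) {
        gram_schmidt(t);
        rhs(p, y, f0, n); // y changed
        next_renorm += renorm;
      }

      if (quiesce_tol > 0) {
        double fn = std::sqrt(f0[0] * f0[0] + f0[1] * f0[1]);
        if (fn < quiesce_tol) {
          if (quiet_since < 0) quiet_since = t;
          else if (t - quiet_since > 1.0) { reason = "converged"; return; }
        } else {
          quiet_since = -1.0;
        }
      }
    }
    reason = (reason == "horizon") ? "horizon" : reason;
  }
};

// ---------------------------------------------------------------------------
// exported entry points
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate(List pars, double v0, double u0, double t0, double t_end,
                  bool reset_on, double rtol, double atol, double hmax,
                  double dt_sample, int max_spikes, double quiesce_tol) {
  Engine e;
  e.p = as_pars(pars);
  e.n = 2;
  e.y[0] = v0; e.y[1] = u0;
  e.t = t0;
  e.t_end = t_end;
  e.reset_on = reset_on;
  e.rtol = rtol; e.atol = atol; e.hmax = hmax;
  e.dt_sample = dt_sample;
  e.max_crossings = max_spikes;
  e.quiesce_tol = quiesce_tol;
  e.run();
  int ns = e.crossings.size();
  NumericVector spt(ns), spu(ns);
  for (int i = 0; i < ns; i++) { spt[i] = e.crossings[i].t; spu[i] = e.crossings[i].u; }
  return List::create(
    _["t"] = wrap(e.out_t), _["v"] = wrap(e.out_v), _["u"] = wrap(e.out_u),
    _["is_spike"] = wrap(e.out_spk),
    _["spike_t"] = spt, _["spike_u_minus"] = spu,
    _["final_t"] = e.t, _["final_v"] = e.y[0], _["final_u"] = e.y[1],
    _["reason"] = e.reason);
}

// Poincare-section crossings. If from_section, the run starts at
// (v_peak, u0) treated as crossing number 0 (not recorded): the reset is
// applied first (hybrid mode) and the monodromy starts as the identity at
// the post-reset point. Records up to l crossings; in monodromy mode the
// run stops at the l-th crossing *before* its reset, returning Phi and the
// flow at the terminal state_minus.
// [[Rcpp::export]]
List cpp_crossings(List pars, double v0, double u0, int l, bool reset_on,
                   bool from_section, bool with_monodromy, double t_cap,
                   double rtol, double atol, double hmax) {
  Engine e;
  e.p = as_pars(pars);
  e.n = with_monodromy ? 6 : 2;
  if (from_section) {
    if (reset_on) { e.y[0] = e.p.v_r; e.y[1] = u0 + e.p.d; }
    else          { e.y[0] = e.p.v_peak; e.y[1] = u0; }
  } else {
    e.y[0] = v0; e.y[1] = u0;
  }
  if (e.n == 6) { e.y[2] = 1; e.y[3] = 0; e.y[4] = 0; e.y[5] = 1; }
  e.t = 0.0;
  e.t_end = t_cap;
  e.reset_on = reset_on;
  e.rtol = rtol; e.atol = atol; e.hmax = hmax;
  e.max_crossings = l;
  e.stop_before_terminal_reset = with_monodromy;
  e.quiesce_tol = 1e-12;
  e.run();
  int ns = e.crossings.size();
  NumericVector ct(ns), cu(ns);
  for (int i = 0; i < ns; i++) { ct[i] = e.crossings[i].t; cu[i] = e.crossings[i].u; }
  NumericVector phi(4);
  phi[0] = e.y[2]; phi[1] = e.y[3]; phi[2] = e.y[4]; phi[3] = e.y[5];
  return List::create(
    _["cross_t"] = ct, _["cross_u"] = cu, _["n_cross"] = ns,
    _["phi"] = phi,
    _["f_minus"] = NumericVector::create(e.f_minus[0], e.f_minus[1]),
    _["final_t"] = e.t, _["final_v"] = e.y[0], _["final_u"] = e.y[1],
    _["reason"] = e.reason);
}

// [[Rcpp::export]]
List cpp_lyapunov(List pars, double v0, double u0, double total_time,
                  double transient, double renorm, bool reset_on,
                  double rtol, double atol, double hmax) {
  Engine e;
  e.p = as_pars(pars);
  e.n = 6;
  e.y[0] = v0; e.y[1] = u0;
  e.y[2] = 1; e.y[3] = 0; e.y[4] = 0; e.y[5] = 1;
  e.t = 0.0;
  e.t_end = total_time;
  e.reset_on = reset_on;
  e.rtol = rtol; e.atol = atol; e.hmax = hmax;
  e.renorm = renorm;
  e.transient_end = transient;
  e.run();
  double T = (e.n_renorm > 0) ? (e.n_renorm * renorm) : NA_REAL;
  double l1 = (e.n_renorm > 0) ? e.sum1 / T : NA_REAL;
  double l2 = (e.n_renorm > 0) ? e.sum2 / T : NA_REAL;
  return List::create(
    _["lambda1"] = l1, _["lambda2"] = l2,
    _["n_renorm"] = (double)e.n_renorm,
    _["n_spikes"] = (double)e.crossings.size(),
    _["trace_t"] = wrap(e.trace_t), _["trace_l1"] = wrap(e.trace_l1),
    _["trace_l2"] = wrap(e.trace_l2),
    _["final_v"] = e.y[0], _["final_u"] = e.y[1],
    _["reason"] = e.reason);
}
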