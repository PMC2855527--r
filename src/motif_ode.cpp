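// Compiled dynamics core: motif ODE/DDE right-hand sides, an adaptive
// Cash-Karp RK45 integrator, a fixed-step method-of-steps solver for the
// delay models, and the Gaussian observation log-likelihood evaluated over
// a multi-step experimental design. The likelihood is called ~2e5 times per
// MCMC fit, hence compiled.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static const double HILL_H = 2.0;   // Hill coefficient, fixed (never estimated)
static const double TH_FIX = 0.5;   // fixed threshold of the cooperative variants

// model codes (kept in sync with the R-side registry)
enum {
  M_SIM = 1, M_RC = 2, M_FF = 3, M_FB = 4,
  M_SIM_H = 5, M_RC_H = 6, M_FF_H = 7, M_FB_H = 8,
  M_FF_C1_AND = 9, M_CONTROL_ARA = 10, M_FF_C1_OR1 = 11, M_CONTROL_FLA = 12,
  M_FF_C1_OR2 = 13, M_FF_C1_OR3 = 14, M_FF_I1_AND = 15, M_CONTROL_GAL = 16
};

static inline int model_nstates(int model) {
  return (model == M_CONTROL_ARA || model == M_CONTROL_FLA ||
          model == M_CONTROL_GAL) ? 1 : 2;
}

static inline bool model_delayed(int model) {
  return model == M_FF_C1_OR2 || model == M_FF_C1_OR3;
}

static inline double fpos(double s, double th) {
  if (s < 0.0) s = 0.0;
  double sh = std::pow(s, HILL_H), thh = std::pow(th, HILL_H);
  return sh / (thh + sh);
}

static inline double fneg(double s, double th) {
  if (s < 0.0) s = 0.0;
  double sh = std::pow(s, HILL_H), thh = std::pow(th, HILL_H);
  return thh / (thh + sh);
}

// probabilistic-sum OR gate
static inline double gor(double a, double b) { return a + b - a * b; }

// piecewise-constant controlled input; `pre` is the level before the first
// breakpoint (the complementary step level, so delayed signal lookups before
// the step start are meaningful)
struct Signal {
  const double *t, *lvl;
  int n;
  double pre;
  double eval(double tt) const {
    if (n == 0 || tt < t[0]) return pre;
    int i = n - 1;
    while (i > 0 && t[i] > tt) --i;
    return lvl[i];
  }
};

// lag: delayed state accessor (NULL for non-delay models)
struct Lag {
  virtual double state(double tt, int k) const = 0;
  virtual ~Lag() {}
};

static void rhs(int model, double t, const double* y, double* dy,
                const double* p, const Signal& sig, double s2,
                const Lag* lag, double tau) {
  double S = sig.eval(t);
  switch (model) {
  case M_SIM:
    dy[0] = p[0] * S - p[1] * y[0];
    dy[1] = p[2] * S - p[3] * y[1];
    break;
  case M_RC:
    dy[0] = p[0] * S - p[1] * y[0];
    dy[1] = p[2] * y[0] - p[3] * y[1];
    break;
  case M_FF: // p: by ay bzs bzy az
    dy[0] = p[0] * S - p[1] * y[0];
    dy[1] = p[2] * S + p[3] * y[0] - p[4] * y[1];
    break;
  case M_FB: // p: by ay bz az th_zy ; end-product repression of y production
    dy[0] = p[0] * S * fneg(y[1], p[4]) - p[1] * y[0];
    dy[1] = p[2] * y[0] - p[3] * y[1];
    break;
  case M_SIM_H:
    dy[0] = p[0] * fpos(S, TH_FIX) - p[1] * y[0];
    dy[1] = p[2] * fpos(S, TH_FIX) - p[3] * y[1];
    break;
  case M_RC_H:
    dy[0] = p[0] * fpos(S, TH_FIX) - p[1] * y[0];
    dy[1] = p[2] * fpos(y[0], TH_FIX) - p[3] * y[1];
    break;
  case M_FF_H: // p: by ay bzs bzy az
    dy[0] = p[0] * fpos(S, TH_FIX) - p[1] * y[0];
    dy[1] = p[2] * fpos(S, TH_FIX) + p[3] * fpos(y[0], TH_FIX) - p[4] * y[1];
    break;
  case M_FB_H:
    dy[0] = p[0] * fpos(S, TH_FIX) * fneg(y[1], p[4]) - p[1] * y[0];
    dy[1] = p[2] * fpos(y[0], TH_FIX) - p[3] * y[1];
    break;
  case M_FF_C1_AND: // p: by ay bz az th_sy th_sz th_yz
    dy[0] = p[0] * fpos(S, p[4]) - p[1] * y[0];
    dy[1] = p[2] * fpos(S, p[5]) * fpos(y[0], p[6]) - p[3] * y[1];
    break;
  case M_CONTROL_ARA: // p: bz az th_s th_l ; s2 = lactose/IPTG input
    dy[0] = p[0] * fpos(S, p[2]) * fpos(s2, p[3]) - p[1] * y[0];
    break;
  case M_FF_C1_OR1:
    dy[0] = p[0] * fpos(S, p[4]) - p[1] * y[0];
    dy[1] = p[2] * gor(fpos(S, p[5]), fpos(y[0], p[6])) - p[3] * y[1];
    break;
  case M_CONTROL_FLA: // p: bz az ; linearly signal-regulated target
    dy[0] = p[0] * S - p[1] * y[0];
    break;
  case M_FF_C1_OR2: { // p: ... th_yz tau ; lagged intermediate in the gate
    double ylag = lag->state(t - tau, 0);
    dy[0] = p[0] * fpos(S, p[4]) - p[1] * y[0];
    dy[1] = p[2] * gor(fpos(S, p[5]), fpos(ylag, p[6])) - p[3] * y[1];
    break;
  }
  case M_FF_C1_OR3: { // delayed signal drives y; lagged y drives z
    double Slag = sig.eval(t - tau);
    double ylag = lag->state(t - tau, 0);
    dy[0] = p[0] * fpos(Slag, p[4]) - p[1] * y[0];
    dy[1] = p[2] * gor(fpos(S, p[5]), fpos(ylag, p[6])) - p[3] * y[1];
    break;
  }
  case M_FF_I1_AND:
    dy[0] = p[0] * fpos(S, p[4]) - p[1] * y[0];
    dy[1] = p[2] * fpos(S, p[5]) * fneg(y[0], p[6]) - p[3] * y[1];
    break;
  case M_CONTROL_GAL: // p: bz az th_s th_l ; s2 = LacI repressor input
    dy[0] = p[0] * fpos(S, p[2]) * fneg(s2, p[3]) - p[1] * y[0];
    break;
  default:
    Rcpp::stop("unknown model code");
  }
}

// ---- adaptive Cash-Karp RK45 over one smooth segment --------------------

static const double CK_B[6][5] = {
  {0, 0, 0, 0, 0},
  {1.0 / 5, 0, 0, 0, 0},
  {3.0 / 40, 9.0 / 40, 0, 0, 0},
  {3.0 / 10, -9.0 / 10, 6.0 / 5, 0, 0},
  {-11.0 / 54, 5.0 / 2, -70.0 / 27, 35.0 / 27, 0},
  {1631.0 / 55296, 175.0 / 512, 575.0 / 13824, 44275.0 / 110592, 253.0 / 4096}
};
static const double CK_A[6] = {0, 1.0 / 5, 3.0 / 10, 3.0 / 5, 1.0, 7.0 / 8};
static const double CK_C5[6] = {37.0 / 378, 0, 250.0 / 621, 125.0 / 594, 0, 512.0 / 1771};
static const double CK_C4[6] = {2825.0 / 27648, 0, 18575.0 / 48384, 13525.0 / 55296,
                                277.0 / 14336, 1.0 / 4};

// integrate y in place from t0 to t1 (t1 > t0); returns false on failure
static bool rk45_segment(int model, const double* p, const Signal& sig,
                         double s2, double t0, double t1, double* y, int n,
                         double rtol, double atol) {
  double t = t0;
  double h = (t1 - t0) / 10.0;
  if (h <= 0) return true;
  double k[6][3], ytmp[3], y5[3], y4[3];
  long nstep = 0;
  const long max_steps = 2000000L;
  while (t < t1) {
    if (++nstep > max_steps) return false;
    if (t + h > t1) h = t1 - t;
    for (int s = 0; s < 6; ++s) {
      for (int i = 0; i < n; ++i) {
        double acc = y[i];
        for (int j = 0; j < s; ++j) acc += h * CK_B[s][j] * k[j][i];
        ytmp[i] = acc;
      }
      rhs(model, t + CK_A[s] * h, ytmp, k[s], p, sig, s2, NULL, 0.0);
    }
    double err = 0.0;
    bool bad = false;
    for (int i = 0; i < n; ++i) {
      double d5 = 0.0, d4 = 0.0;
      for (int s = 0; s < 6; ++s) {
        d5 += CK_C5[s] * k[s][i];
        d4 += CK_C4[s] * k[s][i];
      }
      y5[i] = y[i] + h * d5;
      y4[i] = y[i] + h * d4;
      if (!std::isfinite(y5[i])) bad = true;
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      err = std::max(err, std::fabs(y5[i] - y4[i]) / sc);
    }
    if (!bad && err <= 1.0) {
      t += h;
      for (int i = 0; i < n; ++i) y[i] = y5[i];
    }
    double fac = bad ? 0.2 : std::max(0.2, std::min(5.0, 0.9 * std::pow(err > 1e-300 ? err : 1e-300, -0.2)));
    h *= fac;
    if (h < 1e-12 * std::max(1.0, std::fabs(t1 - t0))) return false;
  }
  return true;
}

// integrate a non-delay model from t0 through sorted output times, splitting
// at signal breakpoints; out is len(times) x n, column-major
static bool ode_solve(int model, const double* p, const Signal& sig, double s2,
                      double t0, const double* y0,
                      const double* times, int ntimes, int n,
                      double rtol, double atol, double* out) {
  double y[3];
  for (int i = 0; i < n; ++i) y[i] = y0[i];
  double t = t0;
  for (int m = 0; m < ntimes; ++m) {
    double target = times[m];
    if (target < t - 1e-12) return false;
    // split at breakpoints inside (t, target)
    for (int b = 0; b < sig.n; ++b) {
      double tb = sig.t[b];
      if (tb > t + 1e-12 && tb < target - 1e-12) {
        if (!rk45_segment(model, p, sig, s2, t, tb, y, n, rtol, atol)) return false;
        t = tb;
      }
    }
    if (target > t) {
      if (!rk45_segment(model, p, sig, s2, t, target, y, n, rtol, atol)) return false;
      t = target;
    }
    for (int i = 0; i < n; ++i) out[m + ntimes * i] = y[i];
  }
  return true;
}

// ---- delay models: fixed-step RK4 method-of-steps -----------------------

struct GridLag : public Lag {
  double t0, h;
  const std::vector<double>* ys; // per state, values on the grid up to `front`
  int n, front;                  // front = index of last computed grid point
  const double* y0;
  double state(double tt, int k) const {
    if (tt <= t0) return y0[k];
    double x = (tt - t0) / h;
    int i = (int)std::floor(x);
    if (i >= front) return ys[k][front]; // lag shorter than step: clamp to front
    double w = x - i;
    return (1.0 - w) * ys[k][i] + w * ys[k][i + 1];
  }
};

static bool dde_solve(int model, const double* p, const Signal& sig, double s2,
                      double t0, const double* y0,
                      const double* times, int ntimes, int n,
                      double tau, double* out) {
  double tmax = times[ntimes - 1];
  if (tmax <= t0) {
    for (int m = 0; m < ntimes; ++m)
      for (int i = 0; i < n; ++i) out[m + ntimes * i] = y0[i];
    return true;
  }
  if (!(tau >= 0.0) || !std::isfinite(tau)) return false;
  // step no larger than the lag (method of steps) nor 0.02; floored so a
  // vanishing lag cannot stall the solver (the lag lookup then clamps)
  double h = std::min(0.02, std::max(tau, 1e-3));
  long nstep = (long)std::ceil((tmax - t0) / h);
  if (nstep > 2000000L) return false;
  h = (tmax - t0) / nstep;

  std::vector<double> ys[2];
  for (int i = 0; i < n; ++i) ys[i].assign(nstep + 1, 0.0);
  for (int i = 0; i < n; ++i) ys[i][0] = y0[i];

  GridLag lag;
  lag.t0 = t0; lag.h = h; lag.ys = ys; lag.n = n; lag.y0 = y0;

  double y[3], k1[3], k2[3], k3[3], k4[3], ytmp[3];
  for (int i = 0; i < n; ++i) y[i] = y0[i];
  for (long s = 0; s < nstep; ++s) {
    lag.front = (int)s;
    double t = t0 + s * h;
    rhs(model, t, y, k1, p, sig, s2, &lag, tau);
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + 0.5 * h * k1[i];
    rhs(model, t + 0.5 * h, ytmp, k2, p, sig, s2, &lag, tau);
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + 0.5 * h * k2[i];
    rhs(model, t + 0.5 * h, ytmp, k3, p, sig, s2, &lag, tau);
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * k3[i];
    rhs(model, t + h, ytmp, k4, p, sig, s2, &lag, tau);
    for (int i = 0; i < n; ++i) {
      y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (!std::isfinite(y[i])) return false;
      ys[i][s + 1] = y[i];
    }
  }
  // linear interpolation of outputs on the dense grid
  for (int m = 0; m < ntimes; ++m) {
    double tt = times[m];
    for (int i = 0; i < n; ++i) {
      double v;
      if (tt <= t0) v = y0[i];
      else {
        double x = (tt - t0) / h;
        long j = (long)std::floor(x);
        if (j >= nstep) v = ys[i][nstep];
        else {
          double w = x - j;
          v = (1.0 - w) * ys[i][j] + w * ys[i][j + 1];
        }
      }
      out[m + ntimes * i] = v;
    }
  }
  return true;
}

static bool solve_dispatch(int model, const double* p, int npar,
                           const Signal& sig, double s2, double t0,
                           const double* y0, const double* times, int ntimes,
                           int n, double rtol, double atol, double* out) {
  if (model_delayed(model)) {
    double tau = p[npar - 1]; // delay is the last parameter by convention
    return dde_solve(model, p, sig, s2, t0, y0, times, ntimes, n, tau, out);
  }
  return ode_solve(model, p, sig, s2, t0, y0, times, ntimes, n, rtol, atol, out);
}

// [[Rcpp::export]]
NumericMatrix cpp_integrate(int model, NumericVector params,
                            NumericVector sig_t, NumericVector sig_lvl,
                            double sig_pre, double s2, double t0,
                            NumericVector y0, NumericVector times,
                            double rtol, double atol) {
  int n = model_nstates(model);
  if ((int)y0.size() != n) stop("initial state has wrong length");
  int ntimes = times.size();
  Signal sig;
  sig.t = sig_t.begin(); sig.lvl = sig_lvl.begin();
  sig.n = sig_t.size(); sig.pre = sig_pre;
  NumericMatrix out(ntimes, n);
  bool ok = solve_dispatch(model, params.begin(), params.size(), sig, s2, t0,
                           y0.begin(), times.begin(), ntimes, n, rtol, atol,
                           out.begin());
  out.attr("ok") = ok;
  return out;
}

// steps: list of lists with fields sig_t, sig_lvl, sig_pre, s2, t0, y0,
// obs_t (sorted unique), obs_tidx (0-based into obs_t), obs_state (0-based),
// obs_val
// [[Rcpp::export]]
double cpp_loglik(int model, NumericVector params, double sigma2, List steps,
                  double rtol, double atol) {
  if (!(sigma2 > 0.0) || !std::isfinite(sigma2)) return R_NegInf;
  for (int i = 0; i < params.size(); ++i)
    if (!std::isfinite(params[i])) return R_NegInf;
  int n = model_nstates(model);
  double ll = 0.0;
  const double lc = -0.5 * std::log(2.0 * M_PI * sigma2);
  double buf[3 * 256];
  std::vector<double> heap;
  for (int s = 0; s < steps.size(); ++s) {
    List st = steps[s];
    NumericVector sig_t = st["sig_t"], sig_lvl = st["sig_lvl"];
    NumericVector y0 = st["y0"], obs_t = st["obs_t"], obs_val = st["obs_val"];
    IntegerVector obs_tidx = st["obs_tidx"], obs_state = st["obs_state"];
    double s2 = as<double>(st["s2"]), sig_pre = as<double>(st["sig_pre"]);
    double t0 = as<double>(st["t0"]);
    Signal sig;
    sig.t = sig_t.begin(); sig.lvl = sig_lvl.begin();
    sig.n = sig_t.size(); sig.pre = sig_pre;
    int ntimes = obs_t.size();
    double* out = buf;
    if (ntimes * n > 3 * 256) {
      heap.assign((size_t)ntimes * n, 0.0);
      out = heap.data();
    }
    bool ok = solve_dispatch(model, params.begin(), params.size(), sig, s2, t0,
                             y0.begin(), obs_t.begin(), ntimes, n, rtol, atol,
                             out);
    if (!ok) return R_NegInf;
    for (int r = 0; r < obs_val.size(); ++r) {
      double pred = out[obs_tidx[r] + ntimes * obs_state[r]];
      if (!std::isfinite(pred)) return R_NegInf;
      double e = obs_val[r] - pred;
      ll += lc - 0.5 * e * e / sigma2;
    }
  }
  return ll;
}
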