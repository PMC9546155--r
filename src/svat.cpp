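// Compiled core: Mualem-van Genuchten hydraulic functions, an implicit
// (backward-Euler, modified-Picard) Richards-equation solver on a layered
// column, root-supply / half-sine transpiration closures, and the daily
// soil loop used by run_simulation().
//
// Conventions: matric potential psi in kPa (<= 0), alpha in 1/hPa,
// conductivity and fluxes in mm/day, depth positive downward in mm.
// Head conversion uses 1 kPa = 101.97 mm water column.

#include <Rcpp.h>
using namespace Rcpp;

static const double CONV = 101.97;   // mm head per kPa
// Wet-end regularization of the solver's storage law: above PSI_E the
// water capacity decays smoothly (exponentially, scale PSI_S) from its
// van Genuchten value at PSI_E to a small saturated storage coefficient
// SS_SAT, and conductivity approaches Ksat. This keeps C(psi) continuous
// through saturation — a capacity discontinuity at psi = 0 makes
// fixed-point iterations cycle — while the public retention-curve API
// keeps the exact van Genuchten form.
static const double PSI_E = -0.25;   // kPa
static const double PSI_S = 1.0;     // kPa capacity decay scale above PSI_E
static const double PSI_SK = 0.1;    // kPa conductivity rise scale (K is steep)
static const double SS_SAT = 1e-4;   // 1/kPa
static const double PSI_MIN = -1e6;  // kPa floor

static long g_iters = 0, g_substeps = 0, g_fails = 0;
// [[Rcpp::export]]
Rcpp::NumericVector solver_counters_cpp(bool reset = false) {
  Rcpp::NumericVector v = Rcpp::NumericVector::create(
    (double)g_iters, (double)g_substeps, (double)g_fails);
  if (reset) { g_iters = g_substeps = g_fails = 0; }
  return v;
}

// soil matrix column indices
enum { COL_DZ = 0, COL_THR, COL_THS, COL_ALPHA, COL_N, COL_KSAT, COL_TAU, COL_GRAVEL };

static inline double se_of_psi(double psi_kpa, double alpha, double n) {
  if (psi_kpa >= 0.0) return 1.0;
  double h = -psi_kpa * 10.0;            // hPa magnitude
  double m = 1.0 - 1.0 / n;
  return std::pow(1.0 + std::pow(alpha * h, n), -m);
}

static inline double theta_of_psi(double psi, double thr, double ths,
                                  double alpha, double n) {
  return thr + (ths - thr) * se_of_psi(psi, alpha, n);
}

// dtheta/dpsi (per kPa), >= 0
static inline double cap_of_psi(double psi, double thr, double ths,
                                double alpha, double n) {
  if (psi >= 0.0) return 0.0;
  double h = -psi * 10.0;
  double m = 1.0 - 1.0 / n;
  double ah = alpha * h;
  double ahn = std::pow(ah, n);
  double dse_dh = m * n * alpha * std::pow(ah, n - 1.0) *
                  std::pow(1.0 + ahn, -m - 1.0);
  return (ths - thr) * dse_dh * 10.0;   // dh/dpsi = -10 hPa/kPa, sign folded
}

static inline double k_of_psi(double psi, double thr, double ths, double alpha,
                              double n, double ksat, double tau) {
  double se = se_of_psi(psi, alpha, n);
  if (se >= 1.0) return ksat;
  double m = 1.0 - 1.0 / n;
  double t1 = 1.0 - std::pow(1.0 - std::pow(se, 1.0 / m), m);
  return ksat * std::pow(se, tau) * t1 * t1;
}

// [[Rcpp::export]]
NumericVector vg_theta_cpp(NumericVector psi, double thr, double ths,
                           double alpha, double n) {
  int len = psi.size();
  NumericVector out(len);
  for (int i = 0; i < len; ++i) out[i] = theta_of_psi(psi[i], thr, ths, alpha, n);
  return out;
}

// [[Rcpp::export]]
NumericVector vg_psi_cpp(NumericVector theta, double thr, double ths,
                         double alpha, double n) {
  int len = theta.size();
  NumericVector out(len);
  double m = 1.0 - 1.0 / n;
  for (int i = 0; i < len; ++i) {
    double se = (theta[i] - thr) / (ths - thr);
    if (se >= 1.0) { out[i] = 0.0; continue; }
    double h = std::pow(std::pow(se, -1.0 / m) - 1.0, 1.0 / n) / alpha; // hPa
    out[i] = -h / 10.0;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector mualem_k_cpp(NumericVector psi, double thr, double ths,
                           double alpha, double n, double ksat, double tau) {
  int len = psi.size();
  NumericVector out(len);
  for (int i = 0; i < len; ++i)
    out[i] = k_of_psi(psi[i], thr, ths, alpha, n, ksat, tau);
  return out;
}

// ---------------------------------------------------------------------------
// Richards solver internals

struct Column {
  int n;
  std::vector<double> dz, thr, ths, alpha, nn, ksat, tau, fe, dzn;
  std::vector<double> thE, cE, kE;   // wet-end constants at PSI_E
  explicit Column(const NumericMatrix& soil) {
    n = soil.nrow();
    dz.resize(n); thr.resize(n); ths.resize(n); alpha.resize(n);
    nn.resize(n); ksat.resize(n); tau.resize(n); fe.resize(n);
    thE.resize(n); cE.resize(n); kE.resize(n);
    for (int i = 0; i < n; ++i) {
      dz[i] = soil(i, COL_DZ); thr[i] = soil(i, COL_THR);
      ths[i] = soil(i, COL_THS); alpha[i] = soil(i, COL_ALPHA);
      nn[i] = soil(i, COL_N); ksat[i] = soil(i, COL_KSAT);
      tau[i] = soil(i, COL_TAU); fe[i] = 1.0 - soil(i, COL_GRAVEL);
      thE[i] = theta_of_psi(PSI_E, thr[i], ths[i], alpha[i], nn[i]);
      cE[i] = std::max(cap_of_psi(PSI_E, thr[i], ths[i], alpha[i], nn[i]),
                       SS_SAT);
      kE[i] = k_of_psi(PSI_E, thr[i], ths[i], alpha[i], nn[i], ksat[i],
                       tau[i]);
    }
    dzn.resize(n - 1 > 0 ? n - 1 : 0);
    for (int i = 0; i + 1 < n; ++i) dzn[i] = 0.5 * (dz[i] + dz[i + 1]);
  }
  // solver storage law above PSI_E: C decays from cE to SS_SAT with
  // scale PSI_S; theta is its integral (continuous at PSI_E)
  double theta(int i, double psi) const {
    if (psi >= PSI_E) {
      double u = psi - PSI_E;
      return thE[i] + SS_SAT * u +
             (cE[i] - SS_SAT) * PSI_S * (1.0 - std::exp(-u / PSI_S));
    }
    return theta_of_psi(psi, thr[i], ths[i], alpha[i], nn[i]);
  }
  double cap(int i, double psi) const {
    if (psi >= PSI_E)
      return SS_SAT + (cE[i] - SS_SAT) * std::exp(-(psi - PSI_E) / PSI_S);
    return cap_of_psi(psi, thr[i], ths[i], alpha[i], nn[i]);
  }
  double keff(int i, double psi) const {  // gravel-corrected conductivity
    if (psi >= PSI_E) {
      double w = std::exp(-(psi - PSI_E) / PSI_SK);
      return fe[i] * (ksat[i] - (ksat[i] - kE[i]) * w);
    }
    return fe[i] * k_of_psi(psi, thr[i], ths[i], alpha[i],
                            nn[i], ksat[i], tau[i]);
  }
  // evaluate theta, dtheta/dpsi and gravel-corrected K in one pass
  void eval(int i, double psi, double& th, double& C, double& K) const {
    if (psi >= PSI_E) {
      th = theta(i, psi); C = cap(i, psi); K = keff(i, psi);
      return;
    }
    double h = -psi * 10.0;
    double m = 1.0 - 1.0 / nn[i];
    double ah = alpha[i] * h;
    double ahn = std::pow(ah, nn[i]);
    double opahn = 1.0 + ahn;
    double se = std::pow(opahn, -m);
    th = thr[i] + (ths[i] - thr[i]) * se;
    C = (ths[i] - thr[i]) * m * nn[i] * alpha[i] * (ahn / ah) / (opahn * std::pow(opahn, m)) * 10.0;
    double t1 = 1.0 - std::pow(1.0 - std::pow(se, 1.0 / m), m);
    K = fe[i] * ksat[i] * std::pow(se, tau[i]) * t1 * t1;
  }
  // storage of layer i in mm
  double store(int i, double psi) const {
    return theta(i, psi) * dz[i] * fe[i];
  }
};

static void thomas(std::vector<double>& a, std::vector<double>& b,
                   std::vector<double>& c, std::vector<double>& d,
                   std::vector<double>& x) {
  int n = b.size();
  for (int i = 1; i < n; ++i) {
    double w = a[i] / b[i - 1];
    b[i] -= w * c[i - 1];
    d[i] -= w * d[i - 1];
  }
  x[n - 1] = d[n - 1] / b[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = (d[i] - c[i] * x[i + 1]) / b[i];
}

// One backward-Euler substep of length dt (days). Returns true on
// convergence; outputs new psi, drainage (mm), runoff (mm), residual (mm).
static bool substep(const Column& col, std::vector<double>& psi,
                    const double* src, const double* snk, double drain,
                    double dt, double& drainage, double& runoff,
                    double& resid) {
  int n = col.n;
  std::vector<double> psio(psi), tho(n), p(psi);
  for (int i = 0; i < n; ++i) tho[i] = col.theta(i, psio[i]);
  bool dirichlet_top = false;

  std::vector<double> a(n), b(n), c(n), d(n), x(n), km(n > 1 ? n - 1 : 0);
  std::vector<double> thv(n), Cv(n), Kv(n);
  const int maxit = 40;
  const double tol_psi = 2e-6;     // kPa
  const double tol_mass = 1e-9;    // mm per substep

  for (int attempt = 0; attempt < 2; ++attempt) {  // flux BC, then Dirichlet
    p = psio;
    bool converged = false;
    double dmax_prev = R_PosInf;
    double omega = 1.0;                  // adaptive under-relaxation
    for (int it = 0; it < maxit; ++it) {
      ++g_iters;
      for (int i = 0; i < n; ++i) col.eval(i, p[i], thv[i], Cv[i], Kv[i]);
      for (int i = 0; i + 1 < n; ++i) km[i] = 0.5 * (Kv[i] + Kv[i + 1]);
      double kbot = drain * Kv[n - 1];
      for (int i = 0; i < n; ++i) {
        // capacity floor: damping of the Picard path at the dry end only;
        // the converged solution is set by theta(psi), not by C
        double C = std::max(Cv[i], 1e-9);
        double diag = C * col.dz[i] * col.fe[i];
        double up = 0.0, dn = 0.0, grav = 0.0;
        if (i > 0) { up = dt * km[i - 1] * CONV / col.dzn[i - 1]; grav += dt * km[i - 1]; }
        if (i + 1 < n) { dn = dt * km[i] * CONV / col.dzn[i]; grav -= dt * km[i]; }
        else grav -= dt * kbot;
        a[i] = (i > 0) ? -up : 0.0;
        c[i] = (i + 1 < n) ? -dn : 0.0;
        b[i] = diag + up + dn;
        d[i] = diag * p[i] - (thv[i] - tho[i]) * col.dz[i] * col.fe[i] +
               grav + dt * (src[i] - snk[i]);
      }
      if (dirichlet_top) { b[0] = 1.0; c[0] = 0.0; d[0] = 0.0; a[0] = 0.0; }
      thomas(a, b, c, d, x);
      double dmax = 0.0;
      for (int i = 0; i < n; ++i) {
        double xi = std::min(std::max(x[i], PSI_MIN), 1e4);
        double step = omega * (xi - p[i]);
        dmax = std::max(dmax, std::fabs(step));
        p[i] += step;
      }
      if (dmax > dmax_prev) omega = std::max(0.25, omega * 0.5);
      else omega = std::min(1.0, omega * 1.25);
      // bail out early when Picard truly stagnates; the caller halves dt
      if (it >= 12 && dmax > 0.95 * dmax_prev && dmax > 100.0 * tol_psi) break;
      dmax_prev = dmax;
      if (dmax < tol_psi) {
        // true nonlinear residual with fully updated K and theta
        for (int i = 0; i + 1 < n; ++i)
          km[i] = 0.5 * (col.keff(i, p[i]) + col.keff(i + 1, p[i + 1]));
        double kbot2 = drain * col.keff(n - 1, p[n - 1]);
        // under a Dirichlet top the accepted infiltration is defined from
        // the layer-1 balance, so layer 1 closes by construction and the
        // residual is accumulated over the remaining layers only
        double res = 0.0;
        for (int i = (dirichlet_top ? 1 : 0); i < n; ++i) {
          double qin = 0.0, qout = 0.0;
          if (i > 0) qin = km[i - 1] * ((p[i - 1] - p[i]) * CONV / col.dzn[i - 1] + 1.0);
          if (i + 1 < n) qout = km[i] * ((p[i] - p[i + 1]) * CONV / col.dzn[i] + 1.0);
          else qout = kbot2;
          res += (col.store(i, p[i]) - col.store(i, psio[i])) -
                 dt * (qin - qout + src[i] - snk[i]);
        }
        if (std::fabs(res) < tol_mass) { converged = true; break; }
      }
    }
    if (!converged) { ++g_fails; return false; }
    if (!dirichlet_top && p[0] > 1e-9 && src[0] > 0.0) {
      dirichlet_top = true;       // ponded top: redo with psi_1 = 0
      continue;
    }
    break;
  }

  // outputs from the converged state
  double kbot = drain * col.keff(n - 1, p[n - 1]);
  drainage = dt * kbot;
  runoff = 0.0;
  if (dirichlet_top) {
    // infiltration actually accepted by layer 1; the rest is surface runoff
    double q12 = (n > 1)
      ? 0.5 * (col.keff(0, p[0]) + col.keff(1, p[1])) *
        ((p[0] - p[1]) * CONV / col.dzn[0] + 1.0)
      : kbot;
    double dW1 = col.store(0, p[0]) - col.store(0, psio[0]);
    double accepted = dW1 + dt * (q12 + snk[0]);
    runoff = std::max(0.0, dt * src[0] - accepted);
  }
  // mass residual over the substep
  double dW = 0.0, in = 0.0, out = drainage + runoff;
  for (int i = 0; i < col.n; ++i) {
    dW += col.store(i, p[i]) - col.store(i, psio[i]);
    in += dt * src[i];
    out += dt * snk[i];
  }
  resid = dW - (in - out);
  if (dirichlet_top) { runoff += resid; resid = 0.0; }  // layer-1 bookkeeping
  if (runoff < 0.0) { resid += runoff; runoff = 0.0; }
  ++g_substeps;
  psi = p;
  return true;
}

// Advance the column by dt_total days with adaptive substepping.
static void richards_advance(const Column& col, std::vector<double>& psi,
                             const double* src_in, const double* snk,
                             double drain, double dt_total, int fixed_substeps,
                             double& drainage, double& runoff, double& resid) {
  drainage = 0.0; runoff = 0.0; resid = 0.0;
  // saturation excess: a layer can accept its free pore space plus what it
  // can pass to the layers below (bounded by their own remaining capacity
  // and the saturated interface conductivity); the rest backs up and leaves
  // as surface runoff. Rates in mm/day over the step.
  std::vector<double> src(src_in, src_in + col.n);
  {
    int n = col.n;
    std::vector<double> room(n);
    for (int i = n - 1; i >= 0; --i) {
      double pass_below;
      if (i == n - 1) pass_below = drain * col.fe[i] * col.ksat[i];
      else {
        double kint = 0.5 * (col.fe[i] * col.ksat[i] +
                             col.fe[i + 1] * col.ksat[i + 1]);
        pass_below = std::min(kint, room[i + 1]);
      }
      double free_pore = std::max(0.0, col.ths[i] - col.theta(i, psi[i])) *
                         col.dz[i] * col.fe[i] / dt_total;
      room[i] = free_pore + snk[i] + pass_below - src[i];
      if (room[i] < 0.0) {            // cannot take all of its source
        double excess = -room[i];
        room[i] = 0.0;
        src[i] -= excess;
        if (i > 0) src[i - 1] += excess;
        else runoff += excess * dt_total;
      }
    }
  }
  if (fixed_substeps > 0) {
    double dt = dt_total / fixed_substeps;
    for (int s = 0; s < fixed_substeps; ++s) {
      double dr, ro, rs;
      double dts = dt;
      // even in fixed mode, halve on non-convergence within the slice
      double done = 0.0;
      while (done < dt - 1e-15) {
        if (substep(col, psi, src.data(), snk, drain, dts, dr, ro, rs)) {
          drainage += dr; runoff += ro; resid += rs; done += dts;
        } else {
          dts *= 0.5;
          if (dts < dt_total / 1048576.0)
            stop("Richards solver failed to converge (fixed substeps)");
        }
        dts = std::min(dts, dt - done);
        if (dts <= 0.0) break;
      }
    }
    return;
  }
  // flux-based initial substep: heavy infiltration days start finer so the
  // backward-Euler time-discretization error stays small
  double srctot = 0.0;
  for (int i = 0; i < col.n; ++i) srctot += src[i];

  double nini = std::max(1.0, std::ceil(srctot * dt_total / 5.0));
  double t = 0.0, dt = dt_total / nini;
  const double dt_min = dt_total / 1024.0;   // 2^-10 of the step
  const double dt_max = dt;
  while (t < dt_total - 1e-15) {
    double dr, ro, rs;
    if (substep(col, psi, src.data(), snk, drain, dt, dr, ro, rs)) {
      drainage += dr; runoff += ro; resid += rs; t += dt;
      dt = std::min(std::min(dt * 2.0, dt_max), dt_total - t);
    } else {
      dt *= 0.5;
      if (dt < dt_min)
        stop("Richards solver failed to converge at minimum substep; "
             "check sources/sinks feasibility");
    }
    if (dt <= 0.0) dt = dt_total - t;
  }
}

// [[Rcpp::export]]
List richards_step_cpp(NumericVector psi, NumericMatrix soil,
                       NumericVector src, NumericVector snk, double drain,
                       double dt = 1.0, int fixed_substeps = 0) {
  Column col(soil);
  std::vector<double> p(psi.begin(), psi.end());
  double drainage, runoff, resid;
  richards_advance(col, p, REAL(src), REAL(snk), drain, dt, fixed_substeps,
                   drainage, runoff, resid);
  // day-end clamp: release (tiny) elastic storage above saturation as runoff
  double swat = 0.0;
  NumericVector out(col.n);
  for (int i = 0; i < col.n; ++i) {
    if (p[i] > 0.0) {   // ponded water at step end leaves as surface runoff
      runoff += col.store(i, p[i]) - col.store(i, 0.0);
      p[i] = 0.0;
    }
    out[i] = p[i];
    swat += col.store(i, p[i]);
  }
  return List::create(_["psi"] = out, _["drainage"] = drainage,
                      _["runoff"] = runoff, _["residual"] = resid,
                      _["swat"] = swat);
}

// ---------------------------------------------------------------------------
// Root supply and half-sine transpiration

// [[Rcpp::export]]
List supply_rate_cpp(NumericVector psi, NumericMatrix soil,
                     NumericVector rootfrac, double mxkpl, double psicr,
                     double fxylem, double rhiz_c) {
  Column col(soil);
  int n = col.n;
  std::vector<double> g(n, 0.0);
  double gsum = 0.0;
  for (int i = 0; i < n; ++i) {
    double rf = rootfrac[i];
    double psimpa = psi[i] / 1000.0;
    if (rf <= 0.0 || psimpa <= psicr) continue;
    double kr = (fxylem < 1.0) ? mxkpl / (1.0 - fxylem) * rf : R_PosInf;
    double gr = rhiz_c * col.keff(i, psi[i]) * rf;
    double gi;
    if (!R_finite(kr)) gi = gr;
    else if (gr <= 0.0) gi = 0.0;
    else gi = 1.0 / (1.0 / kr + 1.0 / gr);
    g[i] = gi;
    gsum += gi;
  }
  NumericVector w(n, 0.0);
  if (gsum <= 0.0)
    return List::create(_["smax"] = 0.0, _["weights"] = w);
  double kx = (fxylem > 0.0) ? mxkpl / fxylem : R_PosInf;
  double gtot = R_finite(kx) ? 1.0 / (1.0 / kx + 1.0 / gsum) : gsum;
  double psieff = 0.0;
  for (int i = 0; i < n; ++i) psieff += g[i] * (psi[i] / 1000.0);
  psieff /= gsum;
  double smax = std::max(0.0, gtot * (psieff - psicr));
  double wsum = 0.0;
  for (int i = 0; i < n; ++i) {
    double wi = g[i] * std::max(0.0, psi[i] / 1000.0 - psicr);
    w[i] = wi; wsum += wi;
  }
  if (wsum > 0.0) for (int i = 0; i < n; ++i) w[i] /= wsum;
  return List::create(_["smax"] = smax, _["weights"] = w);
}

// Daily actual transpiration: demand follows a half-sine over daylength,
// supply caps the rate; closed-form integral of min(demand, supply).
// [[Rcpp::export]]
double half_sine_ta_cpp(double tp, double smax, double daylength) {
  if (tp <= 0.0) return 0.0;
  if (smax <= 0.0) return 0.0;
  double dl = daylength;                 // hours
  double s = smax / 24.0;                // mm/h sustained supply rate
  double R = M_PI * tp / (2.0 * dl);     // mm/h peak demand
  if (s >= R) return tp;
  double t1 = dl / M_PI * std::asin(s / R);
  return 2.0 * R * dl / M_PI * (1.0 - std::cos(M_PI * t1 / dl)) +
         s * (dl - 2.0 * t1);
}

// ---------------------------------------------------------------------------
// Daily soil loop: supply-limited transpiration, soil evaporation,
// infiltration sources and Richards redistribution, one call per run.

// [[Rcpp::export]]
List soil_loop_cpp(NumericVector psi0, NumericMatrix soil,
                   NumericVector rootfrac, NumericMatrix infil,
                   NumericVector tp, NumericVector eps, NumericVector daylen,
                   double mxkpl, double psicr, double fxylem, double rhiz_c,
                   double rssa, double rref, double drain) {
  Column col(soil);
  int n = col.n, nd = tp.size();
  std::vector<double> psi(psi0.begin(), psi0.end());

  NumericMatrix psim(nd, n), rwum(nd, n);
  NumericVector ta(nd), es(nd), drainage(nd), runoff(nd), swat(nd), resid(nd);
  double theta_fc_top = theta_of_psi(-6.3, col.thr[0], col.ths[0],
                                     col.alpha[0], col.nn[0]);
  double psicr_kpa = psicr * 1000.0;
  std::vector<double> src(n), snk(n), w(n);

  for (int d = 0; d < nd; ++d) {
    // root supply from start-of-day state
    double gsum = 0.0, smax = 0.0;
    {
      std::fill(w.begin(), w.end(), 0.0);
      std::vector<double> g(n, 0.0);
      for (int i = 0; i < n; ++i) {
        double rf = rootfrac[i], psimpa = psi[i] / 1000.0;
        if (rf <= 0.0 || psimpa <= psicr) continue;
        double kr = (fxylem < 1.0) ? mxkpl / (1.0 - fxylem) * rf : R_PosInf;
        double gr = rhiz_c * col.keff(i, psi[i]) * rf;
        double gi;
        if (!R_finite(kr)) gi = gr;
        else if (gr <= 0.0) gi = 0.0;
        else gi = 1.0 / (1.0 / kr + 1.0 / gr);
        g[i] = gi; gsum += gi;
      }
      if (gsum > 0.0) {
        double kx = (fxylem > 0.0) ? mxkpl / fxylem : R_PosInf;
        double gtot = R_finite(kx) ? 1.0 / (1.0 / kx + 1.0 / gsum) : gsum;
        double psieff = 0.0;
        for (int i = 0; i < n; ++i) psieff += g[i] * (psi[i] / 1000.0);
        psieff /= gsum;
        smax = std::max(0.0, gtot * (psieff - psicr));
        double wsum = 0.0;
        for (int i = 0; i < n; ++i) {
          w[i] = g[i] * std::max(0.0, psi[i] / 1000.0 - psicr);
          wsum += w[i];
        }
        if (wsum > 0.0) for (int i = 0; i < n; ++i) w[i] /= wsum;
      }
    }
    double ta_d = half_sine_ta_cpp(tp[d], smax, daylen[d]);

    // soil evaporation, reduced by topsoil dryness relative to field capacity
    double th_top = col.theta(0, psi[0]);
    double es_d = 0.0;
    if (eps[d] > 0.0 && th_top > 1e-9) {
      double rss = rssa * (theta_fc_top / th_top);
      es_d = eps[d] * rref / (rref + rss);
    }

    // cap sinks by plant-extractable water in each layer
    for (int i = 0; i < n; ++i) {
      double th_cr = col.theta(i, psicr_kpa);
      double avail = std::max(0.0, (col.theta(i, psi[i]) - th_cr) *
                                       col.dz[i] * col.fe[i]) * 0.9;
      double want = ta_d * w[i] + (i == 0 ? es_d : 0.0);
      if (want > avail && want > 0.0) {
        double f = avail / want;
        if (i == 0) es_d *= f;
        w[i] *= f;  // reduce this layer's uptake share to what it can yield
      }
    }
    // re-normalize: actual rwu uses (possibly reduced) weights
    double rwsum = 0.0;
    for (int i = 0; i < n; ++i) rwsum += w[i];
    double ta_act = ta_d * rwsum;  // weights summed to 1 before caps
    for (int i = 0; i < n; ++i) {
      snk[i] = ta_d * w[i] + (i == 0 ? es_d : 0.0);
      src[i] = infil(d, i);
      rwum(d, i) = ta_d * w[i];
    }
    double dr, ro, rs;
    richards_advance(col, psi, src.data(), snk.data(), drain, 1.0, 0, dr, ro, rs);
    double sw = 0.0;
    for (int i = 0; i < n; ++i) {
      // positive pressures (saturated zone) are carried as state; the
      // reported matric potential is capped at saturation
      psim(d, i) = std::min(psi[i], 0.0);
      sw += col.store(i, psi[i]);
    }
    ta[d] = ta_act; es[d] = es_d; drainage[d] = dr; runoff[d] = ro;
    swat[d] = sw; resid[d] = rs;
  }
  return List::create(_["psi"] = psim, _["rwu"] = rwum, _["ta"] = ta,
                      _["es"] = es, _["drainage"] = drainage,
                      _["runoff"] = runoff, _["swat"] = swat,
                      _["residual"] = resid);
}
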