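#include <Rcpp.h>
using namespace Rcpp;

// Bilinear neural dynamics coupled to balloon-Windkessel haemodynamics,
// integrated with fixed-step classical RK4. The driving input u is supplied
// already averaged over each integration step (piecewise constant), so the
// injected input mass is independent of dt and stick (impulse) inputs are
// well defined. States per region: neural x, vasodilatory signal s, inflow f,
// blood volume v, deoxyhaemoglobin q. Resting fixed point: x=0, s=0, f=v=q=1.

struct DcmSystem {
  int n;                 // regions
  const double *E;       // n x n effective coupling (column-major), row = to
  const double *C;       // n x m driving gains
  int m;                 // inputs
  // haemodynamic parameters, per region
  const double *kappa, *gamma, *tau, *alpha, *E0;

  // dy for packed state [x(n), s(n), f(n), v(n), q(n)]
  void deriv(const double *y, const double *u, double *dy) const {
    const double *x = y;
    const double *s = y + n, *f = y + 2 * n, *v = y + 3 * n, *q = y + 4 * n;
    double *dx = dy, *ds = dy + n, *df = dy + 2 * n, *dv = dy + 3 * n,
           *dq = dy + 4 * n;
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int j = 0; j < n; ++j) acc += E[i + n * j] * x[j];
      for (int k = 0; k < m; ++k) acc += C[i + n * k] * u[k];
      dx[i] = acc;
    }
    for (int i = 0; i < n; ++i) {
      double fi = f[i], vi = v[i], qi = q[i];
      double ia = 1.0 / alpha[i];
      double fout = std::pow(vi, ia);            // outflow from Windkessel
      double Ef = 1.0 - std::pow(1.0 - E0[i], 1.0 / fi); // O2 extraction
      ds[i] = x[i] - kappa[i] * s[i] - gamma[i] * (fi - 1.0);
      df[i] = s[i];
      dv[i] = (fi - fout) / tau[i];
      dq[i] = (fi * Ef / E0[i] - fout * qi / vi) / tau[i];
    }
  }
};

// [[Rcpp::export(name = ".dcm_integrate")]]
NumericMatrix dcm_integrate(NumericMatrix E, NumericMatrix C, NumericMatrix U,
                            NumericVector kappa, NumericVector gamma_,
                            NumericVector tau, NumericVector alpha,
                            NumericVector E0, NumericVector V0,
                            double dt, NumericVector sampleTimes,
                            bool neuralOnly = false) {
  const int n = E.nrow();
  const int m = C.ncol();
  const int nsteps = U.nrow();
  if (U.ncol() != m) stop("input matrix U must have one column per input");
  const int ns = 5 * n;

  DcmSystem sys;
  sys.n = n; sys.m = m;
  sys.E = E.begin(); sys.C = C.begin();
  sys.kappa = kappa.begin(); sys.gamma = gamma_.begin();
  sys.tau = tau.begin(); sys.alpha = alpha.begin(); sys.E0 = E0.begin();

  std::vector<double> y(ns), k1(ns), k2(ns), k3(ns), k4(ns), tmp(ns);
  for (int i = 0; i < n; ++i) {
    y[i] = 0.0;          // x
    y[n + i] = 0.0;      // s
    y[2 * n + i] = 1.0;  // f
    y[3 * n + i] = 1.0;  // v
    y[4 * n + i] = 1.0;  // q
  }

  const int nt = sampleTimes.size();
  NumericMatrix out(nt, n);
  // observation constants (classical BOLD observation equation)
  std::vector<double> o1(n), o2(n), o3(n);
  for (int i = 0; i < n; ++i) {
    o1[i] = 7.0 * E0[i];
    o2[i] = 2.0;
    o3[i] = 2.0 * E0[i] - 0.2;
  }

  // trajectory stored step-wise; sample by linear interpolation
  auto observe = [&](const std::vector<double> &st, int i) {
    if (neuralOnly) return st[i];
    double vv = st[3 * n + i], qq = st[4 * n + i];
    return 100.0 * V0[i] * (o1[i] * (1.0 - qq) + o2[i] * (1.0 - qq / vv) +
                            o3[i] * (1.0 - vv));
  };

  std::vector<double> yprev(ns), uc(m);
  int isamp = 0;
  // emit samples at or before t = 0
  while (isamp < nt && sampleTimes[isamp] <= 0.0) {
    for (int i = 0; i < n; ++i) out(isamp, i) = observe(y, i);
    ++isamp;
  }
  const double *Up = U.begin();
  for (int stp = 0; stp < nsteps && isamp < nt; ++stp) {
    for (int k = 0; k < m; ++k) uc[k] = Up[stp + nsteps * k];
    yprev = y;
    sys.deriv(y.data(), uc.data(), k1.data());
    for (int i = 0; i < ns; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
    sys.deriv(tmp.data(), uc.data(), k2.data());
    for (int i = 0; i < ns; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
    sys.deriv(tmp.data(), uc.data(), k3.data());
    for (int i = 0; i < ns; ++i) tmp[i] = y[i] + dt * k3[i];
    sys.deriv(tmp.data(), uc.data(), k4.data());
    for (int i = 0; i < ns; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    for (int i = 0; i < n; ++i) {
      double fi = y[2 * n + i], vi = y[3 * n + i], qi = y[4 * n + i];
      if (!(fi > 0.0) || !(vi > 0.0) || !(qi > 0.0) || !R_finite(y[i]))
        stop("haemodynamic state left its positive domain (unstable system?)");
    }
    double t0 = stp * dt, t1 = (stp + 1) * dt;
    while (isamp < nt && sampleTimes[isamp] <= t1 + 1e-12) {
      double w = (sampleTimes[isamp] - t0) / dt;
      if (w < 0.0) w = 0.0;
      if (w > 1.0) w = 1.0;
      for (int i = 0; i < n; ++i) {
        double a = observe(yprev, i), b = observe(y, i);
        out(isamp, i) = (1.0 - w) * a + w * b;
      }
      ++isamp;
    }
  }
  if (isamp < nt) stop("sample times extend beyond the integrated horizon");
  return out;
}
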