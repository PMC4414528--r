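#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Right-hand side of the cell/apoplast ring dynamics. Mirrors the R
// reference implementation rhs_ring() exactly: polarized linear efflux,
// linear active influx and passive chemiosmotic entry (both inward only),
// production/degradation inside cells, diffusion between adjacent apoplasts.
struct RingModel {
  int N;
  double I, E, D, D_ca, sigma_c, nu_c, theta_I, theta_P;
  double rho, w, a_ref, A_ref, pol_n, ts;

  RingModel(int n, List pars) : N(n) {
    I = pars["I"]; E = pars["E"]; D = pars["D"]; D_ca = pars["D_ca"];
    sigma_c = pars["sigma_c"]; nu_c = pars["nu_c"];
    theta_I = pars["theta_I"]; theta_P = pars["theta_P"];
    rho = pars["rho"]; w = pars["w"];
    a_ref = pars["a_ref"]; A_ref = pars["A_ref"];
    pol_n = pars["polarity_exponent"]; ts = pars["time_scale"];
  }

  inline int ip1(int i) const { return i + 1 == N ? 0 : i + 1; }
  inline int im1(int i) const { return i == 0 ? N - 1 : i - 1; }

  void rhs(const std::vector<double>& A, const std::vector<double>& a,
           std::vector<double>& dA, std::vector<double>& da) const {
    const double Ecoef = E / A_ref, Icoef = I / a_ref, wr_ = w * rho;
    const bool constP = (theta_P == 0.0), constI = (theta_I == 0.0);
    const bool lin_pol = (pol_n == 1.0);
    // per-cell fluxes into the two flanking apoplasts
    for (int j = 0; j < N; ++j) da[j] = 0.0;
    for (int i = 0; i < N; ++i) {
      double Ai = A[i];
      double p_tot = constP ? 1.0 : Ai / (theta_P + Ai);
      double i_tot = constI ? 0.5 : 0.5 * Ai / (theta_I + Ai);
      if (Ai == 0.0) {   // zero auxin induces no carriers (theta > 0)
        if (!constP) p_tot = 0.0;
        if (!constI) i_tot = 0.0;
      }
      double x = A[ip1(i)], y = A[im1(i)];
      double wrt = lin_pol ? x : std::pow(x, pol_n);
      double wlt = lin_pol ? y : std::pow(y, pol_n);
      double tot = wrt + wlt;
      double phiR = tot > 0.0 ? wrt / tot : 0.5;
      double efflux = Ecoef * p_tot * Ai;
      double upt = Icoef * i_tot + D_ca;
      double JR = efflux * phiR - upt * a[i];
      double JL = efflux * (1.0 - phiR) - upt * a[im1(i)];
      dA[i] = -w * (JL + JR) - nu_c * Ai + sigma_c;
      da[i] += wr_ * JR;
      da[im1(i)] += wr_ * JL;
    }
    for (int j = 0; j < N; ++j) {
      da[j] += D * (a[im1(j)] - 2.0 * a[j] + a[ip1(j)]);
      dA[j] *= ts;
      da[j] *= ts;
    }
  }
};

// [[Rcpp::export(name = ".rk4_ring")]]
List rk4_ring(NumericVector A0, NumericVector a0, List pars,
              double dt, int n_steps, IntegerVector snap_steps) {
  int N = A0.size();
  RingModel m(N, pars);
  std::vector<double> A(A0.begin(), A0.end()), a(a0.begin(), a0.end());
  std::vector<double> k1A(N), k1a(N), k2A(N), k2a(N), k3A(N), k3a(N),
      k4A(N), k4a(N), tA(N), ta(N);

  int n_snap = snap_steps.size();
  NumericMatrix snapA(n_snap, N), snapa(n_snap, N);
  int next_snap = 0;
  auto record = [&](int step) {
    while (next_snap < n_snap && snap_steps[next_snap] == step) {
      for (int i = 0; i < N; ++i) {
        snapA(next_snap, i) = A[i];
        snapa(next_snap, i) = a[i];
      }
      ++next_snap;
    }
  };
  record(0);

  for (int s = 0; s < n_steps; ++s) {
    m.rhs(A, a, k1A, k1a);
    for (int i = 0; i < N; ++i) {
      tA[i] = A[i] + 0.5 * dt * k1A[i];
      ta[i] = a[i] + 0.5 * dt * k1a[i];
    }
    m.rhs(tA, ta, k2A, k2a);
    for (int i = 0; i < N; ++i) {
      tA[i] = A[i] + 0.5 * dt * k2A[i];
      ta[i] = a[i] + 0.5 * dt * k2a[i];
    }
    m.rhs(tA, ta, k3A, k3a);
    for (int i = 0; i < N; ++i) {
      tA[i] = A[i] + dt * k3A[i];
      ta[i] = a[i] + dt * k3a[i];
    }
    m.rhs(tA, ta, k4A, k4a);
    for (int i = 0; i < N; ++i) {
      A[i] += dt / 6.0 * (k1A[i] + 2.0 * k2A[i] + 2.0 * k3A[i] + k4A[i]);
      a[i] += dt / 6.0 * (k1a[i] + 2.0 * k2a[i] + 2.0 * k3a[i] + k4a[i]);
    }
    if ((s & 511) == 0 || s + 1 == n_steps) {
      double mx = 0.0;
      bool bad = false;
      for (int i = 0; i < N; ++i) {
        if (!std::isfinite(A[i]) || !std::isfinite(a[i])) bad = true;
        mx = std::max(mx, std::max(std::fabs(A[i]), std::fabs(a[i])));
      }
      if (bad)
        stop("integration diverged at t = %g (max |state| = %g)",
             (s + 1) * dt, mx);
    }
    record(s + 1);
  }

  return List::create(_["A"] = NumericVector(A.begin(), A.end()),
                      _["a"] = NumericVector(a.begin(), a.end()),
                      _["snapA"] = snapA, _["snapa"] = snapa);
}
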