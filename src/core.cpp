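// Fast engine for the daily time loop: hydraulic property evaluation,
// tridiagonal assembly, Thomas solve, flux-update acceptance, sink terms
// and per-day water-balance accumulation.  The R functions in R/solver.R
// and R/uptake.R implement the same formulas one operation at a time; the
// two paths are pinned against each other in the test suite.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Layer {
  int form;                 // 1 = van Genuchten-Mualem, 2 = tabulated
  double tr, ts, Ks, alpha, n, m;
  std::vector<double> th_h, th_t;   // tabulated h-theta, ascending h
  std::vector<double> tk_t, tk_k;   // tabulated theta-K, ascending theta
};

double lin_interp(const std::vector<double>& x, const std::vector<double>& y,
                  double v) {
  // piecewise linear with flat extrapolation beyond the end nodes
  if (v <= x.front()) return y.front();
  if (v >= x.back())  return y.back();
  std::vector<double>::const_iterator it =
      std::upper_bound(x.begin(), x.end(), v);
  size_t i = static_cast<size_t>(it - x.begin());
  double w = (v - x[i - 1]) / (x[i] - x[i - 1]);
  return y[i - 1] + w * (y[i] - y[i - 1]);
}

double theta_of_h(const Layer& L, double h) {
  if (h >= 0.0) return L.ts;
  if (L.form == 1) {
    double ahn = std::pow(L.alpha * (-h), L.n);
    return L.tr + (L.ts - L.tr) * std::pow(1.0 + ahn, -L.m);
  }
  return lin_interp(L.th_h, L.th_t, h);
}

double h_of_theta(const Layer& L, double th) {
  if (L.form == 1) {
    if (th >= L.ts) return 0.0;
    double Se = (th - L.tr) / (L.ts - L.tr);
    if (Se <= 0.0) return R_NegInf;
    return -(1.0 / L.alpha) *
           std::pow(std::pow(Se, -1.0 / L.m) - 1.0, 1.0 / L.n);
  }
  if (th >= L.th_t.back()) return L.th_h.back();
  return lin_interp(L.th_t, L.th_h, th);
}

double K_of_theta(const Layer& L, double th) {
  if (L.form == 1) {
    double Se = (th - L.tr) / (L.ts - L.tr);
    if (Se >= 1.0) return L.Ks;
    if (Se <= 0.0) return 0.0;
    double t = 1.0 - std::pow(1.0 - std::pow(Se, 1.0 / L.m), L.m);
    return L.Ks * std::sqrt(Se) * t * t;
  }
  return lin_interp(L.tk_t, L.tk_k, th);
}

double cap_of_h(const Layer& L, double h) {
  if (h >= 0.0) return 0.0;
  if (L.form == 1) {
    double a = L.alpha, n = L.n, m = L.m;
    double ahn = std::pow(a * (-h), n);
    return (L.ts - L.tr) * a * n * m * std::pow(a * (-h), n - 1.0) *
           std::pow(1.0 + ahn, -m - 1.0);
  }
  // slope of the active segment; zero beyond the end nodes
  const std::vector<double>& x = L.th_h;
  const std::vector<double>& y = L.th_t;
  if (h <= x.front() || h >= x.back()) return 0.0;
  std::vector<double>::const_iterator it =
      std::upper_bound(x.begin(), x.end(), h);
  size_t i = static_cast<size_t>(it - x.begin());
  return (y[i] - y[i - 1]) / (x[i] - x[i - 1]);
}

double internode_K(double Ku, double Kl, int kmean) {
  if (kmean == 2) return std::sqrt(Ku * Kl);
  return 0.5 * (Ku + Kl);
}

// Feddes trapezoid: zero above the anaerobiosis point h1 and below the
// wilting point h4, optimal on [h3, h2].
double feddes_alpha(double h, double h1, double h2, double h3, double h4) {
  if (h >= h1 || h <= h4) return 0.0;
  if (h > h2) return (h1 - h) / (h1 - h2);
  if (h >= h3) return 1.0;
  return (h - h4) / (h3 - h4);
}

double h3_linear(double Tp, double h31, double h32, double Tp1, double Tp2) {
  if (Tp <= Tp1) return h31;
  if (Tp >= Tp2) return h32;
  double a = (h31 - h32) / (Tp1 - Tp2);
  return a * Tp + h31 - a * Tp1;
}

double lnrd_cubic(double zr, const double* R) {
  double v = R[0] + R[1] * zr + R[2] * zr * zr + R[3] * zr * zr * zr;
  return v > 0.0 ? v : 0.0;   // density floored at zero
}

// mm/day to m/s conversion for the sink term: 86400 s/day * 1000 mm/m
const double UNIT_FACTOR = 86400000.0;

void compute_sink(const std::vector<double>& h, int nz, double dz,
                  double Tp, double Lroot, int icps, double beta,
                  double lambda, const double* R,
                  double h1, double h2, double h3, double h4,
                  std::vector<double>& S) {
  std::fill(S.begin(), S.end(), 0.0);
  if (Tp <= 0.0 || Lroot <= 0.0) return;
  if (icps == 1) {
    for (int i = 0; i < nz; ++i) {
      double z = (i + 0.5) * dz;
      if (z > Lroot) break;
      double a = feddes_alpha(h[i], h1, h2, h3, h4);
      S[i] = a * Tp * (beta + 1.0) * std::pow(1.0 - z / Lroot, beta) /
             (UNIT_FACTOR * Lroot);
    }
  } else if (icps == 3) {
    // Wu density, proportional allocation, no compensation
    double denom = 0.0;
    std::vector<double> w(nz, 0.0);
    for (int i = 0; i < nz; ++i) {
      double z = (i + 0.5) * dz;
      if (z > Lroot) break;
      w[i] = lnrd_cubic(z / Lroot, R) * dz;
      denom += w[i];
    }
    if (denom <= 0.0) return;
    for (int i = 0; i < nz; ++i) {
      if (w[i] <= 0.0) continue;
      double a = feddes_alpha(h[i], h1, h2, h3, h4);
      S[i] = a * Tp * w[i] / (UNIT_FACTOR * dz * denom);
    }
  } else {   // icps == 2: Li-Yadav compensation with Wu density
    double denom = 0.0;
    std::vector<double> Lv(nz, 0.0), av(nz, 0.0);
    for (int i = 0; i < nz; ++i) {
      double z = (i + 0.5) * dz;
      if (z > Lroot) break;
      Lv[i] = lnrd_cubic(z / Lroot, R);
      av[i] = feddes_alpha(h[i], h1, h2, h3, h4);
      if (Lv[i] > 0.0) denom += av[i] * std::pow(Lv[i], lambda);
    }
    if (denom <= 0.0) return;   // full stress: zero uptake, no exception
    for (int i = 0; i < nz; ++i) {
      if (Lv[i] <= 0.0) continue;
      S[i] = av[i] * av[i] * std::pow(Lv[i], lambda) * Tp /
             (UNIT_FACTOR * dz * denom);
    }
  }
}

bool thomas(int n, const std::vector<double>& A, const std::vector<double>& B,
            const std::vector<double>& C, const std::vector<double>& D,
            std::vector<double>& x, std::vector<double>& cp,
            std::vector<double>& dp) {
  if (std::fabs(B[0]) < 1e-300) return false;
  cp[0] = C[0] / B[0];
  dp[0] = D[0] / B[0];
  for (int i = 1; i < n; ++i) {
    double piv = B[i] - A[i] * cp[i - 1];
    if (std::fabs(piv) < 1e-300) return false;
    cp[i] = C[i] / piv;
    dp[i] = (D[i] - A[i] * dp[i - 1]) / piv;
  }
  x[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = dp[i] - cp[i] * x[i + 1];
  return true;
}

struct Uptake {
  int icps;
  double beta, zrmax, lambda, L0;
  int jthaw, jmatur;
  double R[4];
  double h1, h2, h4, h31, h32, Tp1, Tp2;
};

double root_depth(double day, const Uptake& u) {
  if (day <= u.jthaw) return u.L0;
  if (day >= u.jmatur) return u.zrmax;
  double f = (day - u.jthaw) / (double)(u.jmatur - u.jthaw);
  return u.L0 + f * (u.zrmax - u.L0);
}

}  // namespace

// [[Rcpp::export]]
List run_core(int nz, double dz, IntegerVector lay, List layers,
              NumericVector h_init,
              NumericVector day, NumericVector rain_mm,
              NumericVector Ep_mm, NumericVector Tp_mm,
              List uptake, double dt_base, double h_dry,
              int kmean, double sat_tol) {
  int ndays = day.size();
  std::vector<Layer> ly(layers.size());
  for (int j = 0; j < layers.size(); ++j) {
    List lj = layers[j];
    Layer& L = ly[j];
    L.form = as<int>(lj["form"]);
    L.tr = as<double>(lj["theta_r"]);
    L.ts = as<double>(lj["theta_s"]);
    L.Ks = as<double>(lj["K_s"]);
    if (L.form == 1) {
      L.alpha = as<double>(lj["alpha"]);
      L.n = as<double>(lj["n"]);
      L.m = 1.0 - 1.0 / L.n;
    } else {
      L.th_h = as<std::vector<double> >(lj["tab_h"]);
      L.th_t = as<std::vector<double> >(lj["tab_theta"]);
      L.tk_t = as<std::vector<double> >(lj["tab_kt"]);
      L.tk_k = as<std::vector<double> >(lj["tab_k"]);
    }
  }

  Uptake u;
  u.icps = as<int>(uptake["icps"]);
  u.beta = as<double>(uptake["beta"]);
  u.zrmax = as<double>(uptake["zr_max"]);
  u.lambda = as<double>(uptake["lambda"]);
  u.jthaw = as<int>(uptake["jthaw"]);
  u.jmatur = as<int>(uptake["jmatur"]);
  u.L0 = as<double>(uptake["l0"]);
  NumericVector Rv = uptake["r_coeffs"];
  for (int k = 0; k < 4; ++k) u.R[k] = Rv[k];
  u.h1 = as<double>(uptake["h1"]);
  u.h2 = as<double>(uptake["h2"]);
  u.h4 = as<double>(uptake["h4"]);
  u.h31 = as<double>(uptake["h31"]);
  u.h32 = as<double>(uptake["h32"]);
  u.Tp1 = as<double>(uptake["tp1"]);
  u.Tp2 = as<double>(uptake["tp2"]);

  std::vector<double> h(nz), th(nz);
  for (int i = 0; i < nz; ++i) {
    h[i] = h_init[i];
    th[i] = theta_of_h(ly[lay[i] - 1], h[i]);
  }

  NumericMatrix out_h(ndays, nz), out_th(ndays, nz);
  NumericVector d_inf(ndays), d_drain(ndays), d_eva(ndays), d_tra(ndays);

  std::vector<double> cvec(nz), Kold(nz), kh(nz + 1), A(nz), B(nz), C(nz),
      D(nz), hstar(nz), cp(nz), dp(nz), S(nz), Knew(nz), khn(nz + 1),
      J(nz + 1), trial(nz), hn(nz), thn(nz);
  std::vector<bool> sat(nz);
  double dz2 = dz * dz;

  for (int d = 0; d < ndays; ++d) {
    double Lroot = root_depth(day[d], u);
    double h3 = h3_linear(Tp_mm[d], u.h31, u.h32, u.Tp1, u.Tp2);
    double remaining = 86400.0;
    double dt = dt_base;
    double acc_inf = 0.0, acc_drain = 0.0, acc_eva = 0.0, acc_tra = 0.0;

    while (remaining > 1e-9) {
      double dt_use = std::min(dt, remaining);

      // stage-2 evaporation limit: Darcy exfiltration capacity toward a
      // prescribed air-dry surface head, half-block spacing
      double Ksurf = K_of_theta(ly[lay[0] - 1], th[0]);
      double Jdry = -Ksurf * (h[0] - h_dry) / (0.5 * dz) + Ksurf;
      double cap_mm = std::max(0.0, -Jdry) * UNIT_FACTOR;
      double actE = std::min(Ep_mm[d], cap_mm);
      double J0 = (rain_mm[d] - actE) / UNIT_FACTOR;

      compute_sink(h, nz, dz, Tp_mm[d], Lroot, u.icps, u.beta, u.lambda,
                   u.R, u.h1, u.h2, h3, u.h4, S);

      // assemble with old-time K and c; surface flux withheld from the pass
      for (int i = 0; i < nz; ++i) {
        const Layer& L = ly[lay[i] - 1];
        cvec[i] = cap_of_h(L, h[i]);
        Kold[i] = K_of_theta(L, th[i]);
      }
      for (int i = 1; i < nz; ++i)
        kh[i] = internode_K(Kold[i - 1], Kold[i], kmean);
      kh[0] = 0.0;
      kh[nz] = Kold[nz - 1];

      A[0] = 0.0;
      C[0] = -kh[1] / dz2;
      B[0] = cvec[0] / dt_use + kh[1] / dz2;
      D[0] = cvec[0] * h[0] / dt_use - (0.0 - kh[1]) / dz - S[0];
      for (int i = 1; i < nz - 1; ++i) {
        A[i] = -kh[i] / dz2;
        C[i] = -kh[i + 1] / dz2;
        B[i] = cvec[i] / dt_use + (kh[i] + kh[i + 1]) / dz2;
        D[i] = cvec[i] * h[i] / dt_use - (kh[i + 1] - kh[i]) / dz - S[i];
      }
      A[nz - 1] = -kh[nz - 1] / dz2;
      C[nz - 1] = 0.0;
      B[nz - 1] = cvec[nz - 1] / dt_use + kh[nz - 1] / dz2;
      D[nz - 1] = cvec[nz - 1] * h[nz - 1] / dt_use -
                  (Kold[nz - 1] - kh[nz - 1]) / dz - S[nz - 1];

      bool ok = thomas(nz, A, B, C, D, hstar, cp, dp);

      if (ok) {
        // conductivities from HSTAR, fluxes including the surface flux
        for (int i = 0; i < nz; ++i) {
          const Layer& L = ly[lay[i] - 1];
          Knew[i] = K_of_theta(L, theta_of_h(L, hstar[i]));
          if (!std::isfinite(hstar[i])) ok = false;
        }
        if (ok) {
          for (int i = 1; i < nz; ++i)
            khn[i] = internode_K(Knew[i - 1], Knew[i], kmean);
          J[0] = J0;
          for (int i = 1; i < nz; ++i)
            J[i] = -khn[i] * (hstar[i] - hstar[i - 1]) / dz + khn[i];
          J[nz] = Knew[nz - 1];

          for (int i = 0; i < nz; ++i)
            trial[i] = th[i] - dt_use * (J[i + 1] - J[i]) / dz -
                       dt_use * S[i];

          for (int i = 0; i < nz; ++i) {
            const Layer& L = ly[lay[i] - 1];
            sat[i] = trial[i] >= L.ts - sat_tol;
          }
          for (int i = 0; i < nz && ok; ++i) {
            const Layer& L = ly[lay[i] - 1];
            bool up = (i > 0) ? sat[i - 1] : false;       // flux upper BC
            bool dn = (i < nz - 1) ? sat[i + 1] : sat[i]; // bottom: itself
            if (!sat[i] && !up && !dn) {
              if (trial[i] <= L.tr + 1e-12) { ok = false; break; }
              thn[i] = trial[i];
              hn[i] = h_of_theta(L, trial[i]);
            } else {
              hn[i] = hstar[i];
              thn[i] = theta_of_h(L, hstar[i]);
            }
            if (!std::isfinite(hn[i]) || !std::isfinite(thn[i]))
              ok = false;
          }
        }
      }

      if (!ok) {
        dt *= 0.5;
        if (dt < dt_base / 4096.0)
          stop("time step collapsed below dt/4096 on day index %d", d + 1);
        continue;
      }

      double tra = 0.0;
      for (int i = 0; i < nz; ++i) tra += S[i] * dz;
      acc_inf += J0 * dt_use * 1000.0;
      acc_drain += J[nz] * dt_use * 1000.0;
      acc_tra += tra * dt_use * 1000.0;
      acc_eva += actE * dt_use / 86400.0;
      for (int i = 0; i < nz; ++i) { h[i] = hn[i]; th[i] = thn[i]; }
      remaining -= dt_use;
      if (dt < dt_base) dt = std::min(dt * 2.0, dt_base);
    }

    for (int i = 0; i < nz; ++i) {
      out_h(d, i) = h[i];
      out_th(d, i) = th[i];
    }
    d_inf[d] = acc_inf;
    d_drain[d] = acc_drain;
    d_eva[d] = acc_eva;
    d_tra[d] = acc_tra;
  }

  return List::create(
      _["h"] = out_h, _["theta"] = out_th,
      _["inf_mm"] = d_inf, _["drain_mm"] = d_drain,
      _["evap_mm"] = d_eva, _["tran_mm"] = d_tra,
      _["h_final"] = NumericVector(h.begin(), h.end()),
      _["theta_final"] = NumericVector(th.begin(), th.end()));
}
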