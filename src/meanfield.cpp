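// Mean-field reduction of the five-population conductance-based LIF network.
//
// Internal units: volts are mV, times are seconds, conductances are nS,
// rates are Hz.  Capacitance in nF so that Cm[nF]/gm[nS] = seconds.
//
// Populations are ordered L, R, S, nonspecific (excitatory) and then the
// single inhibitory population, indices 0..4.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct MFParams {
  double gm_e, gm_i, Cm_e, Cm_i;
  double VL, Vthr, Vreset, VE, VI;
  double trp_e, trp_i;
  double gae_e, gae_i, gar_e, gar_i, gn_e, gn_i, gg_e, gg_i;
  double tau_ampa, tau_gaba, tau_nr, tau_nd;
  double alpha;  // NMDA saturation rate, 1/s
  double mg;
  double NE, NI, Next, nu_bg;
  double f, wp, wm;
  // derived
  double tau_nmda, beta, gamma;
  double r[4];
  double W[4][4];  // W[j][x]: weight from excitatory pool j onto pool x
};

MFParams parse_params(const List& p) {
  MFParams q;
  q.gm_e = p["gm_exc"]; q.gm_i = p["gm_inh"];
  q.Cm_e = p["Cm_exc"]; q.Cm_i = p["Cm_inh"];
  q.VL = p["V_L"]; q.Vthr = p["V_thr"]; q.Vreset = p["V_reset"];
  q.VE = p["V_E"]; q.VI = p["V_I"];
  q.trp_e = p["tau_rp_exc"]; q.trp_i = p["tau_rp_inh"];
  q.gae_e = p["g_ampa_ext_exc"]; q.gae_i = p["g_ampa_ext_inh"];
  q.gar_e = p["g_ampa_rec_exc"]; q.gar_i = p["g_ampa_rec_inh"];
  q.gn_e = p["g_nmda_exc"]; q.gn_i = p["g_nmda_inh"];
  q.gg_e = p["g_gaba_exc"]; q.gg_i = p["g_gaba_inh"];
  q.tau_ampa = p["tau_ampa"]; q.tau_gaba = p["tau_gaba"];
  q.tau_nr = p["tau_nmda_rise"]; q.tau_nd = p["tau_nmda_decay"];
  q.alpha = p["alpha"]; q.mg = p["mg"];
  q.NE = p["N_E"]; q.NI = p["N_I"];
  q.Next = p["N_ext"]; q.nu_bg = p["nu_ext_source"];
  q.f = p["f"]; q.wp = p["w_plus"]; q.wm = p["w_minus"];
  q.tau_nmda = q.alpha * q.tau_nr * q.tau_nd;
  q.beta = 0.062;
  q.gamma = q.mg / 3.57;
  q.r[0] = q.r[1] = q.r[2] = q.f;
  q.r[3] = 1.0 - 3.0 * q.f;
  for (int j = 0; j < 4; ++j)
    for (int x = 0; x < 4; ++x) q.W[j][x] = 1.0;
  for (int x = 0; x < 3; ++x) {          // selective targets
    for (int j = 0; j < 4; ++j) q.W[j][x] = q.wm;
    q.W[x][x] = q.wp;
  }
  return q;
}

// scaled complementary error function erfcx(z) = exp(z^2) erfc(z), z >= 0
double erfcx_pos(double z) {
  if (z < 26.0) return std::exp(z * z) * std::erfc(z);
  // asymptotic expansion for large argument
  const double isp = 1.0 / std::sqrt(M_PI);
  double z2 = z * z;
  return isp / z * (1.0 - 0.5 / z2 + 0.75 / (z2 * z2));
}

// integrand of the first-passage integral: exp(u^2) (1 + erf(u)) = exp(u^2) erfc(-u)
double fpt_integrand(double u) {
  if (u <= 0.0) return erfcx_pos(-u);
  return 2.0 * std::exp(u * u) - erfcx_pos(u);
}

// 96-point Gauss-Legendre nodes/weights on [0, 1], generated once.
struct GL {
  std::vector<double> x, w;
  GL(int n) : x(n), w(n) {
    // Newton iteration on Legendre polynomials, standard construction
    for (int i = 0; i < n; ++i) {
      double z = std::cos(M_PI * (i + 0.75) / (n + 0.5)), z1, pp;
      do {
        double p0 = 1.0, p1 = 0.0;
        for (int j = 0; j < n; ++j) {
          double p2 = p1; p1 = p0;
          p0 = ((2.0 * j + 1.0) * z * p1 - j * p2) / (j + 1.0);
        }
        pp = n * (z * p0 - p1) / (z * z - 1.0);
        z1 = z; z = z1 - p0 / pp;
      } while (std::fabs(z - z1) > 1e-15);
      x[i] = 0.5 * (1.0 - z);          // map [-1,1] -> [0,1]
      w[i] = 1.0 / ((1.0 - z * z) * pp * pp);
    }
  }
};
static GL gl96(96);

// population transfer function (first-passage time of the effective process)
double phi_rate(double Vthr, double Vreset, double mu, double sigma,
                double tau_x, double trp, double tau_ampa) {
  double k = tau_ampa / tau_x;
  double au = (Vthr - mu) / sigma * (1.0 + 0.5 * k) +
              1.03 * std::sqrt(k) - 0.5 * k;
  double bl = (Vreset - mu) / sigma;
  if (au > 15.0) return 0.0;  // integrand >= exp(225): rate is numerically zero
  double I = 0.0;
  for (size_t i = 0; i < gl96.x.size(); ++i) {
    double u = bl + (au - bl) * gl96.x[i];
    I += gl96.w[i] * fpt_integrand(u);
  }
  I *= (au - bl);
  return 1.0 / (trp + tau_x * std::sqrt(M_PI) * I);
}

// effective NMDA activation psi(nu), series truncated with early stop
double psi_scalar(double nu, const MFParams& q, int nmax) {
  double qn = nu * q.tau_nmda;
  double base = qn / (1.0 + qn);
  if (nu <= 0.0) return 0.0;
  double s = 0.0, sign = -1.0, fac = 2.0;  // (n+1)! starting at n=1
  double at = q.alpha * q.tau_nr;
  double powat = at;
  for (int n = 1; n <= nmax; ++n) {
    // T_n(nu) = sum_k (-1)^k C(n,k) a/(a + k tau_nd), a = tau_nr (1 + nu tau_nmda)
    double aa = q.tau_nr * (1.0 + qn);
    double Tn = 0.0, binom = 1.0;
    for (int kk = 0; kk <= n; ++kk) {
      Tn += ((kk % 2) ? -1.0 : 1.0) * binom * aa / (aa + kk * q.tau_nd);
      binom = binom * (n - kk) / (kk + 1.0);
    }
    double term = sign * powat * Tn / fac;
    s += term;
    if (std::fabs(term) < 1e-12) break;
    sign = -sign;
    powat *= at;
    fac *= (n + 2.0);
  }
  return base * (1.0 + s / (1.0 + qn));
}

struct Fields {
  double mu[5], sigma[5], tau[5], Sx[5], V[5];
  double nA[5], nN[5], nG[5];
};

// Self-consistent mu, sigma, tau, <V> at given rates nu and external rates.
Fields compute_fields(const double* nu, const double* nu_ext,
                      const MFParams& q) {
  Fields f;
  double psi_e[4];
  for (int j = 0; j < 4; ++j) psi_e[j] = psi_scalar(nu[j], q, 64);
  for (int x = 0; x < 4; ++x) {
    f.nA[x] = 0.0; f.nN[x] = 0.0;
    for (int j = 0; j < 4; ++j) {
      f.nA[x] += q.r[j] * q.W[j][x] * nu[j];
      f.nN[x] += q.r[j] * q.W[j][x] * psi_e[j];
    }
    f.nG[x] = nu[4];
  }
  f.nA[4] = 0.0; f.nN[4] = 0.0;
  for (int j = 0; j < 4; ++j) {
    f.nA[4] += q.r[j] * nu[j];
    f.nN[4] += q.r[j] * psi_e[j];
  }
  f.nG[4] = nu[4];

  for (int x = 0; x < 5; ++x) {
    bool exc = x < 4;
    double gm = exc ? q.gm_e : q.gm_i;
    double Cm = exc ? q.Cm_e : q.Cm_i;
    double gae = exc ? q.gae_e : q.gae_i;
    double gar = exc ? q.gar_e : q.gar_i;
    double gn  = exc ? q.gn_e  : q.gn_i;
    double gg  = exc ? q.gg_e  : q.gg_i;
    double tau_m = Cm / gm;
    double Text = gae * q.tau_ampa / gm;
    double TA = gar * q.NE * q.tau_ampa / gm;
    double TI = gg * q.NI * q.tau_gaba / gm;
    double Vx = -55.0, mu = q.VL, tau_x = tau_m, sig2 = 1.0;
    for (int it = 0; it < 200; ++it) {
      double J = 1.0 + q.gamma * std::exp(-q.beta * Vx);
      double rho1 = gn * q.NE / (gm * J);
      double rho2 = q.beta * gn * q.NE * (Vx - q.VE) * (J - 1.0) /
                    (gm * J * J);
      double Sx = 1.0 + Text * nu_ext[x] + TA * f.nA[x] +
                  (rho1 + rho2) * f.nN[x] + TI * f.nG[x];
      double mu_new = ((Text * nu_ext[x] + TA * f.nA[x] + rho1 * f.nN[x]) * q.VE +
                       rho2 * f.nN[x] * Vx + TI * f.nG[x] * q.VI + q.VL) / Sx;
      tau_x = Cm / (gm * Sx);
      sig2 = gae * gae * (Vx - q.VE) * (Vx - q.VE) * nu_ext[x] *
             q.tau_ampa * q.tau_ampa * tau_x / (gm * gm * tau_m * tau_m);
      double Vx_new = mu_new - (q.Vthr - q.Vreset) * nu[x] * tau_x;
      double d = std::fabs(Vx_new - Vx) + std::fabs(mu_new - mu);
      Vx = Vx_new; mu = mu_new;
      f.Sx[x] = Sx;
      if (d < 1e-11) break;
    }
    f.mu[x] = mu;
    f.sigma[x] = std::sqrt(sig2 > 1e-30 ? sig2 : 1e-30);
    f.tau[x] = tau_x;
    f.V[x] = Vx;
  }
  return f;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_psi")]]
NumericVector cpp_psi(NumericVector nu, List params, int nmax = 64) {
  MFParams q = parse_params(params);
  NumericVector out(nu.size());
  for (R_xlen_t i = 0; i < nu.size(); ++i)
    out[i] = psi_scalar(nu[i], q, nmax);
  return out;
}

// [[Rcpp::export(name = ".cpp_phi")]]
NumericVector cpp_phi(NumericVector mu, NumericVector sigma,
                      NumericVector tau_x, NumericVector tau_rp,
                      double tau_ampa, double V_thr, double V_reset) {
  R_xlen_t n = mu.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = phi_rate(V_thr, V_reset, mu[i], sigma[i], tau_x[i], tau_rp[i],
                      tau_ampa);
  return out;
}

// [[Rcpp::export(name = ".cpp_mf_fields")]]
List cpp_mf_fields(NumericVector nu, NumericVector nu_ext, List params) {
  MFParams q = parse_params(params);
  Fields f = compute_fields(REAL(nu), REAL(nu_ext), q);
  return List::create(
      _["mu"] = NumericVector(f.mu, f.mu + 5),
      _["sigma"] = NumericVector(f.sigma, f.sigma + 5),
      _["tau"] = NumericVector(f.tau, f.tau + 5),
      _["S_x"] = NumericVector(f.Sx, f.Sx + 5),
      _["V_mean"] = NumericVector(f.V, f.V + 5),
      _["n_ampa"] = NumericVector(f.nA, f.nA + 5),
      _["n_nmda"] = NumericVector(f.nN, f.nN + 5),
      _["n_gaba"] = NumericVector(f.nG, f.nG + 5));
}

// Euler integration of tau_x dnu/dt = -nu + phi(mu, sigma) to a fixed point.
// [[Rcpp::export(name = ".cpp_mf_solve")]]
List cpp_mf_solve(NumericVector nu0, NumericVector nu_ext, List params,
                  double dt = 1e-4, double tol = 1e-6,
                  double max_steps = 1e6) {
  MFParams q = parse_params(params);
  double nu[5], ext[5];
  for (int i = 0; i < 5; ++i) { nu[i] = nu0[i]; ext[i] = nu_ext[i]; }
  bool conv = false;
  double steps = 0;
  Fields f;
  for (steps = 0; steps < max_steps; ++steps) {
    f = compute_fields(nu, ext, q);
    double dmax = 0.0;
    for (int x = 0; x < 5; ++x) {
      double trp = (x < 4) ? q.trp_e : q.trp_i;
      double ph = phi_rate(q.Vthr, q.Vreset, f.mu[x], f.sigma[x], f.tau[x],
                           trp, q.tau_ampa);
      double dnu = dt / f.tau[x] * (ph - nu[x]);
      nu[x] += dnu;
      if (nu[x] < 0.0) nu[x] = 0.0;
      if (std::fabs(dnu) > dmax) dmax = std::fabs(dnu);
      if (!std::isfinite(nu[x])) stop("mean-field integration diverged");
    }
    if (dmax < tol) { conv = true; ++steps; break; }
  }
  // residual of the self-consistency at the final point
  f = compute_fields(nu, ext, q);
  double resid = 0.0;
  NumericVector phiv(5);
  for (int x = 0; x < 5; ++x) {
    double trp = (x < 4) ? q.trp_e : q.trp_i;
    phiv[x] = phi_rate(q.Vthr, q.Vreset, f.mu[x], f.sigma[x], f.tau[x], trp,
                       q.tau_ampa);
    double r = std::fabs(nu[x] - phiv[x]);
    if (r > resid) resid = r;
  }
  return List::create(
      _["nu"] = NumericVector(nu, nu + 5),
      _["converged"] = conv,
      _["steps"] = steps,
      _["residual"] = resid,
      _["phi"] = phiv,
      _["mu"] = NumericVector(f.mu, f.mu + 5),
      _["sigma"] = NumericVector(f.sigma, f.sigma + 5),
      _["tau"] = NumericVector(f.tau, f.tau + 5),
      _["S_x"] = NumericVector(f.Sx, f.Sx + 5),
      _["V_mean"] = NumericVector(f.V, f.V + 5));
}
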