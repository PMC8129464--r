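// Adaptive Metropolis-within-Gibbs sampler for the hierarchical bridging
// model.  Continuous coordinates are updated by component-wise random-walk
// Metropolis with Roberts-Rosenthal step-size adaptation during burn-in
// (frozen afterwards); the per-subgroup mixture-component indicators are
// updated by exact Gibbs draws from their categorical full conditional.
// Truncated supports (positive sds, correlations in (-1,1), eps in its
// truncation interval, positive delta) are handled by rejecting proposals
// outside the support.  All conditional evaluations only touch the terms of
// the joint density involving the coordinate, which is what makes the
// many interim refits of a simulated trial affordable.  Normalising
// constants that cancel in every acceptance ratio and in the indicator
// full conditional are dropped.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

inline double softplus(double v) { return v > 35.0 ? v : log1p(exp(v)); }

inline double binom_ll(double r, double n, double lin) {
  return r * lin - n * softplus(lin);
}

// bivariate normal log density (sds + correlation), without -log(2*pi)
inline double bvn(double x1, double x2, double m1, double m2,
                  double s1, double s2, double r) {
  if (s1 <= 0.0 || s2 <= 0.0 || std::fabs(r) >= 1.0) return R_NegInf;
  double a = (x1 - m1) / s1, b = (x2 - m2) / s2, q = 1.0 - r * r;
  return -log(s1 * s2) - 0.5 * log(q) -
         0.5 * (a * a - 2.0 * r * a * b + b * b) / q;
}

struct Sampler {
  // dimensions
  int M, K, L;
  // animal data (concatenated dose groups, offsets length M+1)
  std::vector<int> asp;
  std::vector<double> adose, an, ar;
  std::vector<int> aoff;
  // human data
  std::vector<double> hdose, hn, hr;
  std::vector<int> hoff;
  // priors
  double b1, s1, b2, s2, dref, eps_lo, eps_hi;
  std::vector<double> zs, cs, dml, dsl, nu;
  std::vector<double> m01, m02, r0s1, r0s2, r0c;
  std::vector<double> W; // L x (K+2), row-major
  // layout
  int off_theta, off_muS, off_m, off_muH, off_gamma, off_eps, off_delta,
      off_v, npar;
  // state
  std::vector<double> x;
  std::vector<int> z; // 0-based component per subgroup

  void layout() {
    off_theta = 0;
    off_muS = 2 * M;
    off_m = off_muS + 2 * K;
    off_muH = off_m + 2;
    off_gamma = off_muH + 2;
    off_eps = off_gamma + 2 * L;
    off_delta = off_eps + L;
    off_v = off_delta + K;
    npar = off_v + 9; // tau1..4, sigma1, sigma2, rho, kappa, eta
  }

  inline double wgt(int l, int c) const { return W[l * (K + 2) + c]; }

  double ll_study(int i) const {
    double t1 = x[off_theta + 2 * i], t2 = exp(x[off_theta + 2 * i + 1]);
    double ld = log(x[off_delta + asp[i]] / dref);
    double s = 0.0;
    for (int j = aoff[i]; j < aoff[i + 1]; ++j)
      s += binom_ll(ar[j], an[j], t1 + t2 * (log(adose[j]) + ld));
    return s;
  }

  double ll_human(int l) const {
    if (hoff[l] == hoff[l + 1]) return 0.0;
    double g1 = x[off_gamma + 2 * l], g2 = exp(x[off_gamma + 2 * l + 1]);
    double le = log(x[off_eps + l] / dref);
    double s = 0.0;
    for (int j = hoff[l]; j < hoff[l + 1]; ++j)
      s += binom_ll(hr[j], hn[j], g1 + g2 * (log(hdose[j]) + le));
    return s;
  }

  double lp_theta(int i) const {
    int k = asp[i];
    return bvn(x[off_theta + 2 * i], x[off_theta + 2 * i + 1],
               x[off_muS + 2 * k], x[off_muS + 2 * k + 1],
               x[off_v], x[off_v + 1], x[off_v + 6]);
  }

  double lp_muS(int k) const {
    return bvn(x[off_muS + 2 * k], x[off_muS + 2 * k + 1],
               x[off_m], x[off_m + 1],
               x[off_v + 4], x[off_v + 5], x[off_v + 7]);
  }

  // component density of gamma_l under component c (0..K+1)
  double lp_gamma_comp(int l, int c) const {
    double g1 = x[off_gamma + 2 * l], g2 = x[off_gamma + 2 * l + 1];
    if (c < K)
      return bvn(g1, g2, x[off_muS + 2 * c], x[off_muS + 2 * c + 1],
                 x[off_v], x[off_v + 1], x[off_v + 6]);
    if (c == K)
      return bvn(g1, g2, x[off_muH], x[off_muH + 1],
                 x[off_v + 2], x[off_v + 3], x[off_v + 8]);
    return bvn(g1, g2, m01[l], m02[l], r0s1[l], r0s2[l], r0c[l]);
  }

  double lp_gamma(int l) const { return lp_gamma_comp(l, z[l]); }

  // mixture-marginal density of gamma_l (indicator summed out); used by
  // the joint gamma block update, which is followed by an exact Gibbs
  // draw of the indicator so the collapsed move remains valid
  double lp_gamma_mix(int l) const {
    double mx = R_NegInf, lw[64];
    for (int c = 0; c < K + 2; ++c) {
      double w = wgt(l, c);
      lw[c] = (w > 0.0) ? log(w) + lp_gamma_comp(l, c) : R_NegInf;
      if (lw[c] > mx) mx = lw[c];
    }
    if (mx == R_NegInf) return R_NegInf;
    double s = 0.0;
    for (int c = 0; c < K + 2; ++c)
      if (lw[c] > R_NegInf) s += exp(lw[c] - mx);
    return mx + log(s);
  }

  double lp_m() const {
    double a = (x[off_m] - b1) / s1, b = (x[off_m + 1] - b2) / s2;
    return -0.5 * (a * a + b * b);
  }

  double lp_muH() const {
    double a = (x[off_muH] - b1) / s1, b = (x[off_muH + 1] - b2) / s2;
    return -0.5 * (a * a + b * b);
  }

  double lp_delta(int k) const {
    double d = x[off_delta + k];
    if (d <= 0.0) return R_NegInf;
    double a = (log(d) - dml[k]) / dsl[k];
    return -log(d) - 0.5 * a * a;
  }

  double lp_eps(int l) const {
    double e = x[off_eps + l];
    if (e <= eps_lo || e >= eps_hi) return R_NegInf;
    double a = (e - 1.0) / nu[l];
    return -0.5 * a * a;
  }

  // prior of v-block coordinate v (0..8)
  double lp_v(int v) const {
    double val = x[off_v + v];
    if (v <= 3) { // tau
      if (val <= 0.0) return R_NegInf;
      return -0.5 * val * val / (zs[v] * zs[v]);
    }
    if (v <= 5) { // sigma
      if (val <= 0.0) return R_NegInf;
      double c = cs[v - 4];
      return -0.5 * val * val / (c * c);
    }
    return std::fabs(val) >= 1.0 ? R_NegInf : 0.0; // rho, kappa, eta
  }

  // conditional log posterior of coordinate j (terms involving x[j] only)
  double cond(int j) const {
    if (j < off_muS) {
      int i = (j - off_theta) / 2;
      return ll_study(i) + lp_theta(i);
    }
    if (j < off_m) {
      int k = (j - off_muS) / 2;
      double s = lp_muS(k);
      for (int i = 0; i < M; ++i) if (asp[i] == k) s += lp_theta(i);
      for (int l = 0; l < L; ++l) if (z[l] == k) s += lp_gamma(l);
      return s;
    }
    if (j < off_muH) {
      double s = lp_m();
      for (int k = 0; k < K; ++k) s += lp_muS(k);
      return s;
    }
    if (j < off_gamma) {
      double s = lp_muH();
      for (int l = 0; l < L; ++l) if (z[l] == K) s += lp_gamma(l);
      return s;
    }
    if (j < off_eps) {
      int l = (j - off_gamma) / 2;
      return ll_human(l) + lp_gamma(l);
    }
    if (j < off_delta) {
      int l = j - off_eps;
      double lp = lp_eps(l);
      if (lp == R_NegInf) return lp;
      return ll_human(l) + lp;
    }
    if (j < off_v) {
      int k = j - off_delta;
      double s = lp_delta(k);
      if (s == R_NegInf) return s;
      for (int i = 0; i < M; ++i) if (asp[i] == k) s += ll_study(i);
      return s;
    }
    int v = j - off_v;
    double s = lp_v(v);
    if (s == R_NegInf) return s;
    if (v == 0 || v == 1 || v == 6) { // Psi block
      for (int i = 0; i < M; ++i) s += lp_theta(i);
      for (int l = 0; l < L; ++l) if (z[l] < K) s += lp_gamma(l);
    } else if (v == 2 || v == 3 || v == 8) { // Phi block
      for (int l = 0; l < L; ++l) if (z[l] == K) s += lp_gamma(l);
    } else { // Sigma block
      for (int k = 0; k < K; ++k) s += lp_muS(k);
    }
    return s;
  }

  bool has_data(int l) const { return hoff[l + 1] > hoff[l]; }

  // -- symmetric 2x2 helpers for the conjugate mean updates --------------
  struct Mat2 { double a, b, d; };
  static Mat2 cov2(double s1, double s2, double r) {
    return {s1 * s1, r * s1 * s2, s2 * s2};
  }
  static Mat2 inv2(const Mat2& m) {
    double det = m.a * m.d - m.b * m.b;
    return {m.d / det, -m.b / det, m.a / det};
  }

  // draw x ~ BVN(mean, Lambda^{-1}) given precision Lambda and
  // Lambda * mean = rhs; writes into x[j], x[j+1]
  void draw_bvn_prec(int j, const Mat2& Lam, double rhs1, double rhs2) {
    Mat2 C = inv2(Lam);
    double mu1 = C.a * rhs1 + C.b * rhs2;
    double mu2 = C.b * rhs1 + C.d * rhs2;
    double l11 = sqrt(C.a), l21 = C.b / l11, l22 = sqrt(C.d - l21 * l21);
    double z1 = R::norm_rand(), z2 = R::norm_rand();
    x[j] = mu1 + l11 * z1;
    x[j + 1] = mu2 + l21 * z1 + l22 * z2;
  }

  // conjugate Gibbs draw of the species mean muS_k
  void gibbs_muS(int k) {
    Mat2 Psi_inv = inv2(cov2(x[off_v], x[off_v + 1], x[off_v + 6]));
    Mat2 Sig_inv = inv2(cov2(x[off_v + 4], x[off_v + 5], x[off_v + 7]));
    double s1 = 0.0, s2 = 0.0; int nk = 0;
    for (int i = 0; i < M; ++i) if (asp[i] == k) {
      s1 += x[off_theta + 2 * i]; s2 += x[off_theta + 2 * i + 1]; ++nk;
    }
    for (int l = 0; l < L; ++l) if (z[l] == k) {
      s1 += x[off_gamma + 2 * l]; s2 += x[off_gamma + 2 * l + 1]; ++nk;
    }
    Mat2 Lam = {Sig_inv.a + nk * Psi_inv.a, Sig_inv.b + nk * Psi_inv.b,
                Sig_inv.d + nk * Psi_inv.d};
    double rhs1 = Sig_inv.a * x[off_m] + Sig_inv.b * x[off_m + 1] +
                  Psi_inv.a * s1 + Psi_inv.b * s2;
    double rhs2 = Sig_inv.b * x[off_m] + Sig_inv.d * x[off_m + 1] +
                  Psi_inv.b * s1 + Psi_inv.d * s2;
    draw_bvn_prec(off_muS + 2 * k, Lam, rhs1, rhs2);
  }

  // conjugate Gibbs draw of the supra-species mean m
  void gibbs_m() {
    Mat2 Sig_inv = inv2(cov2(x[off_v + 4], x[off_v + 5], x[off_v + 7]));
    double p1 = 1.0 / (s1 * s1), p2 = 1.0 / (s2 * s2);
    double sm1 = 0.0, sm2 = 0.0;
    for (int k = 0; k < K; ++k) {
      sm1 += x[off_muS + 2 * k]; sm2 += x[off_muS + 2 * k + 1];
    }
    Mat2 Lam = {p1 + K * Sig_inv.a, K * Sig_inv.b, p2 + K * Sig_inv.d};
    double rhs1 = p1 * b1 + Sig_inv.a * sm1 + Sig_inv.b * sm2;
    double rhs2 = p2 * b2 + Sig_inv.b * sm1 + Sig_inv.d * sm2;
    draw_bvn_prec(off_m, Lam, rhs1, rhs2);
  }

  // conjugate Gibbs draw of the human population mean muH
  void gibbs_muH() {
    Mat2 Phi_inv = inv2(cov2(x[off_v + 2], x[off_v + 3], x[off_v + 8]));
    double p1 = 1.0 / (s1 * s1), p2 = 1.0 / (s2 * s2);
    double sg1 = 0.0, sg2 = 0.0; int nh = 0;
    for (int l = 0; l < L; ++l) if (z[l] == K) {
      sg1 += x[off_gamma + 2 * l]; sg2 += x[off_gamma + 2 * l + 1]; ++nh;
    }
    Mat2 Lam = {p1 + nh * Phi_inv.a, nh * Phi_inv.b, p2 + nh * Phi_inv.d};
    double rhs1 = p1 * b1 + Phi_inv.a * sg1 + Phi_inv.b * sg2;
    double rhs2 = p2 * b2 + Phi_inv.b * sg1 + Phi_inv.d * sg2;
    draw_bvn_prec(off_muH, Lam, rhs1, rhs2);
  }

  // exact conditional draw of gamma_l from its mixture component (valid
  // whenever the subgroup contributes no likelihood)
  void gibbs_gamma(int l) {
    int c = z[l];
    double m1, m2, s1d, s2d, r;
    if (c < K) {
      m1 = x[off_muS + 2 * c]; m2 = x[off_muS + 2 * c + 1];
      s1d = x[off_v]; s2d = x[off_v + 1]; r = x[off_v + 6];
    } else if (c == K) {
      m1 = x[off_muH]; m2 = x[off_muH + 1];
      s1d = x[off_v + 2]; s2d = x[off_v + 3]; r = x[off_v + 8];
    } else {
      m1 = m01[l]; m2 = m02[l]; s1d = r0s1[l]; s2d = r0s2[l]; r = r0c[l];
    }
    double z1 = R::norm_rand(), z2 = R::norm_rand();
    x[off_gamma + 2 * l] = m1 + s1d * z1;
    x[off_gamma + 2 * l + 1] = m2 + s2d * (r * z1 + sqrt(1.0 - r * r) * z2);
  }

  // exact conditional draw of eps_l from its truncated-normal prior
  void gibbs_eps(int l) {
    double plo = R::pnorm(eps_lo, 1.0, nu[l], 1, 0);
    double phi = R::pnorm(eps_hi, 1.0, nu[l], 1, 0);
    x[off_eps + l] = R::qnorm(R::runif(plo, phi), 1.0, nu[l], 1, 0);
  }

  void gibbs_z(int l) {
    double lw[64];
    int nc = K + 2;
    double mx = R_NegInf;
    for (int c = 0; c < nc; ++c) {
      double w = wgt(l, c);
      lw[c] = (w > 0.0) ? log(w) + lp_gamma_comp(l, c) : R_NegInf;
      if (lw[c] > mx) mx = lw[c];
    }
    double tot = 0.0;
    for (int c = 0; c < nc; ++c) {
      lw[c] = (lw[c] == R_NegInf) ? 0.0 : exp(lw[c] - mx);
      tot += lw[c];
    }
    double u = R::runif(0.0, tot), acc = 0.0;
    for (int c = 0; c < nc; ++c) {
      acc += lw[c];
      if (u <= acc) { z[l] = c; return; }
    }
    z[l] = nc - 1;
  }
};

} // namespace

// [[Rcpp::export(name = ".bridge_mcmc")]]
List bridge_mcmc(List data, List priors, List control) {
  Sampler S;
  S.M = as<int>(data["M"]); S.K = as<int>(data["K"]); S.L = as<int>(data["L"]);
  S.asp = as<std::vector<int>>(data["asp"]);
  S.adose = as<std::vector<double>>(data["adose"]);
  S.an = as<std::vector<double>>(data["an"]);
  S.ar = as<std::vector<double>>(data["ar"]);
  S.aoff = as<std::vector<int>>(data["aoff"]);
  S.hdose = as<std::vector<double>>(data["hdose"]);
  S.hn = as<std::vector<double>>(data["hn"]);
  S.hr = as<std::vector<double>>(data["hr"]);
  S.hoff = as<std::vector<int>>(data["hoff"]);

  S.b1 = as<double>(priors["b1"]); S.s1 = as<double>(priors["s1"]);
  S.b2 = as<double>(priors["b2"]); S.s2 = as<double>(priors["s2"]);
  S.dref = as<double>(priors["dref"]);
  S.eps_lo = as<double>(priors["eps_lo"]); S.eps_hi = as<double>(priors["eps_hi"]);
  S.zs = as<std::vector<double>>(priors["z"]);
  S.cs = as<std::vector<double>>(priors["c_sigma"]);
  S.dml = as<std::vector<double>>(priors["delta_meanlog"]);
  S.dsl = as<std::vector<double>>(priors["delta_sdlog"]);
  S.nu = as<std::vector<double>>(priors["nu"]);
  S.m01 = as<std::vector<double>>(priors["m01"]);
  S.m02 = as<std::vector<double>>(priors["m02"]);
  S.r0s1 = as<std::vector<double>>(priors["r0sd1"]);
  S.r0s2 = as<std::vector<double>>(priors["r0sd2"]);
  S.r0c = as<std::vector<double>>(priors["r0corr"]);
  NumericMatrix Wm = as<NumericMatrix>(priors["weights"]); // L x (K+2)
  S.W.assign(S.L * (S.K + 2), 0.0);
  for (int l = 0; l < S.L; ++l)
    for (int c = 0; c < S.K + 2; ++c) S.W[l * (S.K + 2) + c] = Wm(l, c);

  S.layout();

  int n_chains = as<int>(control["chains"]);
  int n_iter = as<int>(control["iterations"]);
  int n_burn = as<int>(control["burnin"]);
  int thin = as<int>(control["thin"]);
  NumericVector fixed = as<NumericVector>(control["fixed"]); // NA = free
  IntegerVector zfix = as<IntegerVector>(control["zfix"]);   // 0 = free, else 1..K+2

  int kept_per_chain = (n_iter - n_burn) / thin;
  int kept = kept_per_chain * n_chains;
  NumericMatrix draws(kept, S.npar);
  IntegerMatrix zdraws(kept, S.L);
  IntegerVector chain_id(kept);
  NumericVector acc_rate(S.npar);
  int row = 0;

  std::vector<bool> free_par(S.npar, true);
  for (int j = 0; j < S.npar; ++j)
    if (!NumericVector::is_na(fixed[j])) free_par[j] = false;

  RNGScope scope;

  long long acc_tot = 0, att_tot = 0;
  std::vector<double> acc_j(S.npar, 0.0), att_j(S.npar, 0.0);

  for (int ch = 0; ch < n_chains; ++ch) {
    // initial state: prior centres with chain-specific jitter
    S.x.assign(S.npar, 0.0);
    S.z.assign(S.L, S.K + 1);
    for (int i = 0; i < S.M; ++i) {
      S.x[S.off_theta + 2 * i] = S.b1; S.x[S.off_theta + 2 * i + 1] = S.b2;
    }
    for (int k = 0; k < S.K; ++k) {
      S.x[S.off_muS + 2 * k] = S.b1; S.x[S.off_muS + 2 * k + 1] = S.b2;
      S.x[S.off_delta + k] = exp(S.dml[k]);
    }
    S.x[S.off_m] = S.b1; S.x[S.off_m + 1] = S.b2;
    S.x[S.off_muH] = S.b1; S.x[S.off_muH + 1] = S.b2;
    for (int l = 0; l < S.L; ++l) {
      S.x[S.off_gamma + 2 * l] = S.b1; S.x[S.off_gamma + 2 * l + 1] = S.b2;
      S.x[S.off_eps + l] = 1.0;
    }
    for (int v = 0; v < 4; ++v) S.x[S.off_v + v] = 0.5 * S.zs[v];
    S.x[S.off_v + 4] = 0.5 * S.cs[0]; S.x[S.off_v + 5] = 0.5 * S.cs[1];
    S.x[S.off_v + 6] = 0.0; S.x[S.off_v + 7] = 0.0; S.x[S.off_v + 8] = 0.0;

    for (int j = 0; j < S.npar; ++j) {
      if (!free_par[j]) { S.x[j] = fixed[j]; continue; }
      double jit = R::rnorm(0.0, 0.1);
      if (j >= S.off_v && j - S.off_v <= 5) // sds: keep positive
        S.x[j] = S.x[j] * exp(jit);
      else if (j >= S.off_v) // correlations
        S.x[j] = std::max(-0.9, std::min(0.9, S.x[j] + jit));
      else if (j >= S.off_delta && j < S.off_v)
        S.x[j] = S.x[j] * exp(jit);
      else if (j >= S.off_eps && j < S.off_delta)
        S.x[j] = std::max(S.eps_lo + 0.05,
                          std::min(S.eps_hi - 0.05, S.x[j] + 0.5 * jit));
      else
        S.x[j] = S.x[j] + 3.0 * jit;
    }
    for (int l = 0; l < S.L; ++l) {
      if (zfix[l] > 0) { S.z[l] = zfix[l] - 1; continue; }
      // initial component draw from the prior weights
      double u = R::runif(0.0, 1.0), accw = 0.0;
      for (int c = 0; c < S.K + 2; ++c) {
        accw += S.wgt(l, c);
        if (u <= accw) { S.z[l] = c; break; }
      }
    }

    // adaptive step sizes (log scale)
    std::vector<double> ls(S.npar, log(0.4));
    std::vector<double> bacc(S.npar, 0.0), batt(S.npar, 0.0);
    int batch = 0;

    // coordinates with exact conditional draws bypass the random walk:
    // gamma/eps of data-free subgroups, and the conjugate means muS, m, muH
    std::vector<bool> exact(S.npar, false);
    for (int l = 0; l < S.L; ++l) {
      if (S.has_data(l)) continue;
      if (free_par[S.off_gamma + 2 * l] && free_par[S.off_gamma + 2 * l + 1]) {
        exact[S.off_gamma + 2 * l] = true;
        exact[S.off_gamma + 2 * l + 1] = true;
      }
      if (free_par[S.off_eps + l]) exact[S.off_eps + l] = true;
    }
    std::vector<bool> muS_exact(S.K, false);
    for (int k = 0; k < S.K; ++k)
      if (free_par[S.off_muS + 2 * k] && free_par[S.off_muS + 2 * k + 1]) {
        muS_exact[k] = true;
        exact[S.off_muS + 2 * k] = true; exact[S.off_muS + 2 * k + 1] = true;
      }
    bool m_exact = free_par[S.off_m] && free_par[S.off_m + 1];
    if (m_exact) { exact[S.off_m] = true; exact[S.off_m + 1] = true; }
    bool muH_exact = free_par[S.off_muH] && free_par[S.off_muH + 1];
    if (muH_exact) { exact[S.off_muH] = true; exact[S.off_muH + 1] = true; }

    // data-bearing subgroups: joint adaptive Metropolis on (gamma1, gamma2),
    // whose posterior is strongly correlated; empirical proposal covariance
    // accumulated during burn-in (diminishing adaptation), frozen afterwards
    std::vector<int> gblk;
    for (int l = 0; l < S.L; ++l)
      if (S.has_data(l) && free_par[S.off_gamma + 2 * l] &&
          free_par[S.off_gamma + 2 * l + 1]) {
        gblk.push_back(l);
        exact[S.off_gamma + 2 * l] = true;      // skip in componentwise scan
        exact[S.off_gamma + 2 * l + 1] = true;  // (updated as a block below)
      }
    int nb = (int)gblk.size();
    std::vector<double> bmean1(nb, 0.0), bmean2(nb, 0.0);
    std::vector<double> m2_11(nb, 0.0), m2_12(nb, 0.0), m2_22(nb, 0.0);
    std::vector<long> bcnt(nb, 0);
    std::vector<double> lsb(nb, 0.0), bl_acc(nb, 0.0), bl_att(nb, 0.0);

    for (int it = 0; it < n_iter; ++it) {
      for (int j = 0; j < S.npar; ++j) {
        if (!free_par[j] || exact[j]) continue;
        // heterogeneity sds / correlations get extra sweeps: they gate the
        // mixing of every exact mean draw and are cheap to evaluate
        int nrep = (j >= S.off_v) ? 3 : 1;
        for (int rep = 0; rep < nrep; ++rep) {
          double cur = S.x[j];
          double lp0 = S.cond(j);
          S.x[j] = cur + exp(ls[j]) * R::norm_rand();
          double lp1 = S.cond(j);
          batt[j] += 1.0; att_j[j] += 1.0; ++att_tot;
          if (lp1 > R_NegInf &&
              (lp1 >= lp0 || R::unif_rand() < exp(lp1 - lp0))) {
            bacc[j] += 1.0; acc_j[j] += 1.0; ++acc_tot;
          } else {
            S.x[j] = cur;
          }
        }
      }
      for (int b = 0; b < nb; ++b) {
        for (int rep = 0; rep < 4; ++rep) { // cheap block: extra sweeps
        int l = gblk[b], j = S.off_gamma + 2 * l;
        // proposal covariance: empirical after enough history, else diagonal
        double c11 = 0.04, c12 = 0.0, c22 = 0.04;
        if (bcnt[b] >= 50) {
          c11 = m2_11[b] / (bcnt[b] - 1) + 1e-8;
          c12 = m2_12[b] / (bcnt[b] - 1);
          c22 = m2_22[b] / (bcnt[b] - 1) + 1e-8;
        }
        double sc = exp(lsb[b]);
        double l11 = sqrt(c11), l21 = c12 / l11;
        double l22sq = c22 - l21 * l21;
        double l22 = l22sq > 0.0 ? sqrt(l22sq) : 1e-4;
        double z1 = R::norm_rand(), z2 = R::norm_rand();
        double cur1 = S.x[j], cur2 = S.x[j + 1];
        double lp0 = S.ll_human(l) + S.lp_gamma_mix(l);
        S.x[j] = cur1 + sc * l11 * z1;
        S.x[j + 1] = cur2 + sc * (l21 * z1 + l22 * z2);
        double lp1 = S.ll_human(l) + S.lp_gamma_mix(l);
        bl_att[b] += 1.0;
        if (lp1 > R_NegInf &&
            (lp1 >= lp0 || R::unif_rand() < exp(lp1 - lp0))) {
          bl_acc[b] += 1.0;
        } else {
          S.x[j] = cur1; S.x[j + 1] = cur2;
        }
        if (zfix[l] == 0) S.gibbs_z(l); // restore (gamma, z) joint
        if (it < n_burn) { // accumulate empirical moments (Welford)
          ++bcnt[b];
          double d1 = S.x[j] - bmean1[b], d2 = S.x[j + 1] - bmean2[b];
          bmean1[b] += d1 / bcnt[b]; bmean2[b] += d2 / bcnt[b];
          double e1 = S.x[j] - bmean1[b], e2 = S.x[j + 1] - bmean2[b];
          m2_11[b] += d1 * e1; m2_12[b] += d1 * e2; m2_22[b] += d2 * e2;
        }
        }
      }
      for (int k = 0; k < S.K; ++k) if (muS_exact[k]) S.gibbs_muS(k);
      if (m_exact) S.gibbs_m();
      if (muH_exact) S.gibbs_muH();
      for (int l = 0; l < S.L; ++l) {
        if (!S.has_data(l)) {
          // order matters: refresh gamma under the current component first
          // so the indicator draw sees a gamma consistent with the mixture
          if (exact[S.off_gamma + 2 * l]) S.gibbs_gamma(l);
          if (exact[S.off_eps + l]) S.gibbs_eps(l);
        }
        if (zfix[l] == 0) S.gibbs_z(l);
      }

      if (it < n_burn && ((it + 1) % 50 == 0)) {
        ++batch;
        double step = std::min(0.25, 1.0 / sqrt((double)batch));
        for (int j = 0; j < S.npar; ++j) {
          if (batt[j] == 0.0) continue;
          double rate = bacc[j] / batt[j];
          ls[j] += (rate > 0.44 ? step : -step);
          bacc[j] = 0.0; batt[j] = 0.0;
        }
        for (int b = 0; b < nb; ++b) {
          if (bl_att[b] == 0.0) continue;
          double rate = bl_acc[b] / bl_att[b];
          lsb[b] += (rate > 0.234 ? step : -step);
          bl_acc[b] = 0.0; bl_att[b] = 0.0;
        }
      }

      if (it >= n_burn && ((it - n_burn) % thin == 0)) {
        for (int j = 0; j < S.npar; ++j) draws(row, j) = S.x[j];
        for (int l = 0; l < S.L; ++l) zdraws(row, l) = S.z[l] + 1;
        chain_id[row] = ch + 1;
        ++row;
      }
    }
  }

  for (int j = 0; j < S.npar; ++j)
    acc_rate[j] = att_j[j] > 0 ? acc_j[j] / att_j[j] : NA_REAL;

  return List::create(_["draws"] = draws, _["z"] = zdraws,
                      _["chain"] = chain_id, _["accept"] = acc_rate);
}
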