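#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Natural-space parameters of one session.
struct Theta {
  double eps, rho_rew, rho_pun, b, pi_rew, pi_pun, xi;
};

static inline double phi(double x) { return R::pnorm(x, 0.0, 1.0, 1, 0); }

// eta order: eps, rho_rew, rho_pun, b, pi_rew, pi_pun, xi
static inline Theta to_theta(const double *eta) {
  Theta t;
  t.eps = phi(eta[0]);
  t.rho_rew = std::exp(eta[1]);
  t.rho_pun = std::exp(eta[2]);
  t.b = eta[3];
  t.pi_rew = eta[4];
  t.pi_pun = eta[5];
  t.xi = phi(eta[6]);
  return t;
}

// Core recursion: Rescorla-Wagner updates on Q and V, action weights with go
// bias + Pavlovian term, noisy softmax. Stimuli 1..4 in order gw, ngw, gal,
// ngal, so stim <= 2 marks a win cue.
static double sess_ll(const int *stim, const int *go, const int *out, int n,
                      const Theta &th) {
  double Q[4][2] = {{0, 0}, {0, 0}, {0, 0}, {0, 0}};
  double V[4] = {0, 0, 0, 0};
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    const int s = stim[t] - 1;
    const bool win = s < 2;
    const double piv = win ? th.pi_rew : th.pi_pun;
    const double rho = win ? th.rho_rew : th.rho_pun;
    const double wg = Q[s][0] + th.b + piv * V[s];
    const double wn = Q[s][1];
    const double m = wg > wn ? wg : wn;
    const double eg = std::exp(wg - m), en = std::exp(wn - m);
    const double pgo = (1.0 - th.xi) * eg / (eg + en) + 0.5 * th.xi;
    const double p = go[t] ? pgo : 1.0 - pgo;
    ll += std::log(p > 1e-300 ? p : 1e-300);
    const double target = rho * out[t];
    const int a = go[t] ? 0 : 1;
    Q[s][a] += th.eps * (target - Q[s][a]);
    V[s] += th.eps * (target - V[s]);
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_session_loglik(IntegerVector stim, IntegerVector go,
                          IntegerVector outcome, NumericVector theta) {
  if (theta.size() != 7) stop("theta must have length 7");
  Theta th;
  th.eps = theta[0]; th.rho_rew = theta[1]; th.rho_pun = theta[2];
  th.b = theta[3]; th.pi_rew = theta[4]; th.pi_pun = theta[5];
  th.xi = theta[6];
  return sess_ll(stim.begin(), go.begin(), outcome.begin(), stim.size(), th);
}

// Generative pass: draws responses from the model and outcomes from the
// probabilistic schedule, updating values with the realized outcome.
// [[Rcpp::export]]
List cpp_simulate_session(IntegerVector stim, IntegerVector correct_go,
                          IntegerVector is_win, NumericVector theta,
                          double p_corr, double p_incorr) {
  const int n = stim.size();
  Theta th;
  th.eps = theta[0]; th.rho_rew = theta[1]; th.rho_pun = theta[2];
  th.b = theta[3]; th.pi_rew = theta[4]; th.pi_pun = theta[5];
  th.xi = theta[6];
  double Q[4][2] = {{0, 0}, {0, 0}, {0, 0}, {0, 0}};
  double V[4] = {0, 0, 0, 0};
  IntegerVector go(n), outcome(n);
  for (int t = 0; t < n; ++t) {
    const int s = stim[t] - 1;
    const bool win = is_win[t] == 1;
    const double piv = win ? th.pi_rew : th.pi_pun;
    const double rho = win ? th.rho_rew : th.rho_pun;
    const double wg = Q[s][0] + th.b + piv * V[s];
    const double wn = Q[s][1];
    const double m = wg > wn ? wg : wn;
    const double eg = std::exp(wg - m), en = std::exp(wn - m);
    const double pgo = (1.0 - th.xi) * eg / (eg + en) + 0.5 * th.xi;
    const int g = unif_rand() < pgo ? 1 : 0;
    const bool correct = (g == correct_go[t]);
    const double p = correct ? p_corr : p_incorr;
    const bool optimal = unif_rand() < p;
    int r;
    if (win) r = optimal ? 1 : 0;
    else     r = optimal ? 0 : -1;
    go[t] = g; outcome[t] = r;
    const double target = rho * r;
    const int a = g ? 0 : 1;
    Q[s][a] += th.eps * (target - Q[s][a]);
    V[s] += th.eps * (target - V[s]);
  }
  return List::create(_["go"] = go, _["outcome"] = outcome);
}

// ---------------------------------------------------------------------------
// Hierarchical sampler
//
// Non-centered parameterization: eta[i,k] = mu[g_i,k] + (X beta)[i,k]
//                                           + sigma[k] * z[i,k], k = 0..13
// (k < 7: session-1 parameters; k >= 7: session deltas). Priors:
// mu, beta ~ N(0,1); sigma ~ half-N(1) (sampled on the log scale with the
// Jacobian term); z ~ N(0,1). Componentwise adaptive random-walk Metropolis,
// step sizes tuned to ~0.44 acceptance during warmup and frozen afterwards.
// ---------------------------------------------------------------------------

struct HierData {
  int N, G, C;
  std::vector<int> grp;              // 0-based group index per subject
  std::vector<double> X;             // N x C, column-major
  std::vector<int> stim, go, out;    // concatenated trials
  std::vector<int> off1, len1, off2, len2;  // per-subject session slices
};

class HierSampler {
public:
  HierData d;
  std::vector<double> mu, beta, w, z;   // w = log sigma
  std::vector<double> ls_mu, ls_beta, ls_w, ls_z;  // log step sizes
  std::vector<double> ls_mu_t, ls_w_s;  // interweaving-move step sizes
  std::vector<double> cll1, cll2;       // cached per-subject session logliks
  std::vector<long>   acc, tot;         // acceptance bookkeeping (by block)
  double target;
  long sweep_count;
  bool adapting;

  void eta_for(int i, double *eta) const {
    const double *Xr = d.C ? &d.X[0] : nullptr;
    for (int k = 0; k < 14; ++k) {
      double e = mu[k * d.G + d.grp[i]] + std::exp(w[k]) * z[i * 14 + k];
      for (int c = 0; c < d.C; ++c)
        e += Xr[c * d.N + i] * beta[k * d.C + c];
      eta[k] = e;
    }
  }

  double ll1_of(int i, const double *eta) const {
    if (d.len1[i] == 0) return 0.0;
    Theta th = to_theta(eta);
    return sess_ll(&d.stim[d.off1[i]], &d.go[d.off1[i]], &d.out[d.off1[i]],
                   d.len1[i], th);
  }
  double ll2_of(int i, const double *eta) const {
    if (d.len2[i] == 0) return 0.0;
    double e2[7];
    for (int k = 0; k < 7; ++k) e2[k] = eta[k] + eta[7 + k];
    Theta th = to_theta(e2);
    return sess_ll(&d.stim[d.off2[i]], &d.go[d.off2[i]], &d.out[d.off2[i]],
                   d.len2[i], th);
  }

  void refresh_cache() {
    double eta[14];
    for (int i = 0; i < d.N; ++i) {
      eta_for(i, eta);
      cll1[i] = ll1_of(i, eta);
      cll2[i] = ll2_of(i, eta);
    }
  }

  void adapt(double *ls, double alpha) {
    if (!adapting) return;
    const double gamma = 0.75 / std::pow((double)sweep_count + 1.0, 0.6);
    *ls += gamma * (alpha - target);
    if (*ls > 3.0) *ls = 3.0;
    if (*ls < -8.0) *ls = -8.0;
  }

  // Generic single-site update for a parameter entering subject i only.
  void update_z(int i, int k) {
    double eta[14];
    eta_for(i, eta);
    const double cur = z[i * 14 + k];
    const double step = std::exp(ls_z[i * 14 + k]);
    const double prop = cur + step * norm_rand();
    const double sig = std::exp(w[k]);
    eta[k] += sig * (prop - cur);
    double dlp = -0.5 * (prop * prop - cur * cur);
    double n1 = cll1[i], n2;
    if (k < 7) {
      n1 = ll1_of(i, eta);
      dlp += n1 - cll1[i];
    }
    n2 = ll2_of(i, eta);
    dlp += n2 - cll2[i];
    const double alpha = dlp >= 0 ? 1.0 : std::exp(dlp);
    tot[0]++;
    if (unif_rand() < alpha) {
      acc[0]++;
      z[i * 14 + k] = prop;
      cll1[i] = n1;
      cll2[i] = n2;
    }
    adapt(&ls_z[i * 14 + k], alpha);
  }

  // Update of a group-level location mu[g,k]; touches subjects in group g.
  void update_mu(int g, int k) {
    const int idx = k * d.G + g;
    const double cur = mu[idx];
    const double step = std::exp(ls_mu[idx]);
    const double prop = cur + step * norm_rand();
    double dlp = -0.5 * (prop * prop - cur * cur);
    std::vector<double> n1(d.N), n2(d.N);
    double eta[14];
    mu[idx] = prop;
    for (int i = 0; i < d.N; ++i) {
      if (d.grp[i] != g) continue;
      eta_for(i, eta);
      if (k < 7) { n1[i] = ll1_of(i, eta); dlp += n1[i] - cll1[i]; }
      n2[i] = ll2_of(i, eta);
      dlp += n2[i] - cll2[i];
    }
    mu[idx] = cur;
    const double alpha = dlp >= 0 ? 1.0 : std::exp(dlp);
    tot[1]++;
    if (unif_rand() < alpha) {
      acc[1]++;
      mu[idx] = prop;
      for (int i = 0; i < d.N; ++i) {
        if (d.grp[i] != g) continue;
        if (k < 7) cll1[i] = n1[i];
        cll2[i] = n2[i];
      }
    }
    adapt(&ls_mu[idx], alpha);
  }

  void update_beta(int c, int k) {
    const int idx = k * d.C + c;
    const double cur = beta[idx];
    const double step = std::exp(ls_beta[idx]);
    const double prop = cur + step * norm_rand();
    double dlp = -0.5 * (prop * prop - cur * cur);
    std::vector<double> n1(d.N), n2(d.N);
    double eta[14];
    beta[idx] = prop;
    for (int i = 0; i < d.N; ++i) {
      eta_for(i, eta);
      if (k < 7) { n1[i] = ll1_of(i, eta); dlp += n1[i] - cll1[i]; }
      n2[i] = ll2_of(i, eta);
      dlp += n2[i] - cll2[i];
    }
    beta[idx] = cur;
    const double alpha = dlp >= 0 ? 1.0 : std::exp(dlp);
    tot[2]++;
    if (unif_rand() < alpha) {
      acc[2]++;
      beta[idx] = prop;
      for (int i = 0; i < d.N; ++i) {
        if (k < 7) cll1[i] = n1[i];
        cll2[i] = n2[i];
      }
    }
    adapt(&ls_beta[idx], alpha);
  }

  // Group scale on the log scale: prior half-N(1) on sigma plus Jacobian
  // gives log p(w) = -0.5 exp(2w) + w (+ const).
  void update_w(int k) {
    const double cur = w[k];
    const double step = std::exp(ls_w[k]);
    const double prop = cur + step * norm_rand();
    double dlp = (-0.5 * std::exp(2.0 * prop) + prop) -
                 (-0.5 * std::exp(2.0 * cur) + cur);
    std::vector<double> n1(d.N), n2(d.N);
    double eta[14];
    w[k] = prop;
    for (int i = 0; i < d.N; ++i) {
      eta_for(i, eta);
      if (k < 7) { n1[i] = ll1_of(i, eta); dlp += n1[i] - cll1[i]; }
      n2[i] = ll2_of(i, eta);
      dlp += n2[i] - cll2[i];
    }
    w[k] = cur;
    const double alpha = dlp >= 0 ? 1.0 : std::exp(dlp);
    tot[3]++;
    if (unif_rand() < alpha) {
      acc[3]++;
      w[k] = prop;
      for (int i = 0; i < d.N; ++i) {
        if (k < 7) cll1[i] = n1[i];
        cll2[i] = n2[i];
      }
    }
    adapt(&ls_w[k], alpha);
  }

  // Interweaving translation: shift mu[g,k] by delta and counter-shift the
  // z of that group so every subject's eta -- and the likelihood -- stays
  // fixed. Only the normal priors change; the shear has unit Jacobian.
  void update_mu_trans(int g, int k) {
    const int idx = k * d.G + g;
    const double step = std::exp(ls_mu_t[idx]);
    const double delta = step * norm_rand();
    const double sig = std::exp(w[k]);
    const double cur = mu[idx];
    double dlp = -0.5 * ((cur + delta) * (cur + delta) - cur * cur);
    for (int i = 0; i < d.N; ++i) {
      if (d.grp[i] != g) continue;
      const double zc = z[i * 14 + k], zn = zc - delta / sig;
      dlp += -0.5 * (zn * zn - zc * zc);
    }
    const double alpha = dlp >= 0 ? 1.0 : std::exp(dlp);
    if (unif_rand() < alpha) {
      mu[idx] = cur + delta;
      for (int i = 0; i < d.N; ++i)
        if (d.grp[i] == g) z[i * 14 + k] -= delta / sig;
    }
    adapt(&ls_mu_t[idx], alpha);
  }

  // Interweaving rescale: w[k] += delta (sigma scales by e^delta) with all
  // z[.,k] scaled by e^{-delta}; eta invariant, Jacobian term -N*delta.
  void update_w_scale(int k) {
    const double step = std::exp(ls_w_s[k]);
    const double delta = step * norm_rand();
    const double cur = w[k], prop = cur + delta;
    double dlp = (-0.5 * std::exp(2.0 * prop) + prop) -
                 (-0.5 * std::exp(2.0 * cur) + cur) - d.N * delta;
    const double f = std::exp(-delta);
    for (int i = 0; i < d.N; ++i) {
      const double zc = z[i * 14 + k];
      dlp += -0.5 * zc * zc * (f * f - 1.0);
    }
    const double alpha = dlp >= 0 ? 1.0 : std::exp(dlp);
    if (unif_rand() < alpha) {
      w[k] = prop;
      for (int i = 0; i < d.N; ++i) z[i * 14 + k] *= f;
    }
    adapt(&ls_w_s[k], alpha);
  }

  void sweep() {
    for (int i = 0; i < d.N; ++i)
      for (int k = 0; k < 14; ++k) update_z(i, k);
    for (int g = 0; g < d.G; ++g)
      for (int k = 0; k < 14; ++k) { update_mu(g, k); update_mu_trans(g, k); }
    for (int c = 0; c < d.C; ++c)
      for (int k = 0; k < 14; ++k) update_beta(c, k);
    for (int k = 0; k < 14; ++k) { update_w(k); update_w_scale(k); }
    sweep_count++;
  }
};

// [[Rcpp::export]]
List cpp_run_chain(List packed, int iter, int warmup, int thin,
                   double init_jitter, double target_accept) {
  HierSampler s;
  s.d.N = as<int>(packed["n_sub"]);
  s.d.G = as<int>(packed["n_grp"]);
  s.d.C = as<int>(packed["n_cov"]);
  s.d.grp = as<std::vector<int> >(packed["grp"]);
  s.d.X = as<std::vector<double> >(packed["X"]);
  s.d.stim = as<std::vector<int> >(packed["stim"]);
  s.d.go = as<std::vector<int> >(packed["go"]);
  s.d.out = as<std::vector<int> >(packed["outcome"]);
  s.d.off1 = as<std::vector<int> >(packed["off1"]);
  s.d.len1 = as<std::vector<int> >(packed["len1"]);
  s.d.off2 = as<std::vector<int> >(packed["off2"]);
  s.d.len2 = as<std::vector<int> >(packed["len2"]);

  const int N = s.d.N, G = s.d.G, C = s.d.C;
  if (iter <= warmup) stop("iter must exceed warmup");

  s.mu.assign(14 * G, 0.0);
  s.beta.assign(14 * C, 0.0);
  s.w.assign(14, std::log(0.5));
  s.z.assign(14 * N, 0.0);
  for (size_t j = 0; j < s.mu.size(); ++j) s.mu[j] = init_jitter * norm_rand();
  for (size_t j = 0; j < s.beta.size(); ++j)
    s.beta[j] = init_jitter * norm_rand();
  for (size_t j = 0; j < s.w.size(); ++j)
    s.w[j] += 0.5 * init_jitter * norm_rand();
  for (size_t j = 0; j < s.z.size(); ++j)
    s.z[j] = 0.5 * init_jitter * norm_rand();

  s.ls_mu.assign(14 * G, std::log(0.15));
  s.ls_beta.assign(14 * C, std::log(0.15));
  s.ls_w.assign(14, std::log(0.15));
  s.ls_z.assign(14 * N, std::log(0.4));
  s.ls_mu_t.assign(14 * G, std::log(0.3));
  s.ls_w_s.assign(14, std::log(0.3));
  s.acc.assign(4, 0);
  s.tot.assign(4, 0);
  s.target = target_accept;
  s.sweep_count = 0;
  s.adapting = true;
  s.cll1.assign(N, 0.0);
  s.cll2.assign(N, 0.0);
  s.refresh_cache();

  const int P = 14 * G + 14 * C + 14 + 14 * N;
  const int n_keep = iter - warmup;
  NumericMatrix draws(n_keep, P);
  NumericVector lp(n_keep);

  for (int it = 0; it < iter; ++it) {
    if (it == warmup) s.adapting = false;
    for (int r = 0; r < thin; ++r) s.sweep();
    if (it >= warmup) {
      const int row = it - warmup;
      int col = 0;
      for (int k = 0; k < 14; ++k)
        for (int g = 0; g < G; ++g) draws(row, col++) = s.mu[k * G + g];
      for (int k = 0; k < 14; ++k)
        for (int c = 0; c < C; ++c) draws(row, col++) = s.beta[k * C + c];
      for (int k = 0; k < 14; ++k) draws(row, col++) = std::exp(s.w[k]);
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < 14; ++k) draws(row, col++) = s.z[i * 14 + k];
      double tll = 0.0;
      for (int i = 0; i < N; ++i) tll += s.cll1[i] + s.cll2[i];
      lp[row] = tll;
    }
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector arate(4);
  for (int b = 0; b < 4; ++b)
    arate[b] = s.tot[b] ? (double)s.acc[b] / (double)s.tot[b] : NA_REAL;
  arate.names() = CharacterVector::create("z", "mu", "beta", "sigma");
  return List::create(_["draws"] = draws, _["loglik"] = lp,
                      _["accept_rate"] = arate);
}
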