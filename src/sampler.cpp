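#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Draw from p(v) propto v^{-q/2} exp(-S/(2v)) truncated to [lo, hi]
// (the full conditional of a variance under a bounded-uniform prior on the
// variance itself; q = dimension of the quadratic form, df = q - 2).
// Substituting g = S/(2v) gives g ~ Gamma(q/2 - 1, 1) truncated.
static double rtrunc_var_conditional(double S, double q, double lo, double hi) {
  double shape = 0.5 * q - 1.0;
  if (S <= 0.0 || shape <= 1e-8) {
    // no curvature: conditional is flat (or mass at the lower bound as S->0)
    if (S <= 0.0) return lo;
    return lo + unif_rand() * (hi - lo);
  }
  double glo = S / (2.0 * hi), ghi = S / (2.0 * lo);
  double plo = R::pgamma(glo, shape, 1.0, 1, 0);
  double phi = R::pgamma(ghi, shape, 1.0, 1, 0);
  double g;
  if (phi - plo < 1e-12) {
    g = shape; // conditional mode; clamp into the admissible window
    if (g < glo) g = glo;
    if (g > ghi) g = ghi;
  } else {
    double u = plo + unif_rand() * (phi - plo);
    g = R::qgamma(u, shape, 1.0, 1, 0);
    if (g < glo) g = glo;
    if (g > ghi) g = ghi;
  }
  return S / (2.0 * g);
}

static inline double col_dot(const NumericMatrix& X, int k,
                             const std::vector<double>& v) {
  const double* x = &X(0, k);
  double s = 0.0;
  size_t n = v.size();
  for (size_t i = 0; i < n; ++i) s += x[i] * v[i];
  return s;
}

static inline double col_col_dot(const NumericMatrix& X, int k1, int k2) {
  const double* a = &X(0, k1);
  const double* b = &X(0, k2);
  double s = 0.0;
  int n = X.nrow();
  for (int i = 0; i < n; ++i) s += a[i] * b[i];
  return s;
}

// Bayesian Variable Selection chain: y = mu + Z a + sum_k x_k alpha_k + e
// with alpha_k ~ pi0 N(0, sg0) + pi1 N(0, sg1), sg1 = ratio * sg0,
// a ~ N(0, A sa), bounded-uniform priors on sa, se and on the mixture scale
// sg0.  Single-site Gibbs for mu, a; marginalized pairwise (or single-site)
// updates for (delta, alpha); conjugate Beta update for pi1; truncated
// scaled-inverse-chi-square updates for sa, se; a multiplicative
// Metropolis-Hastings move rescaling (sg0, sg1, all alpha) jointly.
// All randomness comes from R's RNG (set.seed upstream).
// [[Rcpp::export(name = ".bvs_chain_cpp")]]
List bvs_chain_cpp(NumericVector y,
                   IntegerVector obs_ind,       // 0-based individual of each record
                   NumericMatrix X,             // n_obs x m, centered codes
                   IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                   int n_ind,
                   List priors, List config) {
  const int n_obs = y.size();
  const int m = X.ncol();
  if (X.nrow() != n_obs) stop("nrow(X) must equal length(y)");

  // ---- priors / config ----
  const double ratio   = as<double>(priors["ratio"]);
  const double beta_a  = as<double>(priors["beta_a"]);   // Beta(a, b) on pi1
  const double beta_b  = as<double>(priors["beta_b"]);
  const double sa_lo   = as<double>(priors["sa_bounds_lo"]);
  const double sa_hi   = as<double>(priors["sa_bounds_hi"]);
  const double se_lo   = as<double>(priors["se_bounds_lo"]);
  const double se_hi   = as<double>(priors["se_bounds_hi"]);
  const double g0_lo   = as<double>(priors["g0_bounds_lo"]);
  const double g0_hi   = as<double>(priors["g0_bounds_hi"]);

  double mu   = as<double>(priors["mu_init"]);
  double sa   = as<double>(priors["sa_init"]);
  double se   = as<double>(priors["se_init"]);
  double sg0  = as<double>(priors["sg0_init"]);
  double pi1  = as<double>(priors["pi1_init"]);
  double step = as<double>(priors["mh_step_init"]);

  const int n_cycles  = as<int>(config["n_cycles"]);
  const int burn_in   = as<int>(config["burn_in"]);
  const int thin      = as<int>(config["thin"]);
  const bool pair_upd = as<bool>(config["pair_updates"]);
  const bool prior_only = as<bool>(config["prior_only"]);
  const int tune_int  = as<int>(config["tune_interval"]);
  const int recomp_int = as<int>(config["recompute_interval"]);

  // ---- state ----
  std::vector<double> a(n_ind, 0.0), alpha(m, 0.0);
  std::vector<int> delta(m, 0);
  std::vector<double> e(n_obs), gsnp(n_obs, 0.0);
  int sumdelta = 0;
  for (int i = 0; i < n_obs; ++i) e[i] = prior_only ? 0.0 : (y[i] - mu);

  // per-individual observation lists (CSR layout)
  std::vector<int> obs_ptr(n_ind + 1, 0), obs_idx(n_obs);
  {
    std::vector<int> cnt(n_ind, 0);
    for (int i = 0; i < n_obs; ++i) cnt[obs_ind[i]]++;
    for (int j = 0; j < n_ind; ++j) obs_ptr[j + 1] = obs_ptr[j] + cnt[j];
    std::vector<int> fill(obs_ptr.begin(), obs_ptr.end() - 1);
    for (int i = 0; i < n_obs; ++i) obs_idx[fill[obs_ind[i]]++] = i;
  }

  std::vector<double> xtx(m);
  for (int k = 0; k < m; ++k) xtx[k] = prior_only ? 0.0 : col_col_dot(X, k, k);

  // ---- storage ----
  const int n_store = (n_cycles - burn_in) / thin;
  const int NSC = 10;
  NumericMatrix samples(n_store, NSC);
  CharacterVector scnames = CharacterVector::create(
      "mu", "sigma_a2", "sigma_e2", "sigma_g02", "sigma_g12",
      "pi1", "n_delta", "v_snp", "mh_step", "mh_accept");
  std::vector<double> p_hat(m, 0.0), alpha_mean(m, 0.0), a_mean(n_ind, 0.0);
  long keep = 0;
  int stored = 0;
  double acc_post = 0.0; long n_post_mh = 0;
  double max_drift = 0.0;
  int acc_win = 0, win_n = 0;
  std::vector<int> perm(m);

  for (int cyc = 1; cyc <= n_cycles; ++cyc) {
    // ---- mean ----
    if (!prior_only && n_obs > 0) {
      double s = 0.0;
      for (int i = 0; i < n_obs; ++i) s += e[i] + mu;
      double mu_new = R::rnorm(s / n_obs, std::sqrt(se / n_obs));
      double d = mu_new - mu;
      for (int i = 0; i < n_obs; ++i) e[i] -= d;
      mu = mu_new;
    }

    // ---- polygenic single-site sweep (pedigree order) ----
    for (int j = 0; j < n_ind; ++j) {
      double S1 = 0.0, djj = 0.0;
      for (int idx = Ap[j]; idx < Ap[j + 1]; ++idx) {
        int i2 = Ai[idx];
        if (i2 == j) djj = Ax[idx];
        else S1 += Ax[idx] * a[i2];
      }
      double prec = djj / sa, rhs = -S1 / sa;
      if (!prior_only) {
        for (int idx = obs_ptr[j]; idx < obs_ptr[j + 1]; ++idx) {
          int o = obs_idx[idx];
          prec += 1.0 / se;
          rhs += (e[o] + a[j]) / se;
        }
      }
      double a_new = R::rnorm(rhs / prec, std::sqrt(1.0 / prec));
      if (!prior_only) {
        double d = a_new - a[j];
        for (int idx = obs_ptr[j]; idx < obs_ptr[j + 1]; ++idx)
          e[obs_idx[idx]] -= d;
      }
      a[j] = a_new;
    }

    // ---- SNP sweep: random disjoint pairs, marginalized indicators ----
    const double sg1 = ratio * sg0;
    for (int k = 0; k < m; ++k) perm[k] = k;
    for (int k = m - 1; k > 0; --k) {
      int r = (int) (unif_rand() * (k + 1));
      int t = perm[k]; perm[k] = perm[r]; perm[r] = t;
    }
    int kk = 0;
    const double lp1 = std::log(pi1), lp0 = std::log1p(-pi1);
    while (kk < m) {
      if (pair_upd && kk + 1 < m) {
        int k1 = perm[kk], k2 = perm[kk + 1];
        kk += 2;
        double x11 = xtx[k1], x22 = xtx[k2];
        double x12 = prior_only ? 0.0 : col_col_dot(X, k1, k2);
        double r1 = 0.0, r2 = 0.0;
        if (!prior_only) {
          r1 = col_dot(X, k1, e) + x11 * alpha[k1] + x12 * alpha[k2];
          r2 = col_dot(X, k2, e) + x12 * alpha[k1] + x22 * alpha[k2];
        }
        double lw[4], C11s[4], C22s[4], C12s[4], m1s[4], m2s[4];
        double lwmax = -INFINITY;
        for (int cfg = 0; cfg < 4; ++cfg) {
          int d1 = cfg & 1, d2 = (cfg >> 1) & 1;
          double v1 = d1 ? sg1 : sg0, v2 = d2 ? sg1 : sg0;
          double C11 = x11 / se + 1.0 / v1;
          double C22 = x22 / se + 1.0 / v2;
          double C12 = x12 / se;
          double det = C11 * C22 - C12 * C12;
          double b1 = r1 / se, b2 = r2 / se;
          double quad = (C22 * b1 * b1 - 2.0 * C12 * b1 * b2 + C11 * b2 * b2) / det;
          lw[cfg] = (d1 ? lp1 : lp0) + (d2 ? lp1 : lp0)
                  - 0.5 * (std::log(v1) + std::log(v2))
                  - 0.5 * std::log(det) + 0.5 * quad;
          C11s[cfg] = C11; C22s[cfg] = C22; C12s[cfg] = C12;
          m1s[cfg] = (C22 * b1 - C12 * b2) / det;
          m2s[cfg] = (C11 * b2 - C12 * b1) / det;
          if (lw[cfg] > lwmax) lwmax = lw[cfg];
        }
        double tot = 0.0, w[4];
        for (int cfg = 0; cfg < 4; ++cfg) { w[cfg] = std::exp(lw[cfg] - lwmax); tot += w[cfg]; }
        double u = unif_rand() * tot, cum = 0.0;
        int cfg = 3;
        for (int c2 = 0; c2 < 4; ++c2) { cum += w[c2]; if (u <= cum) { cfg = c2; break; } }
        // sample (alpha1, alpha2) ~ N(mean, C^{-1}) via Cholesky of C
        double U11 = std::sqrt(C11s[cfg]);
        double U12 = C12s[cfg] / U11;
        double U22 = std::sqrt(C22s[cfg] - U12 * U12);
        // solve U (x - mean) = z with U the upper Cholesky factor of C,
        // giving x ~ N(mean, C^{-1})
        double z1 = norm_rand(), z2 = norm_rand();
        double a2n = m2s[cfg] + z2 / U22;
        double a1n = m1s[cfg] + (z1 - U12 * (a2n - m2s[cfg])) / U11;
        sumdelta += (cfg & 1) - delta[k1] + ((cfg >> 1) & 1) - delta[k2];
        delta[k1] = cfg & 1; delta[k2] = (cfg >> 1) & 1;
        if (!prior_only) {
          double d1v = a1n - alpha[k1], d2v = a2n - alpha[k2];
          if (d1v != 0.0 || d2v != 0.0) {
            const double* c1 = &X(0, k1);
            const double* c2 = &X(0, k2);
            for (int i = 0; i < n_obs; ++i) {
              double ch = d1v * c1[i] + d2v * c2[i];
              e[i] -= ch;
              gsnp[i] += ch;
            }
          }
        }
        alpha[k1] = a1n; alpha[k2] = a2n;
      } else {
        int k1 = perm[kk]; kk += 1;
        double xkk = xtx[k1];
        double r = prior_only ? 0.0
                 : col_dot(X, k1, e) + xkk * alpha[k1];
        double lw[2], cs[2], ms[2];
        for (int d1 = 0; d1 < 2; ++d1) {
          double v = d1 ? sg1 : sg0;
          double c = xkk / se + 1.0 / v;
          double b = r / se;
          lw[d1] = (d1 ? lp1 : lp0) - 0.5 * std::log(v) - 0.5 * std::log(c)
                 + 0.5 * b * b / c;
          cs[d1] = c; ms[d1] = b / c;
        }
        double p1c = 1.0 / (1.0 + std::exp(lw[0] - lw[1]));
        int d1 = (unif_rand() < p1c) ? 1 : 0;
        double a1n = R::rnorm(ms[d1], std::sqrt(1.0 / cs[d1]));
        sumdelta += d1 - delta[k1];
        delta[k1] = d1;
        if (!prior_only) {
          double dv = a1n - alpha[k1];
          if (dv != 0.0) {
            const double* c1 = &X(0, k1);
            for (int i = 0; i < n_obs; ++i) { e[i] -= dv * c1[i]; gsnp[i] += dv * c1[i]; }
          }
        }
        alpha[k1] = a1n;
      }
    }

    // ---- mixture proportion ----
    pi1 = R::rbeta(beta_a + sumdelta, beta_b + (m - sumdelta));
    if (pi1 <= 1e-12) pi1 = 1e-12;
    if (pi1 >= 1.0 - 1e-12) pi1 = 1.0 - 1e-12;

    // ---- variance components ----
    {
      double Sa = 0.0;
      for (int j = 0; j < n_ind; ++j)
        for (int idx = Ap[j]; idx < Ap[j + 1]; ++idx)
          Sa += a[Ai[idx]] * Ax[idx] * a[j];
      sa = rtrunc_var_conditional(Sa, (double) n_ind, sa_lo, sa_hi);
      if (prior_only || n_obs == 0) {
        se = se_lo + unif_rand() * (se_hi - se_lo);
      } else {
        double Se = 0.0;
        for (int i = 0; i < n_obs; ++i) Se += e[i] * e[i];
        se = rtrunc_var_conditional(Se, (double) n_obs, se_lo, se_hi);
      }
    }

    // ---- MH joint rescale of mixture variances and all SNP effects ----
    int mh_acc = 0;
    {
      double uu = (2.0 * unif_rand() - 1.0) * step;
      double f = std::exp(uu);
      double sg0p = f * sg0;
      if (sg0p >= g0_lo && sg0p <= g0_hi) {
        double sf = std::sqrt(f);
        double dll = 0.0;
        if (!prior_only) {
          double sse_new = 0.0, sse_old = 0.0;
          for (int i = 0; i < n_obs; ++i) {
            double en = e[i] - (sf - 1.0) * gsnp[i];
            sse_new += en * en;
            sse_old += e[i] * e[i];
          }
          dll = -(sse_new - sse_old) / (2.0 * se);
        }
        // log acceptance = loglik ratio + log f
        // (Jacobian f^{1+m/2} times the alpha-prior ratio f^{-m/2}; the
        // bounded-uniform prior on sg0 contributes only the support check)
        if (std::log(unif_rand()) < dll + uu) {
          mh_acc = 1;
          sg0 = sg0p;
          for (int k = 0; k < m; ++k) alpha[k] *= sf;
          if (!prior_only)
            for (int i = 0; i < n_obs; ++i) {
              e[i] -= (sf - 1.0) * gsnp[i];
              gsnp[i] *= sf;
            }
        }
      }
      acc_win += mh_acc; win_n += 1;
      if (cyc > burn_in) { acc_post += mh_acc; n_post_mh += 1; }
      if (cyc <= burn_in && win_n >= tune_int) {
        double rate = (double) acc_win / win_n;
        step *= std::exp(rate - 0.5);
        if (step < 1e-3) step = 1e-3;
        if (step > 10.0) step = 10.0;
        acc_win = 0; win_n = 0;
      }
    }

    // ---- periodic residual recomputation (drift guard) ----
    if (!prior_only && recomp_int > 0 && cyc % recomp_int == 0) {
      for (int i = 0; i < n_obs; ++i) {
        double g = 0.0;
        for (int k = 0; k < m; ++k) g += X(i, k) * alpha[k];
        double en = y[i] - mu - a[obs_ind[i]] - g;
        double dr = std::fabs(en - e[i]);
        if (dr > max_drift) max_drift = dr;
        e[i] = en;
        gsnp[i] = g;
      }
    }

    // ---- accumulation & storage ----
    if (cyc > burn_in) {
      keep += 1;
      for (int k = 0; k < m; ++k) {
        p_hat[k] += delta[k];
        alpha_mean[k] += alpha[k];
      }
      for (int j = 0; j < n_ind; ++j) a_mean[j] += a[j];
      if ((cyc - burn_in) % thin == 0 && stored < n_store) {
        double vs = 0.0;
        if (!prior_only && n_obs > 1) {
          double gm = 0.0;
          for (int i = 0; i < n_obs; ++i) gm += gsnp[i];
          gm /= n_obs;
          for (int i = 0; i < n_obs; ++i) vs += (gsnp[i] - gm) * (gsnp[i] - gm);
          vs /= (n_obs - 1);
        }
        samples(stored, 0) = mu;
        samples(stored, 1) = sa;
        samples(stored, 2) = se;
        samples(stored, 3) = sg0;
        samples(stored, 4) = ratio * sg0;
        samples(stored, 5) = pi1;
        samples(stored, 6) = sumdelta;
        samples(stored, 7) = vs;
        samples(stored, 8) = step;
        samples(stored, 9) = mh_acc;
        ++stored;
      }
    }

    if (cyc % 2000 == 0) Rcpp::checkUserInterrupt();
    for (int i = 0; i < n_obs; ++i)
      if (!std::isfinite(e[i]))
        stop("non-finite residual at cycle %d; aborting", cyc);
  }

  if (keep > 0) {
    for (int k = 0; k < m; ++k) { p_hat[k] /= keep; alpha_mean[k] /= keep; }
    for (int j = 0; j < n_ind; ++j) a_mean[j] /= keep;
  }
  colnames(samples) = scnames;
  return List::create(
      _["samples"] = samples,
      _["p_hat"] = NumericVector(p_hat.begin(), p_hat.end()),
      _["alpha_mean"] = NumericVector(alpha_mean.begin(), alpha_mean.end()),
      _["a_mean"] = NumericVector(a_mean.begin(), a_mean.end()),
      _["mh_acceptance"] = n_post_mh > 0 ? acc_post / n_post_mh : NA_REAL,
      _["mh_step_final"] = step,
      _["max_residual_drift"] = max_drift,
      _["n_kept"] = (double) keep);
}
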