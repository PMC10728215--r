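#include <Rcpp.h>
using namespace Rcpp;

// Smoothed-trend (second-order random-walk) state-space model:
//   y_t  = mu_t + eps_t,                eps_t  ~ N(0, sig_eps^2)
//   mu_t = 2 mu_{t-1} - mu_{t-2} + zeta_t,  zeta_t ~ N(0, sig_zeta^2)
// State alpha_t = (mu_t, mu_{t-1})'.  Initial state approximately diffuse
// (large variance), so level and linear trend are absorbed by the
// initialisation rather than the disturbance variances.
//
// Sampling: adaptive random-walk Metropolis on (log sig_zeta, log sig_eps)
// against the Kalman-filter marginal likelihood; the latent trend is drawn
// for each retained parameter draw by backward conditional sampling from the
// filtered states.

static const double DIFFUSE_VAR = 1e7;
static const double LOG_SIG_MIN = -16.0;  // ~1.1e-7 on a unit-scale series
static const double LOG_SIG_MAX = 7.0;

struct FilterStore {
  std::vector<double> a0, a1;          // filtered mean
  std::vector<double> p00, p01, p11;   // filtered covariance
};

// Kalman filter; returns log-likelihood, optionally stores filtered moments.
static double kalman_loglik(const std::vector<double>& y,
                            double q, double h,  // q = sig_zeta^2, h = sig_eps^2
                            FilterStore* store) {
  const int T = (int)y.size();
  double a0 = y[0], a1 = y[0];
  double P00 = DIFFUSE_VAR, P01 = 0.0, P11 = DIFFUSE_VAR;
  double ll = 0.0;
  const double LOG2PI = 1.8378770664093453;
  for (int t = 0; t < T; ++t) {
    double ap0, ap1, Pp00, Pp01, Pp11;
    if (t == 0) {
      ap0 = a0; ap1 = a1; Pp00 = P00; Pp01 = P01; Pp11 = P11;
    } else {
      // alpha_pred = T alpha, T = [2 -1; 1 0]
      ap0 = 2.0 * a0 - a1;
      ap1 = a0;
      // P_pred = T P T' + R q R'
      Pp00 = 4.0 * P00 - 4.0 * P01 + P11 + q;
      Pp01 = 2.0 * P00 - P01;
      Pp11 = P00;
    }
    double v = y[t] - ap0;
    double F = Pp00 + h;
    ll += -0.5 * (LOG2PI + std::log(F) + v * v / F);
    double K0 = Pp00 / F, K1 = Pp01 / F;
    a0 = ap0 + K0 * v;
    a1 = ap1 + K1 * v;
    P00 = Pp00 - K0 * Pp00;
    P01 = Pp01 - K0 * Pp01;
    P11 = Pp11 - K1 * Pp01;
    if (store) {
      store->a0[t] = a0; store->a1[t] = a1;
      store->p00[t] = P00; store->p01[t] = P01; store->p11[t] = P11;
    }
  }
  return ll;
}

// Draw the latent trend mu_{1..T} given (q, h) by backward conditional
// sampling: joint normal draw of (mu_T, mu_{T-1}) from the filtered
// distribution, then mu_t | y_{1:t}, mu_{t+1}, mu_{t+2} for t = T-2 .. 1.
static void draw_states(const std::vector<double>& y, double q, double h,
                        const FilterStore& fs, std::vector<double>& mu) {
  const int T = (int)y.size();
  (void)h;
  double qq = std::max(q, 1e-20);
  // terminal joint draw
  {
    double P00 = fs.p00[T - 1], P01 = fs.p01[T - 1], P11 = fs.p11[T - 1];
    double jit = 1e-12 * (1.0 + P00 + P11);
    P00 += jit; P11 += jit;
    double L00 = std::sqrt(P00);
    double L10 = P01 / L00;
    double d = P11 - L10 * L10;
    double L11 = std::sqrt(d > 0 ? d : 0.0);
    double z0 = R::norm_rand(), z1 = R::norm_rand();
    mu[T - 1] = fs.a0[T - 1] + L00 * z0;
    mu[T - 2] = fs.a1[T - 1] + L10 * z0 + L11 * z1;
  }
  for (int t = T - 3; t >= 0; --t) {
    // filtered (mu_t, mu_{t-1}) ~ N(a, P); pseudo-observations from the
    // already-drawn future: mu_{t+1} = 2 mu_t - mu_{t-1} + zeta,
    // mu_{t+2} = 2 mu_{t+1} - mu_t + zeta.
    double P00 = fs.p00[t], P01 = fs.p01[t], P11 = fs.p11[t];
    double jit = 1e-12 * (1.0 + P00 + P11);
    P00 += jit; P11 += jit;
    double det = P00 * P11 - P01 * P01;
    double I00 = P11 / det, I01 = -P01 / det, I11 = P00 / det;
    double iq = 1.0 / qq;
    // c1 = (2,-1), c2 = (-1,0)
    double L00 = I00 + (4.0 + 1.0) * iq;   // 2*2 + (-1)*(-1)
    double L01 = I01 + (-2.0 + 0.0) * iq;  // 2*(-1) + (-1)*0
    double L11 = I11 + 1.0 * iq;
    double m1 = mu[t + 1];
    double m2 = mu[t + 2] - 2.0 * mu[t + 1];
    double b0 = I00 * fs.a0[t] + I01 * fs.a1[t] + (2.0 * m1 - m2) * iq;
    double b1 = I01 * fs.a0[t] + I11 * fs.a1[t] + (-m1) * iq;
    double detL = L00 * L11 - L01 * L01;
    double S00 = L11 / detL;   // (Lam^{-1})_{00}
    double mean0 = (L11 * b0 - L01 * b1) / detL;
    mu[t] = mean0 + std::sqrt(S00 > 0 ? S00 : 0.0) * R::norm_rand();
  }
}

static inline double log_post(const std::vector<double>& y,
                              double th_z, double th_e,
                              double s_z, double s_e) {
  double sz = std::exp(th_z), se = std::exp(th_e);
  double ll = kalman_loglik(y, sz * sz, se * se, nullptr);
  // half-normal priors on the SDs + log-scale Jacobian
  double lp = -0.5 * (sz * sz) / (s_z * s_z) + th_z
              -0.5 * (se * se) / (s_e * s_e) + th_e;
  return ll + lp;
}

// [[Rcpp::export]]
List trend_mcmc_cpp(NumericVector y_, int chains, int iter, int warmup,
                    double prior_scale_zeta, double prior_scale_eps,
                    NumericMatrix init_log_sigma, bool keep_states) {
  const int T = y_.size();
  std::vector<double> y(y_.begin(), y_.end());
  const int kept = iter - warmup;

  NumericMatrix sig_zeta(kept, chains), sig_eps(kept, chains);
  NumericVector accept(chains);
  List mu_draws(chains);

  FilterStore fs;
  fs.a0.resize(T); fs.a1.resize(T);
  fs.p00.resize(T); fs.p01.resize(T); fs.p11.resize(T);
  std::vector<double> mu(T);

  for (int c = 0; c < chains; ++c) {
    double th_z = init_log_sigma(c, 0), th_e = init_log_sigma(c, 1);
    double lp = log_post(y, th_z, th_e, prior_scale_zeta, prior_scale_eps);
    double step = 0.4;
    int n_acc = 0;
    NumericMatrix mu_c(keep_states ? kept : 0, keep_states ? T : 0);

    for (int i = 0; i < iter; ++i) {
      double pz = th_z + step * R::norm_rand();
      double pe = th_e + step * R::norm_rand();
      bool ok = pz > LOG_SIG_MIN && pz < LOG_SIG_MAX &&
                pe > LOG_SIG_MIN && pe < LOG_SIG_MAX;
      double acc_prob = 0.0;
      bool accepted = false;
      if (ok) {
        double lp_new = log_post(y, pz, pe, prior_scale_zeta, prior_scale_eps);
        double lr = lp_new - lp;
        acc_prob = lr >= 0 ? 1.0 : std::exp(lr);
        if (R::unif_rand() < acc_prob) {
          th_z = pz; th_e = pe; lp = lp_new;
          accepted = true;
        }
      }
      if (i < warmup) {
        // Robbins-Monro adaptation toward 30% acceptance
        step *= std::exp((acc_prob - 0.30) / std::sqrt(1.0 + i));
        step = std::min(std::max(step, 1e-3), 10.0);
      } else {
        int k = i - warmup;
        double sz = std::exp(th_z), se = std::exp(th_e);
        sig_zeta(k, c) = sz;
        sig_eps(k, c) = se;
        if (accepted) ++n_acc;
        if (keep_states) {
          kalman_loglik(y, sz * sz, se * se, &fs);
          draw_states(y, sz * sz, se * se, fs, mu);
          for (int t = 0; t < T; ++t) mu_c(k, t) = mu[t];
        }
      }
    }
    accept[c] = (double)n_acc / kept;
    if (keep_states) mu_draws[c] = mu_c;
  }

  return List::create(_["sigma_zeta"] = sig_zeta,
                      _["sigma_eps"] = sig_eps,
                      _["mu"] = mu_draws,
                      _["accept"] = accept);
}

// [[Rcpp::export]]
double trend_loglik_cpp(NumericVector y_, double sigma_zeta, double sigma_eps) {
  std::vector<double> y(y_.begin(), y_.end());
  return kalman_loglik(y, sigma_zeta * sigma_zeta, sigma_eps * sigma_eps,
                       nullptr);
}
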