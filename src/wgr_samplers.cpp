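#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs samplers for whole-genome regression on a centred
// marker matrix: y = 1*mu + X*beta + e.
//
// model codes: 0 = BRR (common Gaussian effect variance)
//              1 = BayesC (common Gaussian slab + point mass, prob pi)
//              2 = BayesB (per-marker scaled-inv-chi2 variance, i.e. a
//                  scaled-t slab, + point mass)
//              3 = BL (Bayesian LASSO, Park-Casella updates)
//
// All draws use R's RNG so a set.seed() in R makes chains bit-reproducible.

// inverse-Gaussian draw (Michael-Schucany-Haas)
static double rinvgauss(double mu, double lambda) {
  double v = norm_rand();
  double y = v * v;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
             (mu / (2.0 * lambda)) *
             std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0) x = 1e-12;
  double u = unif_rand();
  if (u <= mu / (mu + x)) return x;
  return mu * mu / x;
}

static double rscinvchisq(double df, double S) {
  // scaled-inverse-chi-square with df and scale-sum S: S / chi2_df
  return S / ::Rf_rchisq(df);
}

// [[Rcpp::export(name = ".wgr_gibbs_cpp")]]
List wgr_gibbs_cpp(NumericVector y, NumericMatrix X, int model,
                   int n_iter, int burn_in, int thin,
                   double df_e, double S_e, double df_b, double S_b,
                   double pi0, double pi_counts, bool sample_pi,
                   double bl_shape, double bl_rate,
                   bool update_varb, bool update_vare,
                   double sigb_init, double sige_init) {
  int n = y.size(), p = X.ncol();
  std::vector<double> x2(p);
  for (int j = 0; j < p; ++j) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    x2[j] = s;
  }

  double mu = mean(y);
  std::vector<double> beta(p, 0.0), tau2(p, 1.0), sigb_j(p, S_b / (df_b + 2.0));
  std::vector<int> delta(p, 1);
  double sige = sige_init, sigb = sigb_init, pi = pi0, lambda2 = 1.0;
  if (model == 3 && bl_rate > 0) lambda2 = (bl_shape - 1.0) / bl_rate;

  NumericVector e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  std::vector<double> beta_sum(p, 0.0), incl_sum(p, 0.0);
  double mu_sum = 0, sige_sum = 0, sigb_sum = 0, pi_sum = 0, lambda2_sum = 0;
  std::vector<double> sige_draws;
  int n_kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double se_ = 0;
    for (int i = 0; i < n; ++i) se_ += e[i] + mu;
    double mu_new = se_ / n + norm_rand() * std::sqrt(sige / n);
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    int m_in = 0;
    double ss_beta = 0, ss_beta_tau = 0;

    for (int j = 0; j < p; ++j) {
      double bold = beta[j];
      // rhs for the full conditional with marker j removed from e
      double xe = 0;
      for (int i = 0; i < n; ++i) xe += X(i, j) * e[i];
      double rhs = xe + x2[j] * bold;

      if (model == 0) {                       // BRR
        double C = x2[j] + sige / sigb;
        double bnew = rhs / C + norm_rand() * std::sqrt(sige / C);
        double d = bold - bnew;
        if (d != 0) for (int i = 0; i < n; ++i) e[i] += X(i, j) * d;
        beta[j] = bnew;
        ss_beta += bnew * bnew;
      } else if (model == 1 || model == 2) {  // BayesC / BayesB
        double vb = (model == 1) ? sigb : sigb_j[j];
        double lodds = std::log(pi) - std::log(1.0 - pi)
          - 0.5 * std::log1p(x2[j] * vb / sige)
          + rhs * rhs * vb / (2.0 * sige * (sige + x2[j] * vb));
        double pin = 1.0 / (1.0 + std::exp(-lodds));
        double bnew = 0.0;
        int din = (unif_rand() < pin) ? 1 : 0;
        if (din) {
          double C = x2[j] + sige / vb;
          bnew = rhs / C + norm_rand() * std::sqrt(sige / C);
        }
        double d = bold - bnew;
        if (d != 0) for (int i = 0; i < n; ++i) e[i] += X(i, j) * d;
        beta[j] = bnew;
        delta[j] = din;
        m_in += din;
        if (din) ss_beta += bnew * bnew;
        if (model == 2 && update_varb) {
          // per-marker variance: posterior when in, prior draw when out
          if (din) sigb_j[j] = rscinvchisq(df_b + 1.0, S_b + bnew * bnew);
          else     sigb_j[j] = rscinvchisq(df_b, S_b);
        }
      } else {                                // BL
        double C = x2[j] + 1.0 / tau2[j];
        double bnew = rhs / C + norm_rand() * std::sqrt(sige / C);
        double d = bold - bnew;
        if (d != 0) for (int i = 0; i < n; ++i) e[i] += X(i, j) * d;
        beta[j] = bnew;
        double b2 = bnew * bnew;
        if (b2 < 1e-12) b2 = 1e-12;
        double itau = rinvgauss(std::sqrt(lambda2 * sige / b2), lambda2);
        tau2[j] = 1.0 / itau;
        ss_beta_tau += b2 / tau2[j];
      }
    }

    // variance updates
    if (model == 0 && update_varb)
      sigb = rscinvchisq(df_b + p, S_b + ss_beta);
    if (model == 1 && update_varb)
      sigb = rscinvchisq(df_b + m_in, S_b + ss_beta);
    if ((model == 1 || model == 2) && sample_pi) {
      double a = pi_counts * pi0, b = pi_counts * (1.0 - pi0);
      pi = ::Rf_rbeta(m_in + a, p - m_in + b);
      if (pi < 1e-6) pi = 1e-6;
      if (pi > 1.0 - 1e-6) pi = 1.0 - 1e-6;
    }
    if (model == 3) {
      double sumtau = 0;
      for (int j = 0; j < p; ++j) sumtau += tau2[j];
      lambda2 = ::Rf_rgamma(bl_shape + p, 1.0 / (bl_rate + 0.5 * sumtau));
    }
    if (update_vare) {
      double sse = 0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      if (model == 3)  // beta prior is scaled by sige under Park-Casella
        sige = rscinvchisq(df_e + n + p, S_e + sse + ss_beta_tau);
      else
        sige = rscinvchisq(df_e + n, S_e + sse);
    }

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      ++n_kept;
      mu_sum += mu; sige_sum += sige; sigb_sum += sigb;
      pi_sum += pi; lambda2_sum += lambda2;
      sige_draws.push_back(sige);
      for (int j = 0; j < p; ++j) {
        beta_sum[j] += beta[j];
        incl_sum[j] += (model == 1 || model == 2) ? delta[j] : 1;
      }
    }
  }

  NumericVector bhat(p), pip(p);
  for (int j = 0; j < p; ++j) {
    bhat[j] = beta_sum[j] / n_kept;
    pip[j] = incl_sum[j] / n_kept;
  }
  return List::create(
    _["mu"] = mu_sum / n_kept,
    _["beta"] = bhat,
    _["pip"] = pip,
    _["sige"] = sige_sum / n_kept,
    _["sigb"] = sigb_sum / n_kept,
    _["pi"] = pi_sum / n_kept,
    _["lambda2"] = lambda2_sum / n_kept,
    _["sige_draws"] = wrap(sige_draws),
    _["n_kept"] = n_kept);
}
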