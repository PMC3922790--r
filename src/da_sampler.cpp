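#include <Rcpp.h>
using namespace Rcpp;

// Bernoulli-logistic log-likelihood of y given linear predictor eta.
static double bern_loglik(const std::vector<double>& eta,
                          const std::vector<int>& y) {
  double ll = 0.0;
  const int n = eta.size();
  for (int i = 0; i < n; ++i) {
    ll += (y[i] == 1) ? -std::log1p(std::exp(-eta[i]))
                      : -std::log1p(std::exp(eta[i]));
  }
  return ll;
}

static inline double plogis_d(double eta) {
  return 1.0 / (1.0 + std::exp(-eta));
}

// One componentwise adaptive random-walk Metropolis sweep over the
// coefficients of a Bernoulli-logistic model with independent normal priors.
// eta and ll are updated in place; log step sizes adapt toward the target
// acceptance rate while `adapt` is true (burn-in only, so the post burn-in
// kernel is a fixed, valid Metropolis transition).
static void rw_sweep(std::vector<double>& coef, std::vector<double>& eta,
                     double& ll, const double* X, int n, int p,
                     const std::vector<double>& pr_mean,
                     const std::vector<double>& pr_sd,
                     const std::vector<int>& y,
                     std::vector<double>& log_step, bool adapt,
                     double adapt_gamma, double target,
                     std::vector<double>& scratch, long* n_prop, long* n_acc) {
  for (int j = 0; j < p; ++j) {
    const double delta = norm_rand() * std::exp(log_step[j]);
    const double* xj = X + (size_t)j * n;
    for (int i = 0; i < n; ++i) scratch[i] = eta[i] + xj[i] * delta;
    const double ll_prop = bern_loglik(scratch, y);
    const double cur = coef[j], prop = coef[j] + delta;
    const double lp_diff =
      (-0.5 * (prop - pr_mean[j]) * (prop - pr_mean[j]) +
        0.5 * (cur - pr_mean[j]) * (cur - pr_mean[j])) /
      (pr_sd[j] * pr_sd[j]);
    const double log_ratio = ll_prop - ll + lp_diff;
    bool accept = std::log(unif_rand()) < log_ratio;
    if (accept) {
      coef[j] = prop;
      std::swap(eta, scratch);
      ll = ll_prop;
    }
    if (adapt) log_step[j] += adapt_gamma * ((accept ? 1.0 : 0.0) - target);
    ++(*n_prop);
    if (accept) ++(*n_acc);
  }
}

// One MCMC chain of the data-augmentation sampler for the joint
// misclassification model: an exact Gibbs draw of each record's latent true
// exposure from its full conditional, followed by random-walk Metropolis
// sweeps over the exposure-model coefficients (alpha) and the outcome-model
// coefficients (beta). Xb's column `ex_col` (0-based) carries the latent
// exposure and is managed internally; `reported` initializes it. When
// `update_latent` is false the latent vector stays equal to `reported` and
// the exposure model is not sampled (the naive Bayesian logistic model).
// Uses R's RNG, so the chain is reproducible under set.seed().
// [[Rcpp::export]]
List da_chain_cpp(NumericMatrix Xa, NumericMatrix Xb, int ex_col,
                  IntegerVector y, IntegerVector reported,
                  NumericVector se, NumericVector fpp,
                  NumericVector a_mean, NumericVector a_sd,
                  NumericVector b_mean, NumericVector b_sd,
                  NumericVector alpha_init, NumericVector beta_init,
                  int n_iter, int n_burnin, int thin,
                  double accept_target, bool update_latent) {
  const int n = Xb.nrow(), pa = Xa.ncol(), pb = Xb.ncol();
  if (n_burnin >= n_iter) stop("burn-in must be smaller than the iteration count");
  if (ex_col < 0 || ex_col >= pb) stop("invalid exposure column index");

  std::vector<double> alpha(alpha_init.begin(), alpha_init.end());
  std::vector<double> beta(beta_init.begin(), beta_init.end());
  std::vector<int> x(reported.begin(), reported.end());

  // column-major copies for cache-friendly component updates
  std::vector<double> XaC(Xa.begin(), Xa.end());
  std::vector<double> XbC(Xb.begin(), Xb.end());
  double* xb_ex = XbC.data() + (size_t)ex_col * n;
  for (int i = 0; i < n; ++i) xb_ex[i] = (double)x[i];

  std::vector<double> am(a_mean.begin(), a_mean.end()),
      as(a_sd.begin(), a_sd.end()), bm(b_mean.begin(), b_mean.end()),
      bs(b_sd.begin(), b_sd.end());
  std::vector<int> yv(y.begin(), y.end());

  std::vector<double> eta_a(n, 0.0), eta_b(n, 0.0), scratch(n);
  for (int i = 0; i < n; ++i) {
    double sa = 0.0, sb = 0.0;
    for (int j = 0; j < pa; ++j) sa += XaC[(size_t)j * n + i] * alpha[j];
    for (int j = 0; j < pb; ++j) sb += XbC[(size_t)j * n + i] * beta[j];
    eta_a[i] = sa;
    eta_b[i] = sb;
  }

  std::vector<double> ls_a(pa, std::log(0.2)), ls_b(pb, std::log(0.2));
  const int n_keep = (n_iter - n_burnin) / thin;
  NumericMatrix alpha_draws(n_keep, pa), beta_draws(n_keep, pb);
  NumericVector latent_mean(n);
  long prop_a = 0, acc_a = 0, prop_b = 0, acc_b = 0;
  int kept = 0;

  RNGScope rng;
  for (int it = 1; it <= n_iter; ++it) {
    const bool burn = it <= n_burnin;
    const double gamma = std::min(0.5, 1.0 / std::sqrt((double)it));

    if (update_latent) {
      // exact Gibbs draw of each latent exposure from its full conditional:
      // P(X=1 | X*, Y, C) proportional to P(X*|X=1,Y) P(Y|X=1,C) P(X=1|C)
      const double bx = beta[ex_col];
      for (int i = 0; i < n; ++i) {
        const double la = plogis_d(eta_a[i]);
        const double eta0 = eta_b[i] - bx * x[i];
        const double p1c = plogis_d(eta0 + bx), p0c = plogis_d(eta0);
        const double py1 = (yv[i] == 1) ? p1c : 1.0 - p1c;
        const double py0 = (yv[i] == 1) ? p0c : 1.0 - p0c;
        const double m1 = (reported[i] == 1) ? se[i] : 1.0 - se[i];
        const double m0 = (reported[i] == 1) ? fpp[i] : 1.0 - fpp[i];
        const double f1 = m1 * py1 * la, f0 = m0 * py0 * (1.0 - la);
        const double p = (f1 + f0 > 0.0) ? f1 / (f1 + f0) : la;
        const int xn = (unif_rand() < p) ? 1 : 0;
        x[i] = xn;
        xb_ex[i] = (double)xn;
        eta_b[i] = eta0 + bx * xn;
      }

      double ll_a = bern_loglik(eta_a, x);
      rw_sweep(alpha, eta_a, ll_a, XaC.data(), n, pa, am, as, x, ls_a,
               burn, gamma, accept_target, scratch, &prop_a, &acc_a);
    }

    double ll_b = bern_loglik(eta_b, yv);
    rw_sweep(beta, eta_b, ll_b, XbC.data(), n, pb, bm, bs, yv, ls_b,
             burn, gamma, accept_target, scratch, &prop_b, &acc_b);

    if (!burn && ((it - n_burnin) % thin == 0)) {
      for (int j = 0; j < pa; ++j) alpha_draws(kept, j) = alpha[j];
      for (int j = 0; j < pb; ++j) beta_draws(kept, j) = beta[j];
      for (int i = 0; i < n; ++i) latent_mean[i] += x[i];
      ++kept;
    }
  }
  if (kept > 0) {
    for (int i = 0; i < n; ++i) latent_mean[i] /= kept;
  }
  return List::create(
      _["alpha"] = alpha_draws, _["beta"] = beta_draws,
      _["latent_mean"] = latent_mean,
      _["accept_alpha"] = prop_a > 0 ? (double)acc_a / prop_a : NA_REAL,
      _["accept_beta"] = prop_b > 0 ? (double)acc_b / prop_b : NA_REAL);
}
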