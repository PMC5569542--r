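#include <Rcpp.h>
using namespace Rcpp;

// Spike-and-slab Gibbs chain for the Bayes-C model
//   y = 1 mu + M Q q + e,  q_j ~ N(0, sigma2_q) w.p. pi, else 0.
//
// Single-site updates in fixed ascending SNP order; the running residual
// e = y - 1 mu - M q is maintained by add-back/subtract, and each SNP's
// right-hand side m_j'e is recomputed every sweep. Uses R's RNG so
// set.seed() gives bit-reproducible chains. Optionally samples sigma2_q
// and sigma2_e from their scaled-inverse-chi-square full conditionals.
//
// Returns posterior means of q, inclusion frequencies, the intercept, the
// per-SNP Monte-Carlo standard errors of q, and the kept-sample count.
//
// [[Rcpp::export]]
List bayesc_chain_cpp(const NumericMatrix& M, const NumericVector& y,
                      double pi, double sigma2_e0, double sigma2_q0,
                      int n_iter, int burn_in, int thin,
                      bool sample_variances, double nu_q, double nu_e) {
  const int n = M.nrow(), m = M.ncol();
  NumericVector mtm(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += M(i, j) * M(i, j);
    mtm[j] = s;
  }
  double sigma2_e = sigma2_e0, sigma2_q = sigma2_q0;
  // prior scales chosen so the prior mode sits at the supplied variances
  const double S_q = sigma2_q0 * (nu_q + 2.0) / nu_q;
  const double S_e = sigma2_e0 * (nu_e + 2.0) / nu_e;
  const bool always_in = pi >= 1.0;
  const double log_prior_odds = always_in ? 0.0 : std::log(pi / (1.0 - pi));

  double mu = mean(y);
  NumericVector q(m, 0.0), e = clone(y);
  for (int i = 0; i < n; ++i) e[i] -= mu;

  NumericVector q_sum(m, 0.0), q_ssq(m, 0.0), incl_sum(m, 0.0);
  double mu_sum = 0.0;
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // intercept: flat prior, Gaussian full conditional
    double ebar = mean(e);
    double mu_new = mu + ebar + norm_rand() * std::sqrt(sigma2_e / n);
    for (int i = 0; i < n; ++i) e[i] -= (mu_new - mu);
    mu = mu_new;

    const double lambda = sigma2_e / sigma2_q;
    int n_in = 0;
    double ssq_in = 0.0;
    for (int j = 0; j < m; ++j) {
      const double* mj = &M(0, j);
      double dot = 0.0;
      for (int i = 0; i < n; ++i) dot += mj[i] * e[i];
      const double rhs = dot + mtm[j] * q[j];
      const double denom = mtm[j] + lambda;
      const double logbf = 0.5 * std::log(lambda / denom)
        + 0.5 * rhs * rhs / (sigma2_e * denom);
      double qnew;
      bool incl;
      if (always_in) {
        incl = true;
      } else {
        const double lo = log_prior_odds + logbf;
        const double p1 = (lo > 0) ? 1.0 / (1.0 + std::exp(-lo))
                                   : std::exp(lo) / (1.0 + std::exp(lo));
        incl = unif_rand() < p1;
      }
      if (incl) {
        qnew = rhs / denom + norm_rand() * std::sqrt(sigma2_e / denom);
        ++n_in;
        ssq_in += qnew * qnew;
      } else {
        qnew = 0.0;
      }
      const double dq = qnew - q[j];
      if (dq != 0.0)
        for (int i = 0; i < n; ++i) e[i] -= mj[i] * dq;
      q[j] = qnew;
      if (it > burn_in && (it - burn_in) % thin == 0)
        if (incl) incl_sum[j] += 1.0;
    }

    if (sample_variances) {
      sigma2_q = (ssq_in + nu_q * S_q) / R::rchisq(nu_q + n_in);
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      sigma2_e = (sse + nu_e * S_e) / R::rchisq(nu_e + n);
    }

    if (it > burn_in && (it - burn_in) % thin == 0) {
      ++kept;
      mu_sum += mu;
      for (int j = 0; j < m; ++j) {
        q_sum[j] += q[j];
        q_ssq[j] += q[j] * q[j];
      }
    }
  }

  NumericVector q_hat(m), mcse(m), incl(m);
  for (int j = 0; j < m; ++j) {
    q_hat[j] = q_sum[j] / kept;
    incl[j] = incl_sum[j] / kept;
    double v = (q_ssq[j] - kept * q_hat[j] * q_hat[j]) / (kept - 1.0);
    mcse[j] = std::sqrt(std::max(v, 0.0) / kept);
  }
  return List::create(_["q_hat"] = q_hat, _["inclusion_prob"] = incl,
                      _["mu_hat"] = mu_sum / kept, _["q_mcse"] = mcse,
                      _["n_samples_kept"] = kept);
}
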