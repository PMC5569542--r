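#include <Rcpp.h>
using namespace Rcpp;

// One full iterative-conditional-expectation sweep over the SNP effects.
//
// For each SNP j (fixed ascending order) the residual e is adjusted back
// to y* = e + m_j q_j, the log likelihood ratio for a large effect is
//   log(LR_j) = 1/2 log(lambda) - 1/2 log(m'm + lambda)
//             + 1/2 ((m'y*)^2 + m'PEVm) / sigma2_e / (m'm + lambda),
// the posterior probability follows from prior odds exp(log_ppr), and the
// new effect is PostProb * m'y* / (m'm + lambda). e is maintained
// incrementally. q and e are updated in place (they are duplicated on the
// R side before the call).
//
// [[Rcpp::export]]
List ice_sweep_cpp(const NumericMatrix& M, NumericVector e, NumericVector q,
                   const NumericVector& mtm, const NumericVector& pevq,
                   double lambda, double sigma2_e, double log_ppr) {
  const int n = M.nrow(), m = M.ncol();
  NumericVector postprob(m), loglr(m);
  double max_dq = 0.0;
  for (int j = 0; j < m; ++j) {
    const double* mj = &M(0, j);
    double dot = 0.0;
    for (int i = 0; i < n; ++i) dot += mj[i] * e[i];
    const double mty = dot + mtm[j] * q[j];   // m_j' y*
    const double denom = mtm[j] + lambda;
    const double llr = 0.5 * std::log(lambda) - 0.5 * std::log(denom)
      + 0.5 * (mty * mty + pevq[j]) / sigma2_e / denom;
    const double lo = log_ppr + llr;
    const double pp = (lo > 0) ? 1.0 / (1.0 + std::exp(-lo))
                               : std::exp(lo) / (1.0 + std::exp(lo));
    const double qnew = pp * mty / denom;
    const double dq = qnew - q[j];
    if (dq != 0.0)
      for (int i = 0; i < n; ++i) e[i] -= mj[i] * dq;
    if (std::fabs(dq) > max_dq) max_dq = std::fabs(dq);
    q[j] = qnew;
    postprob[j] = pp;
    loglr[j] = llr;
  }
  return List::create(_["q"] = q, _["e"] = e, _["postprob"] = postprob,
                      _["loglr"] = loglr, _["max_dq"] = max_dq);
}
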