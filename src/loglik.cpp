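#include <Rcpp.h>
using namespace Rcpp;

// Grid log-likelihood for the per-locus binomial mixture:
//   L_i(tf) = rho_i * Binom(k_i; n_i, clamp(tf * e_i + eps_i))
//           + (1 - rho_i) * Binom(k_i; n_i, clamp(eps_i))
// summed in log space over loci for every grid value of tf.
// The estimator evaluates this for hundreds of grid points times
// thousands of loci per sample, so the inner loop lives here; the k = 0
// majority of cells skips the k*log(p) term and the log-sum-exp is
// skipped once one mixture branch is more than 40 nats below the other.
// [[Rcpp::export]]
NumericVector cpp_grid_loglik(NumericVector tf, IntegerVector k, IntegerVector n,
                              NumericVector eps, NumericVector eff,
                              NumericVector rho) {
  const double PMIN = 1e-12, PMAX = 1.0 - 1e-12;
  const int G = tf.size(), D = k.size();
  std::vector<double> lc(D), lb(D), lrho(D), l1mrho(D);
  for (int i = 0; i < D; ++i) {
    lc[i] = R::lchoose((double)n[i], (double)k[i]);
    double pe = std::min(std::max(eps[i], PMIN), PMAX);
    lb[i] = lc[i] + k[i] * std::log(pe) + (n[i] - k[i]) * std::log1p(-pe);
    lrho[i]   = rho[i] > 0.0 ? std::log(rho[i])   : R_NegInf;
    l1mrho[i] = rho[i] < 1.0 ? std::log1p(-rho[i]) : R_NegInf;
  }
  NumericVector out(G);
  std::vector<double> acc(G, 0.0);
  for (int i = 0; i < D; ++i) {
    const double ki = k[i], nki = n[i] - k[i], effi = eff[i], epsi = eps[i];
    const double lci = lc[i], lbi = lb[i], lr = lrho[i], l1r = l1mrho[i];
    for (int g = 0; g < G; ++g) {
      double p = tf[g] * effi + epsi;
      p = std::min(std::max(p, PMIN), PMAX);
      double la = lci + nki * std::log1p(-p);
      if (ki > 0) la += ki * std::log(p);
      double t1 = lr + la, t2 = l1r + lbi;
      double hi = t1 > t2 ? t1 : t2, lo = t1 > t2 ? t2 : t1;
      if (hi == R_NegInf) { acc[g] = R_NegInf; continue; }
      double d = lo - hi;
      acc[g] += (d < -40.0) ? hi : hi + std::log1p(std::exp(d));
    }
  }
  for (int g = 0; g < G; ++g) out[g] = acc[g];
  return out;
}
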