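#include <Rcpp.h>
using namespace Rcpp;

// Soft-thresholding operator: proximal map of the L1 penalty.
inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Cyclic coordinate descent for the Gaussian elastic net, Gram ("covariance")
// formulation, over a (decreasing) lambda path with warm starts.
//
// Minimizes, for centered X and y,
//   (1/2n) * ||y - X b||^2 + lambda * (alpha * ||b||_1 + (1-alpha)/2 * ||b||_2^2)
// given G = X'X / n and c = X'y / n.  A zero-variance column (G_jj = 0, no
// ridge term) keeps its coefficient at exactly zero.
//
// [[Rcpp::export]]
List cd_enet_gram(const NumericMatrix& G, const NumericVector& c,
                  const NumericVector& lambdas, double alpha,
                  double tol, int max_sweeps, NumericVector beta_init) {
  const int p = c.size();
  const int nl = lambdas.size();
  NumericVector beta = clone(beta_init);
  std::vector<double> gb(p, 0.0);  // running G %*% beta
  for (int j = 0; j < p; ++j) {
    if (beta[j] != 0.0) {
      for (int k = 0; k < p; ++k) gb[k] += G(k, j) * beta[j];
    }
  }
  NumericMatrix betas(p, nl);
  IntegerVector sweeps(nl);
  LogicalVector conv(nl);

  for (int l = 0; l < nl; ++l) {
    const double lam = lambdas[l];
    const double la = lam * alpha;
    const double lr = lam * (1.0 - alpha);
    int s = 0;
    bool ok = false;
    while (s < max_sweeps) {
      ++s;
      double maxd = 0.0;
      for (int j = 0; j < p; ++j) {
        const double denom = G(j, j) + lr;
        double bj;
        if (denom <= 0.0) {
          bj = 0.0;
        } else {
          const double z = c[j] - gb[j] + G(j, j) * beta[j];
          bj = soft(z, la) / denom;
        }
        const double d = bj - beta[j];
        if (d != 0.0) {
          beta[j] = bj;
          for (int k = 0; k < p; ++k) gb[k] += d * G(k, j);
          const double ad = d < 0.0 ? -d : d;
          if (ad > maxd) maxd = ad;
        }
      }
      if (maxd <= tol) { ok = true; break; }
    }
    for (int j = 0; j < p; ++j) betas(j, l) = beta[j];
    sweeps[l] = s;
    conv[l] = ok;
  }
  return List::create(_["beta"] = betas,
                      _["sweeps"] = sweeps,
                      _["converged"] = conv);
}
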