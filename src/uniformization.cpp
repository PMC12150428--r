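#include <Rcpp.h>
using namespace Rcpp;

// Uniformized action of the matrix exponential for the projected master
// equation: computes w = exp(A * tau) v as
//
//   w = sum_{k=0}^{K} Pois(k; Lambda*tau) P^k v,   P = I + A / Lambda,
//
// where Lambda >= max_j |A_jj| makes P (sub)stochastic, so every term is
// nonnegative and no cancellation occurs. The series is truncated at the
// Poisson quantile K = Q(1 - tol; Lambda*tau); the discarded tail mass is
// at most tol in l1 norm because ||P^k v||_1 <= ||v||_1.
//
// P is passed in compressed sparse column form (dgCMatrix slots).
//
// [[Rcpp::export]]
NumericVector unif_expv_cpp(IntegerVector Pi, IntegerVector Pp, NumericVector Px,
                            NumericVector v, double lt, double tol) {
  const int n = v.size();
  NumericVector out(n);
  if (lt <= 0.0) {
    for (int i = 0; i < n; ++i) out[i] = v[i];
    return out;
  }
  const int kmax = static_cast<int>(R::qpois(1.0 - tol, lt, 1, 0)) + 2;

  std::vector<double> w(n), vk(n), vnext(n);
  const double p0 = R::dpois(0.0, lt, 0);
  for (int i = 0; i < n; ++i) {
    vk[i] = v[i];
    w[i] = p0 * v[i];
  }
  const int *pi = INTEGER(Pi);
  const int *pp = INTEGER(Pp);
  const double *px = REAL(Px);

  for (int k = 1; k <= kmax; ++k) {
    std::fill(vnext.begin(), vnext.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      const double vj = vk[j];
      if (vj == 0.0) continue;
      const int end = pp[j + 1];
      for (int idx = pp[j]; idx < end; ++idx) vnext[pi[idx]] += px[idx] * vj;
    }
    vk.swap(vnext);
    const double pk = R::dpois(static_cast<double>(k), lt, 0);
    if (pk > 0.0)
      for (int i = 0; i < n; ++i) w[i] += pk * vk[i];
    if ((k & 255) == 0) Rcpp::checkUserInterrupt();
  }
  for (int i = 0; i < n; ++i) out[i] = w[i];
  return out;
}
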