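#include <Rcpp.h>
using namespace Rcpp;

// Adam update applied leaf-by-leaf over flat lists of parameter, moment and
// gradient vectors (the depth-first leaves of the parameter tree).  The
// parameter and moment vectors are updated in place, so the parameter tree
// sharing those vectors advances without any per-step copying; the caller
// guarantees exclusive ownership.  wflag marks weight-matrix leaves, which
// receive L2 weight decay 2*l2*w.
// [[Rcpp::export(rng = false)]]
void adam_update_leaves(List p, List m, List v, List g, NumericVector wflag,
                        double lr, double l2, double beta1, double beta2,
                        double eps, int t) {
  const int K = p.size();
  if (m.size() != K || v.size() != K || g.size() != K || wflag.size() != K)
    stop("adam_update_leaves: leaf count mismatch");
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  for (int k = 0; k < K; ++k) {
    NumericVector pk = p[k], mk = m[k], vk = v[k], gk = g[k];
    const R_xlen_t n = pk.size();
    if (mk.size() != n || vk.size() != n || gk.size() != n)
      stop("adam_update_leaves: leaf length mismatch at leaf %d", k + 1);
    const double wd = 2.0 * l2 * wflag[k];
    for (R_xlen_t i = 0; i < n; ++i) {
      const double gi = gk[i] + wd * pk[i];
      const double mi = beta1 * mk[i] + (1.0 - beta1) * gi;
      const double vi = beta2 * vk[i] + (1.0 - beta2) * gi * gi;
      mk[i] = mi;
      vk[i] = vi;
      pk[i] -= lr * (mi / bc1) / (std::sqrt(vi / bc2) + eps);
    }
  }
}
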