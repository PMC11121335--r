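#include <Rcpp.h>
using namespace Rcpp;

// SMO-style pairwise coordinate descent on the linear eps-SVR dual in
// beta = alpha - alpha*:
//
//   min  0.5 * beta' K beta + eps * ||beta||_1 - y' beta
//   s.t. sum(beta) = 0,  -C <= beta_i <= C
//
// Each step picks the maximally KKT-violating pair (i, j), then solves the
// 1-D piecewise-quadratic subproblem along (e_i - e_j) exactly (candidate
// points: interval ends, the two L1 kinks, and the unconstrained minimizer
// under each effective L1 slope).
//
// [[Rcpp::export]]
List svr_smo_cpp(NumericMatrix K, NumericVector y, double C, double eps,
                 double tol, int max_iter) {
  const int n = y.size();
  std::vector<double> beta(n, 0.0), Kb(n, 0.0);
  int it = 0;
  bool converged = false;

  for (it = 0; it < max_iter; ++it) {
    // KKT scores: cost of increasing (up) / decreasing (dn) each beta_i
    int i1 = -1, i2 = -1, j1 = -1, j2 = -1; // best and second-best indices
    double u1 = R_PosInf, u2 = R_PosInf, d1 = R_PosInf, d2 = R_PosInf;
    for (int k = 0; k < n; ++k) {
      double g = Kb[k] - y[k];
      double up = (beta[k] >= C) ? R_PosInf
                                 : g + (beta[k] >= 0 ? eps : -eps);
      double dn = (beta[k] <= -C) ? R_PosInf
                                  : -g + (beta[k] <= 0 ? eps : -eps);
      if (up < u1) { u2 = u1; i2 = i1; u1 = up; i1 = k; }
      else if (up < u2) { u2 = up; i2 = k; }
      if (dn < d1) { d2 = d1; j2 = j1; d1 = dn; j1 = k; }
      else if (dn < d2) { d2 = dn; j2 = k; }
    }
    int i = i1, j = j1;
    if (i == j) { // best off-diagonal pair
      if (i2 >= 0 && (j2 < 0 || u2 + d1 <= u1 + d2)) i = i2;
      else j = j2;
    }
    if (i < 0 || j < 0) { converged = true; break; }
    double viol = -((i == i1 ? u1 : u2) + (j == j1 ? d1 : d2));
    if (!R_finite(viol) || viol < tol) { converged = true; break; }

    double lo = std::max(-C - beta[i], beta[j] - C);
    double hi = std::min(C - beta[i], beta[j] + C);
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    double lin = Kb[i] - Kb[j] - y[i] + y[j];

    std::vector<double> cand;
    cand.push_back(lo);
    cand.push_back(hi);
    cand.push_back(-beta[i]);
    cand.push_back(beta[j]);
    if (eta > 0) {
      for (int s = -1; s <= 1; ++s)
        cand.push_back((-lin - 2.0 * s * eps) / eta);
    }
    double best_d = 0.0, best_v = 0.0;
    for (size_t c = 0; c < cand.size(); ++c) {
      double d = std::min(hi, std::max(lo, cand[c]));
      double v = 0.5 * eta * d * d + lin * d +
                 eps * (std::fabs(beta[i] + d) + std::fabs(beta[j] - d) -
                        std::fabs(beta[i]) - std::fabs(beta[j]));
      if (v < best_v) { best_v = v; best_d = d; }
    }
    if (best_d == 0.0) { converged = true; break; }
    beta[i] += best_d;
    beta[j] -= best_d;
    for (int k = 0; k < n; ++k) Kb[k] += best_d * (K(k, i) - K(k, j));
  }

  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["iterations"] = it,
                      _["converged"] = converged);
}
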