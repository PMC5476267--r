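// Hot inner loops of the KL-NMF multiplicative updates. All protocol
// logic (restart selection, seeded initialization, configuration) stays
// in R; these functions only iterate the update rules
//   W <- W .* ((V ./ WH) H^T) ./ (1 H^T)
//   H <- H .* (W^T (V ./ WH)) ./ (W^T 1)
// with a 1e-12 floor inside divisions, tracking the generalized KL
// divergence D(V || WH) for the trace and the relative-change stop rule.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double EPS = 1e-12;

static inline void floor_eps(mat& M) {
  M.for_each([](double& x) { if (x < EPS) x = EPS; });
}

static inline vec floored(vec v) {
  v.for_each([](double& x) { if (x < EPS) x = EPS; });
  return v;
}

// KL divergence given WH and the V-dependent constants:
// D = C + sum(WH) - sum_{V>0} V log(WH)
static inline double kl_eval(const vec& vpos, const uvec& pos, double C,
                             const mat& WH) {
  return C + accu(WH) - dot(vpos, log(WH.elem(pos)));
}

// [[Rcpp::export(name = ".cppNmfDecomposeLoop")]]
Rcpp::List nmf_decompose_loop(const arma::mat& V, arma::mat W, arma::mat H,
                              int maxIter, double tol) {
  uvec pos = find(V > 0);
  vec vpos = V.elem(pos);
  double C = dot(vpos, log(vpos)) - accu(V);
  std::vector<double> trace;
  trace.reserve(maxIter);
  double prev = datum::inf;

  mat WH = W * H;
  floor_eps(WH);
  for (int it = 0; it < maxIter; ++it) {
    W %= (V / WH) * H.t();
    W.each_row() /= floored(sum(H, 1)).t();
    WH = W * H;
    floor_eps(WH);
    H %= W.t() * (V / WH);
    H.each_col() /= floored(sum(W, 0).t());
    WH = W * H;
    floor_eps(WH);
    double kl = kl_eval(vpos, pos, C, WH);
    trace.push_back(kl);
    if (std::isfinite(prev) && std::isfinite(kl) &&
        std::abs(prev - kl) <= tol * std::max(std::abs(prev), EPS)) {
      break;
    }
    prev = kl;
  }
  return Rcpp::List::create(Rcpp::Named("W") = W, Rcpp::Named("H") = H,
                            Rcpp::Named("trace") = trace);
}

// [[Rcpp::export(name = ".cppNmfInferLoop")]]
Rcpp::List nmf_infer_loop(const arma::mat& V, const arma::mat& W,
                          arma::mat H, int maxIter, double tol,
                          int traceEvery) {
  uvec pos = find(V > 0);
  vec vpos = V.elem(pos);
  double C = dot(vpos, log(vpos)) - accu(V);
  vec colW = floored(sum(W, 0).t());
  std::vector<double> trace;
  double prev = datum::inf;

  for (int it = 1; it <= maxIter; ++it) {
    mat WH = W * H;
    floor_eps(WH);
    H %= W.t() * (V / WH);
    H.each_col() /= colW;
    if (it % traceEvery == 0 || it == maxIter) {
      mat WH2 = W * H;
      floor_eps(WH2);
      double kl = kl_eval(vpos, pos, C, WH2);
      trace.push_back(kl);
      if (std::isfinite(prev) && std::isfinite(kl) &&
          std::abs(prev - kl) <= tol * std::max(std::abs(prev), EPS)) {
        break;
      }
      prev = kl;
    }
  }
  return Rcpp::List::create(Rcpp::Named("H") = H,
                            Rcpp::Named("trace") = trace);
}
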