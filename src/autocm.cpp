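#include <Rcpp.h>
using namespace Rcpp;

// Online epoch loop of the auto contractive map. Presentation orders are
// generated in R (so the R RNG owns reproducibility) and passed as a
// 1-based epochs x n matrix. Returns the state after running either all
// supplied epochs or until the mono-weights of the active variables are
// within tol*C of saturation.
// [[Rcpp::export(name = ".autocm_epochs")]]
List autocm_epochs(NumericMatrix S, NumericVector v0, NumericMatrix W0,
                   double C, double lambda, IntegerMatrix orders,
                   LogicalVector active, double tol) {
  const int n = S.nrow(), N = S.ncol(), E = orders.nrow();
  NumericVector v = clone(v0);
  NumericMatrix W = clone(W0);
  std::vector<double> h(N), net(N), o(N);
  bool conv = false;
  int ep = 0;
  for (; ep < E && !conv; ++ep) {
    for (int k = 0; k < n; ++k) {
      const int r = orders(ep, k) - 1;
      for (int i = 0; i < N; ++i) h[i] = S(r, i) * (1.0 - v[i] / C);
      for (int i = 0; i < N; ++i) {
        double acc = 0.0;
        for (int j = 0; j < N; ++j) acc += h[j] * (1.0 - W(i, j) / C);
        net[i] = acc;
      }
      for (int i = 0; i < N; ++i) o[i] = h[i] * (1.0 - net[i] / C);
      for (int i = 0; i < N; ++i) {
        double nv = v[i] + lambda * (S(r, i) - h[i]) * (1.0 - v[i] / C);
        v[i] = std::min(C, std::max(0.0, nv));
      }
      for (int i = 0; i < N; ++i) {
        const double gi = lambda * (h[i] - o[i]);
        for (int j = 0; j < N; ++j) {
          double nw = W(i, j) + gi * (1.0 - W(i, j) / C) * h[j];
          W(i, j) = std::min(C, std::max(0.0, nw));
        }
      }
    }
    double worst = 0.0;
    for (int i = 0; i < N; ++i)
      if (active[i] && C - v[i] > worst) worst = C - v[i];
    conv = worst <= tol * C;
  }
  return List::create(_["v"] = v, _["w"] = W, _["epochsRun"] = ep,
                      _["converged"] = conv);
}
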