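// Deterministic SMO solver for a soft-margin binary SVM with RBF kernel.
// Pair selection is systematic (sweep i, pick j maximising |E_i - E_j|,
// lowest index on ties), so repeated runs on identical inputs are identical.
#include <Rcpp.h>
using namespace Rcpp;

static inline double rbf(double a, double b, double gamma) {
  const double d = a - b;
  return std::exp(-gamma * d * d);
}

// Train on scalar features x (already standardised by the caller) with labels
// y in {-1,+1}; return decision values f(x_new) for the test points.
// [[Rcpp::export]]
NumericVector svm_rbf_decision_cpp(NumericVector x, NumericVector y,
                                   NumericVector xnew, double C, double gamma,
                                   double tol = 1e-3, int max_quiet = 3,
                                   int max_sweeps = 200) {
  const int n = x.size();
  std::vector<std::vector<double>> K(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) K[i][j] = rbf(x[i], x[j], gamma);

  std::vector<double> alpha(n, 0.0);
  double b = 0.0;

  auto fval = [&](int i) {
    double s = b;
    for (int t = 0; t < n; ++t)
      if (alpha[t] > 0.0) s += alpha[t] * y[t] * K[t][i];
    return s;
  };

  int quiet = 0, sweeps = 0;
  while (quiet < max_quiet && sweeps < max_sweeps) {
    int changed = 0;
    ++sweeps;
    for (int i = 0; i < n; ++i) {
      const double Ei = fval(i) - y[i];
      if (!((y[i] * Ei < -tol && alpha[i] < C) ||
            (y[i] * Ei > tol && alpha[i] > 0.0)))
        continue;
      // second choice: largest |Ei - Ej|, ties to the lowest index
      int j = -1;
      double best = -1.0;
      for (int t = 0; t < n; ++t) {
        if (t == i) continue;
        const double Et = fval(t) - y[t];
        const double gap = std::fabs(Ei - Et);
        if (gap > best + 1e-15) { best = gap; j = t; }
      }
      if (j < 0) continue;
      const double Ej = fval(j) - y[j];
      const double ai_old = alpha[i], aj_old = alpha[j];
      double L, H;
      if (y[i] != y[j]) {
        L = std::max(0.0, aj_old - ai_old);
        H = std::min(C, C + aj_old - ai_old);
      } else {
        L = std::max(0.0, ai_old + aj_old - C);
        H = std::min(C, ai_old + aj_old);
      }
      if (L >= H) continue;
      const double eta = 2.0 * K[i][j] - K[i][i] - K[j][j];
      if (eta >= 0.0) continue;
      double aj = aj_old - y[j] * (Ei - Ej) / eta;
      aj = std::min(H, std::max(L, aj));
      if (std::fabs(aj - aj_old) < 1e-8) continue;
      const double ai = ai_old + y[i] * y[j] * (aj_old - aj);
      alpha[i] = ai;
      alpha[j] = aj;
      const double b1 = b - Ei - y[i] * (ai - ai_old) * K[i][i] -
                        y[j] * (aj - aj_old) * K[i][j];
      const double b2 = b - Ej - y[i] * (ai - ai_old) * K[i][j] -
                        y[j] * (aj - aj_old) * K[j][j];
      if (ai > 0.0 && ai < C)
        b = b1;
      else if (aj > 0.0 && aj < C)
        b = b2;
      else
        b = 0.5 * (b1 + b2);
      ++changed;
    }
    quiet = (changed == 0) ? quiet + 1 : 0;
  }

  const int m = xnew.size();
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    double s = b;
    for (int t = 0; t < n; ++t)
      if (alpha[t] > 0.0) s += alpha[t] * y[t] * rbf(x[t], xnew[q], gamma);
    out[q] = s;
  }
  return out;
}
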