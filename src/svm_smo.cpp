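// RBF-kernel support vector machine trained by sequential minimal
// optimization (the simplified working-set variant: first index by KKT
// violation scan, second drawn at random). The full kernel matrix is
// cached, which is fine at the corpus sizes this package targets
// (thousands of rows). Probabilities are produced downstream by Platt
// scaling of the decision values.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

static double rbf(const NumericMatrix& X, int i, int j, double gamma) {
  double s = 0.0;
  for (int k = 0; k < X.ncol(); ++k) {
    double d = X(i, k) - X(j, k);
    s += d * d;
  }
  return std::exp(-gamma * s);
}

// [[Rcpp::export(name = ".svm_train_cpp")]]
List svm_train_cpp(NumericMatrix X, NumericVector y, double C, double gamma,
                   double tol, int max_passes, int seed) {
  int n = X.nrow();
  if (n != y.size()) stop("X and y disagree on the number of rows");
  std::vector<std::vector<double> > K(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) K[i][j] = K[j][i] = rbf(X, i, j, gamma);

  std::vector<double> alpha(n, 0.0), E(n);
  double b = 0.0;
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> pick(0, n - 2);

  auto f = [&](int i) {
    double s = b;
    for (int k = 0; k < n; ++k)
      if (alpha[k] > 0.0) s += alpha[k] * y[k] * K[k][i];
    return s;
  };

  int passes = 0, iters = 0, max_iters = 200 * n;
  while (passes < max_passes && iters < max_iters) {
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      ++iters;
      double Ei = f(i) - y[i];
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0.0)) {
        int j = pick(rng);
        if (j >= i) ++j;
        double Ej = f(j) - y[j];
        double ai = alpha[i], aj = alpha[j];
        double L, H;
        if (y[i] != y[j]) {
          L = std::max(0.0, aj - ai);
          H = std::min(C, C + aj - ai);
        } else {
          L = std::max(0.0, ai + aj - C);
          H = std::min(C, ai + aj);
        }
        if (L >= H) continue;
        double eta = 2.0 * K[i][j] - K[i][i] - K[j][j];
        if (eta >= 0.0) continue;
        double aj_new = aj - y[j] * (Ei - Ej) / eta;
        aj_new = std::min(H, std::max(L, aj_new));
        if (std::fabs(aj_new - aj) < 1e-7) continue;
        double ai_new = ai + y[i] * y[j] * (aj - aj_new);
        double b1 = b - Ei - y[i] * (ai_new - ai) * K[i][i] -
                    y[j] * (aj_new - aj) * K[i][j];
        double b2 = b - Ej - y[i] * (ai_new - ai) * K[i][j] -
                    y[j] * (aj_new - aj) * K[j][j];
        alpha[i] = ai_new;
        alpha[j] = aj_new;
        if (ai_new > 0.0 && ai_new < C) b = b1;
        else if (aj_new > 0.0 && aj_new < C) b = b2;
        else b = 0.5 * (b1 + b2);
        ++changed;
      }
    }
    passes = changed == 0 ? passes + 1 : 0;
  }

  // keep only support vectors
  std::vector<int> sv;
  for (int i = 0; i < n; ++i)
    if (alpha[i] > 1e-8) sv.push_back(i);
  NumericMatrix Xsv(sv.size(), X.ncol());
  NumericVector coef(sv.size());
  for (size_t s = 0; s < sv.size(); ++s) {
    coef[s] = alpha[sv[s]] * y[sv[s]];
    for (int k = 0; k < X.ncol(); ++k) Xsv(s, k) = X(sv[s], k);
  }
  return List::create(_["sv"] = Xsv, _["coef"] = coef, _["b"] = b,
                      _["gamma"] = gamma);
}

// [[Rcpp::export(name = ".svm_decision_cpp")]]
NumericVector svm_decision_cpp(List model, NumericMatrix X) {
  NumericMatrix sv = model["sv"];
  NumericVector coef = model["coef"];
  double b = model["b"], gamma = model["gamma"];
  int n = X.nrow(), m = sv.nrow(), p = X.ncol();
  if (p != sv.ncol()) stop("feature count mismatch with support vectors");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = b;
    for (int j = 0; j < m; ++j) {
      double d2 = 0.0;
      for (int k = 0; k < p; ++k) {
        double d = X(i, k) - sv(j, k);
        d2 += d * d;
      }
      s += coef[j] * std::exp(-gamma * d2);
    }
    out[i] = s;
  }
  return out;
}
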