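#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// C-SVC dual solver: sequential minimal optimization with maximal-violating
// pair working-set selection. Deterministic; the full kernel matrix is kept
// in memory, so it is suited to the moderate problem sizes used here
// (n up to a few thousand).

static inline double kernel_val(const NumericMatrix& X, int i, int j,
                                double gamma, int kernel_type) {
  const int p = X.ncol();
  if (kernel_type == 1) { // linear
    double s = 0.0;
    for (int k = 0; k < p; ++k) s += X(i, k) * X(j, k);
    return s;
  }
  double d2 = 0.0;
  for (int k = 0; k < p; ++k) {
    const double d = X(i, k) - X(j, k);
    d2 += d * d;
  }
  return std::exp(-gamma * d2);
}

// [[Rcpp::export]]
List smo_train(NumericMatrix X, NumericVector y, double cost, double gamma,
               int kernel_type = 0, double tol = 1e-3,
               int max_iter = 200000) {
  const int n = X.nrow();
  if (y.size() != n) stop("X and y disagree on the number of observations");
  for (int i = 0; i < n; ++i)
    if (y[i] != 1.0 && y[i] != -1.0) stop("labels must be coded +1/-1");

  // kernel matrix
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      const double v = kernel_val(X, i, j, gamma, kernel_type);
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }

  std::vector<double> alpha(n, 0.0), G(n, -1.0); // G = Q alpha - e
  int iter = 0;
  const double TAU = 1e-12;

  while (iter < max_iter) {
    // working-set selection: maximal violating pair
    int i = -1, j = -1;
    double gmax = -HUGE_VAL, gmin = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool in_up = (y[t] > 0 && alpha[t] < cost) ||
                         (y[t] < 0 && alpha[t] > 0);
      const bool in_low = (y[t] > 0 && alpha[t] > 0) ||
                          (y[t] < 0 && alpha[t] < cost);
      if (in_up && v > gmax) { gmax = v; i = t; }
      if (in_low && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) break;

    const double Kii = K[(size_t)i * n + i], Kjj = K[(size_t)j * n + j],
                 Kij = K[(size_t)i * n + j];
    double quad = Kii + Kjj - 2.0 * y[i] * y[j] * Kij;
    if (quad <= 0) quad = TAU;
    const double delta = (gmax - gmin) / quad;

    const double old_ai = alpha[i], old_aj = alpha[j];
    alpha[i] += y[i] * delta;
    alpha[j] -= y[j] * delta;

    // project back onto the box while preserving y' alpha
    const double s = y[i] * old_ai + y[j] * old_aj;
    if (alpha[i] > cost) alpha[i] = cost;
    if (alpha[i] < 0) alpha[i] = 0;
    alpha[j] = y[j] * (s - y[i] * alpha[i]);
    if (alpha[j] > cost) alpha[j] = cost;
    if (alpha[j] < 0) alpha[j] = 0;
    alpha[i] = y[i] * (s - y[j] * alpha[j]);
    if (alpha[i] > cost) alpha[i] = cost;
    if (alpha[i] < 0) alpha[i] = 0;

    const double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    if (dai != 0.0 || daj != 0.0) {
      for (int t = 0; t < n; ++t)
        G[t] += y[t] * (y[i] * K[(size_t)i * n + t] * dai +
                        y[j] * K[(size_t)j * n + t] * daj);
    }
    ++iter;
  }

  // intercept: average over free support vectors, else midpoint of bounds
  double b;
  int n_free = 0;
  double sum_free = 0.0, ub = HUGE_VAL, lb = -HUGE_VAL;
  for (int t = 0; t < n; ++t) {
    const double yg = y[t] * G[t]; // y_t * (Q alpha - e)_t = f0_t*y_t... see below
    // f0_t = sum_j alpha_j y_j K_tj = y_t * (G_t + 1) since G = Q alpha - e
    const double f0 = y[t] * (G[t] + 1.0);
    const double r = y[t] - f0;
    (void)yg;
    if (alpha[t] > 0 && alpha[t] < cost) { sum_free += r; ++n_free; }
    else if ((y[t] > 0 && alpha[t] == 0) || (y[t] < 0 && alpha[t] == cost)) {
      if (r < ub) ub = r;
    } else {
      if (r > lb) lb = r;
    }
  }
  b = n_free > 0 ? sum_free / n_free : (ub + lb) / 2.0;

  // compact support vectors
  std::vector<int> sv_idx;
  for (int t = 0; t < n; ++t) if (alpha[t] > 0) sv_idx.push_back(t);
  const int nsv = (int)sv_idx.size();
  NumericMatrix SV(nsv, X.ncol());
  NumericVector coef(nsv);
  IntegerVector index(nsv);
  for (int s2 = 0; s2 < nsv; ++s2) {
    const int t = sv_idx[s2];
    for (int k = 0; k < X.ncol(); ++k) SV(s2, k) = X(t, k);
    coef[s2] = alpha[t] * y[t];
    index[s2] = t + 1;
  }

  return List::create(_["sv"] = SV, _["coef"] = coef, _["b"] = b,
                      _["index"] = index, _["iterations"] = iter,
                      _["converged"] = iter < max_iter);
}

// [[Rcpp::export]]
NumericVector smo_decision(NumericMatrix SV, NumericVector coef, double b,
                           NumericMatrix Xnew, double gamma,
                           int kernel_type = 0) {
  const int m = Xnew.nrow(), nsv = SV.nrow(), p = SV.ncol();
  if (Xnew.ncol() != p) stop("feature dimension mismatch");
  NumericVector f(m);
  for (int i = 0; i < m; ++i) {
    double s = 0.0;
    for (int v = 0; v < nsv; ++v) {
      double k;
      if (kernel_type == 1) {
        k = 0.0;
        for (int c = 0; c < p; ++c) k += Xnew(i, c) * SV(v, c);
      } else {
        double d2 = 0.0;
        for (int c = 0; c < p; ++c) {
          const double d = Xnew(i, c) - SV(v, c);
          d2 += d * d;
        }
        k = std::exp(-gamma * d2);
      }
      s += coef[v] * k;
    }
    f[i] = s + b;
  }
  return f;
}
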