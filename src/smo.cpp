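// Sequential Minimal Optimization solver for the soft-margin SVM dual,
// with second-order working-set selection (LIBSVM-style), plus helpers that
// keep the hot loops of grid search and recursive feature elimination in C++.
//
// Conventions: labels are +1/-1; kernels are either linear (Gram matrix) or
// RBF exp(-gamma * ||xi - xj||^2); the decision value is
// f(x) = sum_i alpha_i y_i K(x_i, x) + b and class = sign(f) (ties -> +1).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double TAU = 1e-12;

struct SmoFit {
  std::vector<double> alpha;
  double b;
  int iterations;
  bool converged;
};

// Solve the dual on a precomputed kernel (K is n x n, column-major, symmetric).
// warm (optional, length n) seeds alpha with a feasible point: it must satisfy
// 0 <= alpha <= C and sum(alpha * y) = 0, as solutions of related problems
// (previous RFE step, previous C on the same kernel after rescaling) do.
static SmoFit smo_solve(const double* K, int n, const int* y,
                        double C, double tol, int max_iter,
                        const double* warm = 0) {
  std::vector<double> alpha(n, 0.0);
  std::vector<double> grad(n, -1.0); // gradient of 1/2 a'Qa - e'a at a = 0
  if (warm) {
    for (int i = 0; i < n; ++i) alpha[i] = warm[i];
    for (int j = 0; j < n; ++j) {
      if (alpha[j] == 0.0) continue;
      const double* Kj = K + (size_t)j * n;
      double aj = alpha[j] * y[j];
      for (int t = 0; t < n; ++t) grad[t] += y[t] * Kj[t] * aj;
    }
  }
  const double INF = std::numeric_limits<double>::infinity();

  int iter = 0;
  bool converged = false;
  for (iter = 0; iter < max_iter; ++iter) {
    // select i: maximal violation on the "up" set
    int i = -1;
    double Gmax = -INF;
    for (int t = 0; t < n; ++t) {
      if (y[t] == 1) {
        if (alpha[t] < C && -grad[t] > Gmax) { Gmax = -grad[t]; i = t; }
      } else {
        if (alpha[t] > 0 && grad[t] > Gmax) { Gmax = grad[t]; i = t; }
      }
    }
    if (i < 0) { converged = true; break; }
    const double* Ki = K + (size_t)i * n;

    // select j: second-order gain among the "low" set; also track the
    // maximal low-side violation for the stopping criterion
    int j = -1;
    double Gmax2 = -INF;
    double best_obj = 0.0;
    for (int t = 0; t < n; ++t) {
      bool in_low = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
      if (!in_low) continue;
      double viol = (y[t] == 1) ? grad[t] : -grad[t];
      if (viol > Gmax2) Gmax2 = viol;
      double grad_diff = Gmax + viol;
      if (grad_diff > 0) {
        double quad = K[(size_t)i * n + i] + K[(size_t)t * n + t] - 2.0 * Ki[t];
        if (quad <= 0) quad = TAU;
        double obj = -(grad_diff * grad_diff) / quad;
        if (obj < best_obj) { best_obj = obj; j = t; }
      }
    }
    if (Gmax + Gmax2 < tol || j < 0) { converged = true; break; }
    const double* Kj = K + (size_t)j * n;

    double old_ai = alpha[i], old_aj = alpha[j];
    // in both branches the curvature along the feasible direction is
    // Q_ii + Q_jj -/+ 2 Q_ij = K_ii + K_jj - 2 K_ij
    if (y[i] != y[j]) {
      double quad = Ki[i] + Kj[j] - 2.0 * Ki[j];
      if (quad <= 0) quad = TAU;
      double delta = (-grad[i] - grad[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = Ki[i] + Kj[j] - 2.0 * Ki[j];
      if (quad <= 0) quad = TAU;
      double delta = (grad[i] - grad[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    double di = alpha[i] - old_ai, dj = alpha[j] - old_aj;
    if (di != 0.0 || dj != 0.0) {
      for (int t = 0; t < n; ++t) {
        grad[t] += y[t] * (y[i] * Ki[t] * di + y[j] * Kj[t] * dj);
      }
    }
  }

  // intercept: f(x) = sum alpha_i y_i K(x_i, x) + b, b = -rho
  double ub = std::numeric_limits<double>::infinity();
  double lb = -std::numeric_limits<double>::infinity();
  double sum_free = 0.0;
  int nr_free = 0;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * grad[t];
    if (alpha[t] >= C) {
      if (y[t] == -1) { if (yG < ub) ub = yG; } else { if (yG > lb) lb = yG; }
    } else if (alpha[t] <= 0) {
      if (y[t] == 1) { if (yG < ub) ub = yG; } else { if (yG > lb) lb = yG; }
    } else {
      ++nr_free; sum_free += yG;
    }
  }
  double rho = (nr_free > 0) ? sum_free / nr_free : (ub + lb) / 2.0;

  SmoFit out;
  out.alpha = alpha;
  out.b = -rho;
  out.iterations = iter;
  out.converged = converged;
  return out;
}

// squared Euclidean distance matrix (n x n) of the rows of X (n x p)
static std::vector<double> sqdist_matrix(const NumericMatrix& X) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> sq(n, 0.0);
  for (int j = 0; j < p; ++j) {
    const double* col = &X(0, j);
    for (int i = 0; i < n; ++i) sq[i] += col[i] * col[i];
  }
  std::vector<double> D((size_t)n * n, 0.0);
  // D = sq_i + sq_j - 2 x_i . x_j
  for (int j = 0; j < p; ++j) {
    const double* col = &X(0, j);
    for (int b = 0; b < n; ++b) {
      double xb = col[b];
      double* Dcol = &D[(size_t)b * n];
      for (int a = 0; a < n; ++a) Dcol[a] -= 2.0 * col[a] * xb;
    }
  }
  for (int b = 0; b < n; ++b) {
    double* Dcol = &D[(size_t)b * n];
    for (int a = 0; a < n; ++a) {
      Dcol[a] += sq[a] + sq[b];
      if (Dcol[a] < 0) Dcol[a] = 0;
    }
  }
  return D;
}

static std::vector<double> gram_matrix(const NumericMatrix& X) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> G((size_t)n * n, 0.0);
  for (int j = 0; j < p; ++j) {
    const double* col = &X(0, j);
    for (int b = 0; b < n; ++b) {
      double xb = col[b];
      double* Gcol = &G[(size_t)b * n];
      for (int a = 0; a < n; ++a) Gcol[a] += col[a] * xb;
    }
  }
  return G;
}

// [[Rcpp::export]]
List cpp_svm_fit(NumericMatrix X, IntegerVector y, double C, double gamma,
                 bool linear, double tol, int max_iter) {
  int n = X.nrow();
  std::vector<double> K;
  if (linear) {
    K = gram_matrix(X);
  } else {
    K = sqdist_matrix(X);
    for (size_t t = 0; t < K.size(); ++t) K[t] = std::exp(-gamma * K[t]);
  }
  SmoFit fit = smo_solve(K.data(), n, INTEGER(y), C, tol, max_iter);
  return List::create(_["alpha"] = NumericVector(fit.alpha.begin(), fit.alpha.end()),
                      _["b"] = fit.b,
                      _["iterations"] = fit.iterations,
                      _["converged"] = fit.converged);
}

// decision values of an RBF model at new points
// [[Rcpp::export]]
NumericVector cpp_rbf_decision(NumericMatrix Xtr, NumericVector coef, double b,
                               double gamma, NumericMatrix Xnew) {
  int n = Xtr.nrow(), m = Xnew.nrow(), p = Xtr.ncol();
  NumericVector out(m);
  for (int a = 0; a < m; ++a) {
    double f = b;
    for (int i = 0; i < n; ++i) {
      if (coef[i] == 0.0) continue;
      double d = 0.0;
      for (int j = 0; j < p; ++j) {
        double diff = Xtr(i, j) - Xnew(a, j);
        d += diff * diff;
      }
      f += coef[i] * std::exp(-gamma * d);
    }
    out[a] = f;
  }
  return out;
}

// Cross-validated accuracy (%) for every (C, gamma) combo over the given fold
// assignment. fold is 1-based with values in 1..K. Returns ncombo x K matrix.
// For linear kernels the gamma entries are ignored.
// [[Rcpp::export]]
NumericMatrix cpp_svm_cv_grid(NumericMatrix X, IntegerVector y,
                              NumericVector C_vec, NumericVector g_vec,
                              IntegerVector fold, bool linear,
                              double tol, int max_iter) {
  int n = X.nrow();
  int ncombo = C_vec.size();
  int K = 0;
  for (int i = 0; i < n; ++i) if (fold[i] > K) K = fold[i];
  NumericMatrix acc(ncombo, K);

  std::vector<double> base = linear ? gram_matrix(X) : sqdist_matrix(X);
  std::vector<double> kern((size_t)n * n);

  // group combos by gamma so each kernel is built once
  std::vector<bool> done(ncombo, false);
  for (int c0 = 0; c0 < ncombo; ++c0) {
    if (done[c0]) continue;
    double g = g_vec[c0];
    if (linear) {
      kern = base;
    } else {
      for (size_t t = 0; t < base.size(); ++t) kern[t] = std::exp(-g * base[t]);
    }
    std::vector<int> combos;
    for (int c = c0; c < ncombo; ++c)
      if (!done[c] && (linear || g_vec[c] == g)) { combos.push_back(c); done[c] = true; }

    for (int k = 1; k <= K; ++k) {
      std::vector<int> tr, te;
      tr.reserve(n); te.reserve(n);
      for (int i = 0; i < n; ++i) (fold[i] == k ? te : tr).push_back(i);
      int ntr = (int)tr.size(), nte = (int)te.size();
      if (ntr == 0 || nte == 0) continue;
      std::vector<double> Ktr((size_t)ntr * ntr);
      for (int b = 0; b < ntr; ++b) {
        const double* col = &kern[(size_t)tr[b] * n];
        for (int a = 0; a < ntr; ++a) Ktr[(size_t)b * ntr + a] = col[tr[a]];
      }
      std::vector<int> ytr(ntr);
      for (int a = 0; a < ntr; ++a) ytr[a] = y[tr[a]];

      std::vector<double> warm;
      double prev_C = -1.0;
      for (size_t cc = 0; cc < combos.size(); ++cc) {
        int c = combos[cc];
        // warm start from the previous C on the same kernel and fold:
        // rescaling keeps the seed feasible for the new box
        const double* seed = 0;
        if (!warm.empty() && prev_C > 0) {
          double scale = C_vec[c] / prev_C;
          if (scale < 1.0) {
            for (int t = 0; t < ntr; ++t) warm[t] *= scale;
          }
          seed = warm.data();
        }
        SmoFit fit = smo_solve(Ktr.data(), ntr, ytr.data(), C_vec[c], tol,
                               max_iter, seed);
        warm = fit.alpha;
        prev_C = C_vec[c];
        int correct = 0;
        for (int a = 0; a < nte; ++a) {
          double f = fit.b;
          const double* col = &kern[(size_t)te[a] * n];
          for (int i = 0; i < ntr; ++i) {
            if (fit.alpha[i] == 0.0) continue;
            f += fit.alpha[i] * ytr[i] * col[tr[i]];
          }
          int pred = (f >= 0) ? 1 : -1;
          if (pred == y[te[a]]) ++correct;
        }
        acc(c, k - 1) = 100.0 * correct / nte;
      }
    }
  }
  return acc;
}

// Recursive feature elimination with a linear SVM (penalty C) on all rows of X.
// At each iteration the accuracy of the current feature set is recorded
// (stratified CV over `fold` if given, resubstitution if fold is empty), a
// linear SVM is fitted on all rows and the `step` features with the smallest
// squared weight are removed (ties -> lower column index first).
// Returns the removal order (1-based column indices), the evaluated set sizes,
// their accuracies, and the number of solver calls that hit the iteration cap.
// [[Rcpp::export]]
List cpp_svm_rfe(NumericMatrix X, IntegerVector y, double C,
                 IntegerVector fold, int step, double tol, int max_iter) {
  int n = X.nrow(), p = X.ncol();
  int K = 0;
  for (int i = 0; i < fold.size(); ++i) if (fold[i] > K) K = fold[i];
  bool use_cv = (fold.size() == (R_xlen_t)n) && K >= 2;

  std::vector<double> G = gram_matrix(X); // Gram over all active features
  std::vector<bool> active(p, true);
  int n_active = p;

  std::vector<int> order;           // removal order, 0-based
  std::vector<int> sizes;           // evaluated set sizes (p, p-step, ..., 1)
  std::vector<double> accs;         // accuracy (%) per evaluated size
  int n_capped = 0;

  std::vector<int> yv(n);
  for (int i = 0; i < n; ++i) yv[i] = y[i];

  // warm starts across elimination steps: slot 0 = ranking fit on all rows,
  // slots 1..K = the CV fold solves (the kernel changes by one rank-1 term
  // per removed feature, so the previous alphas are near-optimal seeds)
  std::vector<std::vector<double> > warm(K + 1);

  while (true) {
    // evaluate the current feature set
    double a = 0.0;
    if (use_cv) {
      double sum = 0.0;
      int nf = 0;
      for (int k = 1; k <= K; ++k) {
        std::vector<int> tr, te;
        for (int i = 0; i < n; ++i) (fold[i] == k ? te : tr).push_back(i);
        int ntr = (int)tr.size(), nte = (int)te.size();
        if (ntr == 0 || nte == 0) continue;
        std::vector<double> Ktr((size_t)ntr * ntr);
        for (int b = 0; b < ntr; ++b) {
          const double* col = &G[(size_t)tr[b] * n];
          for (int t = 0; t < ntr; ++t) Ktr[(size_t)b * ntr + t] = col[tr[t]];
        }
        std::vector<int> ytr(ntr);
        for (int t = 0; t < ntr; ++t) ytr[t] = yv[tr[t]];
        const double* seed = (warm[k].size() == (size_t)ntr) ? warm[k].data() : 0;
        SmoFit fit = smo_solve(Ktr.data(), ntr, ytr.data(), C, tol, max_iter, seed);
        warm[k] = fit.alpha;
        if (!fit.converged) ++n_capped;
        int correct = 0;
        for (int t = 0; t < nte; ++t) {
          double f = fit.b;
          const double* col = &G[(size_t)te[t] * n];
          for (int i = 0; i < ntr; ++i) {
            if (fit.alpha[i] == 0.0) continue;
            f += fit.alpha[i] * ytr[i] * col[tr[i]];
          }
          if (((f >= 0) ? 1 : -1) == yv[te[t]]) ++correct;
        }
        sum += 100.0 * correct / nte;
        ++nf;
      }
      a = (nf > 0) ? sum / nf : NA_REAL;
    } else {
      const double* seed = (warm[0].size() == (size_t)n) ? warm[0].data() : 0;
      SmoFit fit = smo_solve(G.data(), n, yv.data(), C, tol, max_iter, seed);
      warm[0] = fit.alpha;
      if (!fit.converged) ++n_capped;
      int correct = 0;
      for (int t = 0; t < n; ++t) {
        double f = fit.b;
        const double* col = &G[(size_t)t * n];
        for (int i = 0; i < n; ++i) {
          if (fit.alpha[i] == 0.0) continue;
          f += fit.alpha[i] * yv[i] * col[i];
        }
        if (((f >= 0) ? 1 : -1) == yv[t]) ++correct;
      }
      a = 100.0 * correct / n;
    }
    sizes.push_back(n_active);
    accs.push_back(a);

    if (n_active <= 1) break;

    // rank features by squared weight of a linear SVM on all rows
    const double* seed0 = (warm[0].size() == (size_t)n) ? warm[0].data() : 0;
    SmoFit fit = smo_solve(G.data(), n, yv.data(), C, tol, max_iter, seed0);
    warm[0] = fit.alpha;
    if (!fit.converged) ++n_capped;
    std::vector<std::pair<double, int> > w2;
    w2.reserve(n_active);
    for (int j = 0; j < p; ++j) {
      if (!active[j]) continue;
      double w = 0.0;
      for (int i = 0; i < n; ++i) {
        if (fit.alpha[i] == 0.0) continue;
        w += fit.alpha[i] * yv[i] * X(i, j);
      }
      w2.push_back(std::make_pair(w * w, j));
    }
    std::sort(w2.begin(), w2.end()); // ascending weight^2, then lower index
    int nrem = std::min(step, n_active - 1);
    for (int r = 0; r < nrem; ++r) {
      int j = w2[r].second;
      active[j] = false;
      --n_active;
      order.push_back(j);
      // downdate the Gram matrix: G -= x_j x_j'
      const double* col = &X(0, j);
      for (int b = 0; b < n; ++b) {
        double xb = col[b];
        double* Gcol = &G[(size_t)b * n];
        for (int a2 = 0; a2 < n; ++a2) Gcol[a2] -= col[a2] * xb;
      }
    }
  }

  IntegerVector ord(order.size());
  for (size_t t = 0; t < order.size(); ++t) ord[t] = order[t] + 1;
  return List::create(_["order"] = ord,
                      _["sizes"] = IntegerVector(sizes.begin(), sizes.end()),
                      _["accuracies"] = NumericVector(accs.begin(), accs.end()),
                      _["n_capped"] = n_capped);
}
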