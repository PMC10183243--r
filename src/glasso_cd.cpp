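// Graphical LASSO via block coordinate descent (Friedman-style):
// maximises log det K - tr(S K) - lambda * ||K||_1,offdiag.
// The diagonal is unpenalised, so diag(W) stays diag(S).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Solve the lasso subproblem  min_b 0.5 b'Vb - s'b + lambda|b|_1
// by cyclic coordinate descent with an active-set strategy: full sweeps
// alternate with convergence passes over the nonzero coordinates only.
static void lasso_cd(const mat& V, const vec& s, vec& b, double lambda,
                     double thr, int max_iter) {
  const uword q = s.n_elem;
  vec g = V * b;  // maintained gradient product
  int it = 0;
  while (it < max_iter) {
    // one full sweep over all coordinates
    double dmax = 0.0;
    for (uword k = 0; k < q; ++k) {
      double grad = s(k) - g(k) + V(k, k) * b(k);
      double bnew = soft(grad, lambda) / V(k, k);
      double d = bnew - b(k);
      if (d != 0.0) {
        g += d * V.col(k);
        b(k) = bnew;
        if (std::abs(d) > dmax) dmax = std::abs(d);
      }
    }
    ++it;
    if (dmax < thr) break;
    // converge on the active set
    uvec act = find(b != 0.0);
    while (it < max_iter && act.n_elem > 0) {
      double amax = 0.0;
      for (uword a = 0; a < act.n_elem; ++a) {
        uword k = act(a);
        double grad = s(k) - g(k) + V(k, k) * b(k);
        double bnew = soft(grad, lambda) / V(k, k);
        double d = bnew - b(k);
        if (d != 0.0) {
          g += d * V.col(k);
          b(k) = bnew;
          if (std::abs(d) > amax) amax = std::abs(d);
        }
      }
      ++it;
      if (amax < thr) break;
    }
  }
}

// [[Rcpp::export(name = ".glasso_cd")]]
Rcpp::List glasso_cd(const arma::mat& S, double lambda,
                     Rcpp::Nullable<Rcpp::NumericMatrix> W_init = R_NilValue,
                     Rcpp::Nullable<Rcpp::NumericMatrix> B_init = R_NilValue,
                     double tol = 1e-4, int max_iter = 200,
                     int inner_max_iter = 1000) {
  const uword p = S.n_rows;
  mat W(p, p), B(p, p, fill::zeros);
  if (W_init.isNotNull()) {
    W = Rcpp::as<mat>(W_init.get());
  } else {
    W = S;
  }
  if (B_init.isNotNull()) B = Rcpp::as<mat>(B_init.get());
  W.diag() = S.diag();  // unpenalised diagonal

  // scale for the convergence threshold, as in the reference algorithm
  double sbar = 0.0;
  if (p > 1) {
    mat absS = abs(S);
    absS.diag().zeros();
    sbar = accu(absS) / (double)(p * (p - 1));
  }
  double thr_outer = tol * std::max(sbar, 1e-12);
  double thr_inner = thr_outer / 10.0;

  bool converged = (p == 1);
  int iters = 0;
  if (p > 1) {
    uvec all = regspace<uvec>(0, p - 1);
    for (int it = 0; it < max_iter; ++it) {
      double dmax = 0.0;
      for (uword j = 0; j < p; ++j) {
        uvec rest = all.elem(find(all != j));
        mat V = W.submat(rest, rest);
        vec s12 = S.col(j);
        s12 = s12.elem(rest);
        vec b = B.col(j);
        b = b.elem(rest);
        lasso_cd(V, s12, b, lambda, thr_inner, inner_max_iter);
        vec w12 = V * b;
        for (uword k = 0; k < rest.n_elem; ++k) {
          double d = std::abs(w12(k) - W(rest(k), j));
          if (d > dmax) dmax = d;
          W(rest(k), j) = w12(k);
          W(j, rest(k)) = w12(k);
          B(rest(k), j) = b(k);
        }
      }
      iters = it + 1;
      if (dmax < thr_outer) { converged = true; break; }
    }
  }

  // Recover the precision matrix from the regression coefficients:
  // k_jj = 1 / (w_jj - w12' b_j),  k_12 = -b_j k_jj.
  mat K(p, p, fill::zeros);
  if (p == 1) {
    K(0, 0) = 1.0 / W(0, 0);
  } else {
    uvec all = regspace<uvec>(0, p - 1);
    for (uword j = 0; j < p; ++j) {
      uvec rest = all.elem(find(all != j));
      vec b = B.col(j);
      b = b.elem(rest);
      vec w12 = W.col(j);
      w12 = w12.elem(rest);
      double kjj = 1.0 / (W(j, j) - dot(w12, b));
      K(j, j) = kjj;
      for (uword k = 0; k < rest.n_elem; ++k) K(rest(k), j) = -b(k) * kjj;
    }
    // sparsity pattern: an edge is absent iff both regressions dropped it
    for (uword j = 0; j < p; ++j)
      for (uword i = j + 1; i < p; ++i) {
        if (B(i, j) == 0.0 && B(j, i) == 0.0) {
          K(i, j) = 0.0; K(j, i) = 0.0;
        } else {
          double v = 0.5 * (K(i, j) + K(j, i));
          K(i, j) = v; K(j, i) = v;
        }
      }
  }

  return Rcpp::List::create(
      Rcpp::Named("K") = K, Rcpp::Named("W") = W, Rcpp::Named("B") = B,
      Rcpp::Named("iters") = iters, Rcpp::Named("converged") = converged);
}
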