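#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Soft threshold, the scalar lasso prox.
static inline double soft1(double a, double t) {
  if (a > t) return a - t;
  if (a < -t) return a + t;
  return 0.0;
}

// Proximal map of the sparse-group penalty acting positionwise on the
// off-diagonal entries of a stack of K p x p matrices: at each (i, j),
// i != j, soft-threshold the K-vector entrywise at t2, then shrink the
// group by max(0, 1 - t3 / ||.||_2).  Diagonals pass through unchanged.
// [[Rcpp::export]]
arma::cube ggl_prox_cpp(const arma::cube& A, double t2, double t3) {
  const uword p = A.n_rows, K = A.n_slices;
  cube Z(A);
  for (uword j = 0; j < p; ++j) {
    for (uword i = 0; i < p; ++i) {
      if (i == j) continue;
      double nrm2 = 0.0;
      for (uword k = 0; k < K; ++k) {
        double v = soft1(A(i, j, k), t2);
        Z(i, j, k) = v;
        nrm2 += v * v;
      }
      if (t3 > 0.0) {
        double nrm = std::sqrt(nrm2);
        double scale = (nrm > t3) ? (1.0 - t3 / nrm) : 0.0;
        for (uword k = 0; k < K; ++k) Z(i, j, k) *= scale;
      }
    }
  }
  return Z;
}

// Closed-form minimizer of w(tr(S Omega) - log det Omega)
// + (rho/2)||Omega - Mhat||_F^2 where the caller passes
// M = rho * Mhat - w * S.  Eigenvalues phi_j = (l_j + sqrt(l_j^2 +
// 4 rho w)) / (2 rho) of the symmetrized M; always PD for rho, w > 0.
// [[Rcpp::export]]
arma::mat logdet_update_cpp(const arma::mat& M, double w, double rho) {
  mat Ms = 0.5 * (M + M.t());
  vec l;
  mat V;
  eig_sym(l, V, Ms);
  vec phi = (l + sqrt(square(l) + 4.0 * rho * w)) / (2.0 * rho);
  return V * diagmat(phi) * V.t();
}

// ADMM for the weighted joint graphical lasso:
//   max sum_k w_k [log det Omega_k - tr(S_k Omega_k)]
//       - lam2 sum_k sum_{i != j} |omega_kij|
//       - lam3 sum_{i != j} (sum_k omega_kij^2)^{1/2}
// Consensus split Omega_k = Z_k; scaled dual U_k.  Returns Z (exact
// sparsity) with diagonals taken from Omega.
// [[Rcpp::export]]
Rcpp::List solve_jgl_cpp(const arma::cube& S, const arma::vec& w,
                         double lam2, double lam3, double rho,
                         double abs_tol, double rel_tol, int max_iter,
                         const arma::cube& Z0, bool adapt_rho) {
  const uword p = S.n_rows, K = S.n_slices;
  cube Z(Z0), U(p, p, K, fill::zeros), Omega(Z0), Zold(p, p, K);
  double r = 0.0, s = 0.0, eps_pri = 0.0, eps_dual = 0.0;
  bool converged = false;
  int it = 0;
  const double root = std::sqrt((double)(K * p * p));
  for (it = 1; it <= max_iter; ++it) {
    for (uword k = 0; k < K; ++k) {
      mat M = rho * (Z.slice(k) - U.slice(k)) - w(k) * S.slice(k);
      Omega.slice(k) = logdet_update_cpp(M, w(k), rho);
    }
    Zold = Z;
    Z = ggl_prox_cpp(Omega + U, lam2 / rho, lam3 / rho);
    U += Omega - Z;

    r = std::sqrt(accu(square(Omega - Z)));
    s = rho * std::sqrt(accu(square(Z - Zold)));
    double nOmega = std::sqrt(accu(square(Omega)));
    double nZ = std::sqrt(accu(square(Z)));
    double nY = rho * std::sqrt(accu(square(U)));
    eps_pri = root * abs_tol + rel_tol * std::max(nOmega, nZ);
    eps_dual = root * abs_tol + rel_tol * nY;
    if (r < eps_pri && s < eps_dual) { converged = true; break; }
    if (adapt_rho) {
      if (r > 10.0 * s) { rho *= 2.0; U /= 2.0; }
      else if (s > 10.0 * r) { rho /= 2.0; U *= 2.0; }
    }
  }
  // sparse estimate from the prox output, diagonals from Omega
  for (uword k = 0; k < K; ++k)
    Z.slice(k).diag() = Omega.slice(k).diag();
  return Rcpp::List::create(
      Rcpp::Named("Z") = Z, Rcpp::Named("n_iter") = std::min(it, max_iter),
      Rcpp::Named("converged") = converged, Rcpp::Named("primal_residual") = r,
      Rcpp::Named("dual_residual") = s, Rcpp::Named("eps_primal") = eps_pri,
      Rcpp::Named("eps_dual") = eps_dual, Rcpp::Named("rho") = rho);
}
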