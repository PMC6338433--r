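#' Proximal map of the sparse-group penalty
#'
#' At each off-diagonal position (i, j) the K entries are soft-thresholded
#' elementwise at \code{t2}, then the resulting K-vector is shrunk by the
#' group factor \eqn{\max(0, 1 - t3/\|\cdot\|_2)}.  Diagonals are returned
#' unchanged (they are unpenalized).  This is the exact minimizer of
#' \eqn{\frac12\|z - a\|_2^2 + t_2\|z\|_1 + t_3\|z\|_2} applied positionwise.
#'
#' @param A p x p x K array.
#' @param t2,t3 nonnegative thresholds.
#' @return p x p x K array.
#' @export
ggl_prox <- function(A, t2, t3) {
  stopifnot(t2 >= 0, t3 >= 0, length(dim(A)) == 3L)
  ggl_prox_cpp(A, t2, t3)
}

#' Closed-form log-det ADMM block update
#'
#' Minimizer of \eqn{w(\mathrm{tr}(\tilde S\Omega) - \log\det\Omega)
#' + (\rho/2)\|\Omega - \hat M\|_F^2} where the caller passes
#' \eqn{M = \rho \hat M - w \tilde S}: eigendecompose M and map each
#' eigenvalue \eqn{\ell_j} to \eqn{(\ell_j + \sqrt{\ell_j^2 + 4\rho w})
#' /(2\rho)}.  The result is positive definite for any symmetric M.
#'
#' @param M p x p symmetric matrix.
#' @param w positive cluster weight.
#' @param rho positive ADMM step.
#' @return p x p positive definite matrix.
#' @export
logdet_update <- function(M, w, rho) {
  stopifnot(w > 0, rho > 0, nrow(M) == ncol(M))
  logdet_update_cpp(as.matrix(M), w, rho)
}

#' ADMM solver for the weighted joint graphical lasso
#'
#' Maximizes \eqn{\sum_k w_k[\log\det\Omega_k - \mathrm{tr}(\tilde S_k
#' \Omega_k)] - \lambda_2 \sum_k \sum_{i\ne j}|\omega_{kij}| - \lambda_3
#' \sum_{i\ne j}(\sum_k \omega_{kij}^2)^{1/2}} over positive definite
#' \eqn{\Omega_1,\dots,\Omega_K} by consensus ADMM: closed-form log-det
#' updates per cluster, a sparse-group proximal step, a dual ascent step,
#' standard primal/dual residual stopping and step-size rescaling.  The
#' returned stack is the prox output (exact zeros in the off-diagonals)
#' with diagonals taken from the smooth block.
#'
#' @param S p x p x K array of (pseudo) sample covariance matrices.
#' @param w length-K positive weights, typically \eqn{n_k/n}.
#' @param lambda2,lambda3 nonnegative penalty levels.
#' @param options list with \code{rho}, \code{abs_tol}, \code{rel_tol},
#'   \code{max_iter}, \code{adapt_rho}; see \code{\link{scan_control}}.
#' @param warm_start optional p x p x K array used to initialize the
#'   consensus variable (defaults to inverted regularized diagonals).
#' @return p x p x K array of precision estimates, with attributes
#'   \code{n_iter}, \code{converged}, \code{primal_residual},
#'   \code{dual_residual}.
#' @export
solve_jgl <- function(S, w, lambda2, lambda3, options = list(),
                      warm_start = NULL) {
  stopifnot(length(dim(S)) == 3L, all(w > 0), lambda2 >= 0, lambda3 >= 0)
  opts <- modifyList(list(rho = 1, abs_tol = 1e-5, rel_tol = 1e-4,
                          max_iter = 500L, adapt_rho = TRUE), options)
  p <- dim(S)[1]
  K <- dim(S)[3]
  if (length(w) != K) stop("length(w) must match the number of slices")
  if (is.null(warm_start)) {
    warm_start <- array(0, c(p, p, K))
    for (k in seq_len(K))
      warm_start[, , k] <- diag(1 / pmax(diag(S[, , k]), 1e-8), p)
  }
  res <- solve_jgl_cpp(S, w, lambda2, lambda3, opts$rho, opts$abs_tol,
                       opts$rel_tol, as.integer(opts$max_iter),
                       warm_start, isTRUE(opts$adapt_rho))
  if (!res$converged &&
      (res$primal_residual > 10 * res$eps_primal ||
       res$dual_residual > 10 * res$eps_dual))
    stop(sprintf(paste0("ADMM did not converge in %d iterations ",
                        "(primal residual %.3g vs %.3g, dual %.3g vs %.3g)"),
                 opts$max_iter, res$primal_residual, res$eps_primal,
                 res$dual_residual, res$eps_dual))
  Z <- res$Z
  attr(Z, "n_iter") <- res$n_iter
  attr(Z, "converged") <- res$converged
  attr(Z, "primal_residual") <- res$primal_residual
  attr(Z, "dual_residual") <- res$dual_residual
  Z
}

#' Objective of the weighted joint graphical lasso
#'
#' \eqn{\sum_k w_k[\log\det\Omega_k - \mathrm{tr}(\tilde S_k\Omega_k)]
#' - \lambda_2 P_2 - \lambda_3 P_3}; used for solver diagnostics and
#' cross-checking.
#'
#' @param omega p x p x K array of positive definite matrices.
#' @inheritParams solve_jgl
#' @return The objective value.
#' @export
jgl_objective <- function(omega, S, w, lambda2, lambda3) {
  p <- dim(S)[1]
  off <- !diag(p)
  val <- 0
  sq <- matrix(0, p, p)
  for (k in seq_len(dim(S)[3])) {
    O <- omega[, , k]
    val <- val + w[k] * (determinant(O, logarithm = TRUE)$modulus -
                           sum(S[, , k] * O))
    val <- val - lambda2 * sum(abs(O[off]))
    sq <- sq + O^2
  }
  as.numeric(val - lambda3 * sum(sqrt(sq[off])))
}
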