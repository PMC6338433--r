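#' Construct a Gaussian graphical mixture model object
#'
#' Bundles the parameters of a K-component Gaussian mixture with
#' cluster-specific precision matrices: mixing weights \eqn{\pi_k}, mean
#' vectors \eqn{\mu_k} and precision matrices \eqn{\Omega_k = \Sigma_k^{-1}}.
#'
#' @param weights length-K vector on the probability simplex.
#' @param means K x p matrix; row k is \eqn{\mu_k}.
#' @param precisions p x p x K array; slice k is \eqn{\Omega_k}, symmetric
#'   positive definite.
#' @param check validate invariants (simplex weights, symmetric PD
#'   precisions)?  Default \code{TRUE}.
#' @return An object of class \code{"mixture_ggm"}: a list with elements
#'   \code{K}, \code{p}, \code{weights}, \code{means}, \code{precisions}.
#' @export
mixture_ggm <- function(weights, means, precisions, check = TRUE) {
  means <- as.matrix(means)
  K <- length(weights)
  p <- ncol(means)
  if (length(dim(precisions)) != 3L)
    stop("'precisions' must be a p x p x K array")
  if (check) {
    if (any(weights < 0) || abs(sum(weights) - 1) > 1e-10)
      stop("'weights' must be nonnegative and sum to 1")
    if (nrow(means) != K || dim(precisions)[3] != K)
      stop("'means' and 'precisions' must have one slice per component")
    if (!all(dim(precisions)[1:2] == p))
      stop("'precisions' slices must be p x p")
    for (k in seq_len(K)) {
      O <- precisions[, , k]
      if (max(abs(O - t(O))) > 1e-8)
        stop("precision matrix ", k, " is not symmetric")
      ev <- min(eigen(O, symmetric = TRUE, only.values = TRUE)$values)
      if (ev <= 0)
        stop("precision matrix ", k, " is not positive definite ",
             "(min eigenvalue ", format(ev), ")")
    }
  }
  structure(list(K = K, p = p, weights = as.numeric(weights),
                 means = means, precisions = precisions),
            class = "mixture_ggm")
}

#' Log density of one multivariate Gaussian component
#'
#' Evaluates \eqn{\log f(x; \mu, \Omega)} for a Gaussian parameterized by
#' its precision matrix, through the Cholesky factor of \eqn{\Omega} (the
#' covariance is never formed): \eqn{-(p/2)\log 2\pi + \frac12 \log|\Omega|
#' - \frac12 (x-\mu)^\top \Omega (x-\mu)}.
#'
#' @param x length-p numeric vector.
#' @param mu length-p mean vector.
#' @param omega p x p symmetric positive definite precision matrix.
#' @return The log density, a single number.
#' @export
log_component_density <- function(x, mu, omega) {
  R <- chol_precision(omega)
  p <- length(x)
  d <- R %*% (x - mu)
  -0.5 * p * log(2 * pi) + sum(log(diag(R))) - 0.5 * sum(d * d)
}

# Cholesky with an explicit PD error message.
chol_precision <- function(omega) {
  tryCatch(chol(omega), error = function(e)
    stop("precision matrix is not positive definite (Cholesky failed)",
         call. = FALSE))
}

# n x K matrix of per-component log densities log f_k(x_i), vectorized
# over samples through the Cholesky factor of each Omega_k.
log_density_matrix <- function(X, model) {
  n <- nrow(X)
  out <- matrix(0, n, model$K)
  for (k in seq_len(model$K)) {
    R <- chol_precision(model$precisions[, , k])
    Xc <- sweep(X, 2L, model$means[k, ], "-")
    q <- rowSums((Xc %*% t(R))^2)
    out[, k] <- -0.5 * model$p * log(2 * pi) + sum(log(diag(R))) - 0.5 * q
  }
  out
}

#' Observed-data log likelihood of a Gaussian graphical mixture
#'
#' Computes \eqn{\sum_i \log \sum_k \pi_k f_k(x_i)} with the log-sum-exp
#' trick.  Unpenalized; penalties are applied by callers.
#'
#' @param X n x p data matrix.
#' @param model a \code{\link{mixture_ggm}}.
#' @return The total log likelihood (a sum over samples, not a mean).
#' @export
observed_loglik <- function(X, model) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty data matrix")
  lp <- sweep(log_density_matrix(X, model), 2L, log(model$weights), "+")
  sum(log_row_sum_exp(lp))
}

log_row_sum_exp <- function(lp) {
  m <- apply(lp, 1L, max)
  m + log(rowSums(exp(lp - m)))
}

#' E-step: posterior cluster responsibilities
#'
#' Computes the n x K matrix of posterior membership probabilities
#' \eqn{\pi_k f_k(x_i) / \sum_j \pi_j f_j(x_i)} in log space, with rows
#' renormalized to remove rounding drift.
#'
#' @inheritParams observed_loglik
#' @return A list of class \code{"scan_resp"} with \code{matrix} (n x K,
#'   rows summing to 1), \code{masses} (column sums \eqn{n_k}),
#'   \code{loglik} (observed-data log likelihood, a by-product of the
#'   same densities) and \code{loglik_rows} (its per-sample terms).
#' @export
e_step <- function(X, model) {
  X <- as.matrix(X)
  lp <- sweep(log_density_matrix(X, model), 2L, log(model$weights), "+")
  m <- apply(lp, 1L, max)
  bad <- !is.finite(m)
  if (any(bad))
    stop("all component densities underflow for row(s) ",
         paste(which(bad), collapse = ", "))
  r <- exp(lp - m)
  rs <- rowSums(r)
  ll_rows <- m + log(rs)
  r <- r / rs
  structure(list(matrix = r, masses = colSums(r), loglik = sum(ll_rows),
                 loglik_rows = ll_rows), class = "scan_resp")
}

#' CM-step update of the mixing weights
#'
#' \eqn{\pi_k = n_k / n} where \eqn{n_k} is the posterior mass of cluster
#' k.  Near-empty clusters (\eqn{n_k < K \cdot \epsilon \cdot n}) are
#' floored and the weights renormalized onto the simplex, with a warning,
#' rather than aborting.
#'
#' @param resp a responsibility object from \code{\link{e_step}} (or a
#'   bare n x K matrix with rows summing to 1).
#' @param n number of samples.
#' @param eps empty-cluster floor constant (default \code{1e-8}).
#' @return Length-K weight vector on the simplex.
#' @export
update_weights <- function(resp, n, eps = 1e-8) {
  masses <- if (inherits(resp, "scan_resp")) resp$masses else colSums(resp)
  K <- length(masses)
  w <- masses / n
  floor_at <- K * eps
  if (any(w < floor_at)) {
    warning("near-empty cluster(s): ",
            paste(which(w < floor_at), collapse = ", "),
            "; flooring weight at ", format(floor_at))
    w <- pmax(w, floor_at)
    w <- w / sum(w)
  }
  w
}
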