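#' Sparse cluster mean patterns
#'
#' The three-class mean pattern used by the simulation scenarios: the
#' first 10 coordinates of class 1 are \eqn{(\mu \mathbf 1_5, -\mu
#' \mathbf 1_5)}, class 2 is \eqn{\mu \mathbf 1_{10}}, class 3 is
#' \eqn{-\mu \mathbf 1_{10}}; the remaining p - 10 coordinates are zero.
#'
#' @param p feature dimension (at least 10).
#' @param K number of classes (3).
#' @param mu mean magnitude.
#' @return K x p matrix of class means.
#' @export
make_mean_vectors <- function(p, K = 3L, mu) {
  if (p < 10) stop("p must be at least 10")
  if (K != 3L) stop("the mean pattern is defined for K = 3")
  m <- matrix(0, K, p)
  m[1, 1:10] <- c(rep(mu, 5), rep(-mu, 5))
  m[2, 1:10] <- mu
  m[3, 1:10] <- -mu
  m
}

block_diag <- function(blocks) {
  p <- sum(vapply(blocks, nrow, integer(1)))
  M <- matrix(0, p, p)
  at <- 0L
  for (B in blocks) {
    idx <- at + seq_len(nrow(B))
    M[idx, idx] <- B
    at <- at + nrow(B)
  }
  M
}

# Tridiagonal matrix: unit diagonal, value `off` on the first off-diagonal.
tridiag_block <- function(size, off) {
  B <- diag(1, size)
  if (size > 1) {
    i <- seq_len(size - 1)
    B[cbind(i, i + 1)] <- off
    B[cbind(i + 1, i)] <- off
  }
  B
}

# One scale-free block precision seed: preferential-attachment graph
# (1 edge per new node), unit diagonal, edge weights Unif(+-[0.1, 0.4]),
# rows rescaled so each off-diagonal absolute row sum is 0.9 (strict
# diagonal dominance), then averaged with the transpose.
powerlaw_block <- function(size) {
  g <- igraph::sample_pa(size, power = 1, m = 1, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  W <- diag(1, size)
  for (r in seq_len(nrow(el))) {
    wgt <- runif(1, 0.1, 0.4) * sample(c(-1, 1), 1)
    W[el[r, 1], el[r, 2]] <- wgt
    W[el[r, 2], el[r, 1]] <- wgt
  }
  s <- rowSums(abs(W)) - 1
  for (i in seq_len(size)) for (j in seq_len(size)) {
    if (i == j || W[i, j] == 0) next
    # symmetric row normalization: each entry shrunk by the larger of its
    # two row sums, so every row's off-diagonal absolute sum is at most
    # 0.9 and the matrix stays symmetric and strictly diagonally dominant
    # (plain per-row rescaling followed by transpose averaging loses
    # dominance at hub columns of a scale-free graph)
    W[i, j] <- W[i, j] * 0.9 / max(s[i], s[j])
  }
  W
}

# Covariance block from a diagonally dominant seed A:
# Sigma_ij = d_ij (A^-1)_ij / sqrt((A^-1)_ii (A^-1)_jj) with d_ij = 0.9
# off the diagonal and 1 on it (so the diagonal is exactly 1).
cov_from_seed <- function(A) {
  Ainv <- solve(A)
  dd <- sqrt(diag(Ainv))
  S <- 0.9 * Ainv / outer(dd, dd)
  diag(S) <- 1
  (S + t(S)) / 2
}

# Chain (AR-decay) covariance block: entries exp(-a |s_i - s_j|) with
# ordered sites whose increments are Unif(0.5, 1).
chain_block <- function(size, a) {
  s <- cumsum(c(0, runif(size - 1, 0.5, 1)))
  exp(-a * abs(outer(s, s, "-")))
}

#' Construct a simulation scenario
#'
#' Materializes the ground truth (class means, covariance and precision
#' matrices) for one of three network families, all with K = 3 balanced
#' latent classes:
#' \describe{
#'   \item{\code{"regular"}}{block-diagonal precisions with
#'     \code{n_blocks} (default 5) equal tridiagonal blocks; the first
#'     off-diagonal entries are \eqn{\eta}, \eqn{0.99\eta}, \eqn{1.01\eta}
#'     for classes 1-3 and diagonals are 1.}
#'   \item{\code{"powerlaw"}}{ten equal blocks, each a scale-free
#'     (preferential-attachment) graph with edge weights drawn from
#'     \eqn{\pm[0.1, 0.4]}, row-rescaled to strict diagonal dominance and
#'     symmetrized; covariances via the correlation-normalized inverse
#'     with off-diagonal damping 0.9.  Class 2 resets the last block of
#'     \eqn{\Sigma} to the identity; class 3 resets the last two.}
#'   \item{\code{"chain"}}{ten equal blocks with AR-decay covariance
#'     entries \eqn{\exp(-a|s_i - s_j|)}, site increments Unif(0.5, 1);
#'     the same identity-block resets for classes 2 and 3.  Block
#'     precisions are tridiagonal by the Markov property.}
#' }
#' Means follow \code{\link{make_mean_vectors}}.
#'
#' @param family \code{"regular"}, \code{"powerlaw"} or \code{"chain"}.
#' @param p feature dimension (default 100; divisible by \code{n_blocks}
#'   for \code{"regular"}, by 10 otherwise).
#' @param n default sample size carried by the scenario (default 300).
#' @param mu mean magnitude.
#' @param eta tridiagonal off-diagonal magnitude (regular family).
#' @param a decay rate (chain family, default 1).
#' @param n_blocks number of tridiagonal blocks for the regular family
#'   (default 5).
#' @param seed integer seed; the scenario is deterministic given it.
#' @return An object of class \code{"scan_scenario"}: the generating
#'   \code{\link{mixture_ggm}} (\code{$true_model}), covariance stack
#'   (\code{$sigma}), and the scenario parameters.
#' @export
scan_scenario <- function(family = c("regular", "powerlaw", "chain"),
                          p = 100L, n = 300L, mu = 1, eta = 0.4, a = 1,
                          n_blocks = 5L, seed = 1L) {
  family <- match.arg(family)
  K <- 3L
  set.seed(seed)
  if (family == "regular") {
    if (p %% n_blocks != 0)
      stop("p must be divisible by the block count")
    bs <- p %/% n_blocks
    omega <- array(0, c(p, p, K))
    sigma <- array(0, c(p, p, K))
    fac <- c(1, 0.99, 1.01)
    for (k in 1:K) {
      O <- block_diag(replicate(n_blocks, tridiag_block(bs, eta * fac[k]),
                                simplify = FALSE))
      ev <- min(eigen(O, symmetric = TRUE, only.values = TRUE)$values)
      if (ev <= 0)
        stop("tridiagonal precision not positive definite ",
             "(min eigenvalue ", format(ev), "); reduce eta")
      omega[, , k] <- O
      sigma[, , k] <- chol2inv(chol(O))
    }
  } else {
    if (p %% 10 != 0) stop("p must be divisible by 10")
    bs <- p %/% 10L
    for (attempt in 1:10) {
      if (attempt > 1) set.seed(seed + 1000000L * attempt)
      blocks <- replicate(10, switch(family,
                                     powerlaw = cov_from_seed(powerlaw_block(bs)),
                                     chain = chain_block(bs, a)),
                          simplify = FALSE)
      sig1 <- blocks
      sig2 <- blocks; sig2[[10]] <- diag(1, bs)
      sig3 <- sig2; sig3[[9]] <- diag(1, bs)
      sigma <- array(0, c(p, p, K))
      sigma[, , 1] <- block_diag(sig1)
      sigma[, , 2] <- block_diag(sig2)
      sigma[, , 3] <- block_diag(sig3)
      ok <- all(vapply(1:K, function(k)
        min(eigen(sigma[, , k], symmetric = TRUE,
                  only.values = TRUE)$values) > 1e-8, logical(1)))
      if (ok) break
      if (attempt == 10) stop("failed to generate a PD covariance stack")
    }
    omega <- array(0, c(p, p, K))
    for (k in 1:K) omega[, , k] <- chol2inv(chol(sigma[, , k]))
  }
  means <- make_mean_vectors(p, K, mu)
  structure(list(family = family, p = as.integer(p), K = K,
                 n = as.integer(n), mu = mu, eta = eta, a = a,
                 n_blocks = as.integer(n_blocks), seed = as.integer(seed),
                 sigma = sigma,
                 true_model = mixture_ggm(rep(1 / K, K), means, omega,
                                          check = FALSE)),
            class = "scan_scenario")
}

#' @export
print.scan_scenario <- function(x, ...) {
  cat(sprintf("scenario '%s': p = %d, K = %d, n = %d, mu = %g%s, seed %d\n",
              x$family, x$p, x$K, x$n, x$mu,
              if (x$family == "regular") sprintf(", eta = %g", x$eta) else "",
              x$seed))
  invisible(x)
}

#' Draw a labeled dataset from a scenario
#'
#' Labels are i.i.d. uniform on the K classes; each sample is drawn from
#' its class Gaussian through the Cholesky factor of \eqn{\Sigma_k}.
#' Deterministic given \code{seed}.
#'
#' @param scenario a \code{"scan_scenario"}.
#' @param n sample size (defaults to the scenario's).
#' @param seed integer seed (defaults to the scenario's).
#' @return List with \code{X} (n x p matrix) and \code{labels} (length-n
#'   integers in 1..K).
#' @export
sample_scenario <- function(scenario, n = scenario$n,
                            seed = scenario$seed) {
  set.seed(seed)
  K <- scenario$K
  p <- scenario$p
  labels <- sample.int(K, n, replace = TRUE)
  X <- matrix(rnorm(n * p), n, p)
  for (k in seq_len(K)) {
    idx <- labels == k
    if (!any(idx)) next
    R <- chol(scenario$sigma[, , k])
    X[idx, ] <- sweep(X[idx, , drop = FALSE] %*% R, 2L,
                      scenario$true_model$means[k, ], "+")
  }
  list(X = X, labels = labels)
}

#' Two-dimensional correlated-cluster illustration data
#'
#' n = 1000 points in the plane, 500 per class, from
#' \eqn{N(\mu_1, \Sigma)} and \eqn{N(\mu_2, \Sigma)} with
#' \eqn{\mu_1 = (0, 1)}, \eqn{\mu_2 = (0, -1)} and a shared strongly
#' correlated covariance (unit variances, correlation 0.8).  The strong
#' off-diagonal covariance makes the clusters highly non-spherical, the
#' setting in which distance-based K-means fails while the mixture fit
#' does not.
#'
#' @param seed integer seed.
#' @return List with \code{X} (1000 x 2), \code{labels}, and the
#'   generating \code{\link{mixture_ggm}} (\code{$true_model}).
#' @export
make_illustration_2d <- function(seed = 1L) {
  set.seed(seed)
  Sigma <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
  R <- chol(Sigma)
  means <- rbind(c(0, 1), c(0, -1))
  X <- matrix(rnorm(2000), 1000, 2) %*% R
  labels <- rep(1:2, each = 500)
  X <- X + means[labels, ]
  omega <- array(0, c(2, 2, 2))
  omega[, , 1] <- omega[, , 2] <- solve(Sigma)
  list(X = X, labels = labels,
       true_model = mixture_ggm(c(0.5, 0.5), means, omega, check = FALSE))
}

#' Export scenario ground truth as plain-text files
#'
#' Writes the class means (TSV), one weighted edge list per class
#' (feature_i, feature_j, omega value for the nonzero upper-triangular
#' entries) and a metadata file with the scenario parameters.
#'
#' @param scenario a \code{"scan_scenario"}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
export_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(scenario$true_model$means, file.path(dir, "means.tsv"),
              sep = "\t", row.names = FALSE, col.names = FALSE)
  up <- which(upper.tri(matrix(0, scenario$p, scenario$p)), arr.ind = TRUE)
  for (k in seq_len(scenario$K)) {
    O <- scenario$true_model$precisions[, , k]
    v <- O[up]
    keep <- abs(v) > 1e-8
    write.table(data.frame(i = up[keep, 1], j = up[keep, 2],
                           weight = v[keep]),
                file.path(dir, sprintf("network_class%d.tsv", k)),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  meta <- scenario[c("family", "p", "K", "n", "mu", "eta", "a",
                     "n_blocks", "seed")]
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "scenario.json"))
  invisible(dir)
}
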