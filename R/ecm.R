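#' Value of the sparse-group penalty
#'
#' \eqn{R(\Theta) = \lambda_1 \sum_k \sum_j |\mu_{kj}|
#'   + \lambda_2 \sum_k \sum_{i \ne j} |\omega_{kij}|
#'   + \lambda_3 \sum_{i \ne j} (\sum_k \omega_{kij}^2)^{1/2}}.
#' Off-diagonal sums run over both \eqn{(i,j)} and \eqn{(j,i)}; precision
#' diagonals are never penalized.
#'
#' @param model a \code{\link{mixture_ggm}}.
#' @param lambda1,lambda2,lambda3 nonnegative penalty levels for the mean
#'   lasso, the per-matrix off-diagonal lasso and the cross-cluster group
#'   penalty.
#' @return The penalty value, a single nonnegative number.
#' @export
penalty_value <- function(model, lambda1, lambda2, lambda3) {
  p <- model$p
  off <- !diag(p)
  p2 <- 0
  sq <- matrix(0, p, p)
  for (k in seq_len(model$K)) {
    O <- model$precisions[, , k]
    p2 <- p2 + sum(abs(O[off]))
    sq <- sq + O^2
  }
  lambda1 * sum(abs(model$means)) + lambda2 * p2 +
    lambda3 * sum(sqrt(sq[off]))
}

#' CM-step update of the sparse cluster means
#'
#' Coordinatewise maximization of the penalized conditional expected
#' complete log likelihood with a lasso penalty on the means, the
#' responsibilities and precision matrices held at the previous iterate.
#' For cluster k and coordinate j the unpenalized stationary point is
#' \eqn{g_{1,j} = \mu_{kj} + [(\bar x_k - \mu_k)^\top
#' \Omega_k^{(t-1)}]_j / \omega_{kjj}^{(t-1)}} with \eqn{\bar x_k} the
#' responsibility-weighted sample mean; the update soft-thresholds it at
#' \eqn{n\lambda_1 / (n_k \omega_{kjj}^{(t-1)})}.  Coordinates are swept
#' sequentially, each one evaluated at the current partially updated mean
#' vector, so each 1-D update is an exact maximization and the sweep never
#' decreases the objective (a simultaneous one-shot update of all
#' coordinates can overshoot under a non-diagonal precision).
#'
#' @param X n x p data matrix.
#' @param resp responsibilities from \code{\link{e_step}} under the
#'   previous iterate.
#' @param prev the previous-iterate \code{\link{mixture_ggm}}.
#' @param lambda1 nonnegative mean-lasso level.
#' @return K x p matrix of updated means.
#' @export
update_means <- function(X, resp, prev, lambda1) {
  X <- as.matrix(X)
  L <- resp$matrix
  n <- nrow(X)
  out <- matrix(0, prev$K, prev$p)
  for (k in seq_len(prev$K)) {
    O <- prev$precisions[, , k]
    d <- diag(O)
    if (any(d <= 0))
      stop("precision matrix ", k, " has a nonpositive diagonal entry")
    nk <- sum(L[, k])
    if (nk <= 0) stop("cluster ", k, " has zero responsibility mass")
    xbar <- colSums(L[, k] * X) / nk
    mu <- prev$means[k, ]
    thr <- n * lambda1 / (nk * d)
    for (j in seq_len(prev$p)) {
      g1 <- mu[j] + sum((xbar - mu) * O[, j]) / d[j]
      mu[j] <- sign(g1) * max(abs(g1) - thr[j], 0)
    }
    out[k, ] <- mu
  }
  out
}

#' Responsibility-weighted pseudo sample covariances
#'
#' \eqn{\tilde S_k = \sum_i L_{ik} (x_i - \mu_k)(x_i - \mu_k)^\top / n_k},
#' the sufficient statistic for the precision CM-step.  Per the ECM
#' schedule the means passed in are the previous-iterate \eqn{\mu_k^{(t-1)}}.
#'
#' @inheritParams update_means
#' @param means K x p matrix of centering means.
#' @return p x p x K array of symmetric positive semidefinite matrices.
#' @export
pseudo_covariances <- function(X, resp, means) {
  X <- as.matrix(X)
  L <- resp$matrix
  K <- ncol(L)
  p <- ncol(X)
  S <- array(0, c(p, p, K))
  for (k in seq_len(K)) {
    nk <- sum(L[, k])
    if (nk <= 0) stop("cluster ", k, " has zero responsibility mass")
    Xc <- sweep(X, 2L, means[k, ], "-")
    Sk <- crossprod(Xc, Xc * L[, k]) / nk
    S[, , k] <- (Sk + t(Sk)) / 2
  }
  S
}

#' Min-magnitude symmetrization of a precision stack
#'
#' For each off-diagonal pair keeps the entry of smaller absolute value and
#' assigns it to both positions; diagonals untouched.  This is the standard
#' CLIME-style symmetrization applied after the (not necessarily symmetric)
#' precision update.
#'
#' @param omega_stack p x p x K array.
#' @return The symmetrized p x p x K array.
#' @export
symmetrize_minmag <- function(omega_stack) {
  attributes(omega_stack) <- list(dim = dim(omega_stack))
  K <- dim(omega_stack)[3]
  p <- dim(omega_stack)[1]
  up <- upper.tri(matrix(0, p, p))
  for (k in seq_len(K)) {
    O <- omega_stack[, , k]
    Ot <- t(O)
    v <- ifelse(abs(O[up]) <= abs(Ot[up]), O[up], Ot[up])
    O[up] <- v
    O <- t(O)
    O[up] <- v
    omega_stack[, , k] <- t(O)
  }
  omega_stack
}

#' Control parameters for the ECM fit
#'
#' @param max_iter maximum ECM iterations.  The default (\code{NULL})
#'   resolves at fit time to 2 when \eqn{p \ge n/4} and 200 otherwise:
#'   once the initialization is at statistical accuracy, the number of
#'   contraction steps worth taking scales with the log of the ratio of
#'   initial to statistical error, which is O(1) in the high-dimensional
#'   regime -- and empirically, additional sweeps there let the
#'   cluster-specific precisions absorb noise and degrade the clustering
#'   rather than improve it.
#' @param rel_tol termination constant for the summed relative parameter
#'   change statistic (default 0.01).
#' @param obj_tol secondary stop: relative change of the penalized
#'   objective below this declares convergence (default 1e-8).
#' @param n_restarts number of restarts (default 5); the fit with the
#'   lowest adaptive BIC is kept (a wrong clustering with denser
#'   parameters can always out-score the sparse truthful one on raw
#'   penalized likelihood when p is comparable to n).
#' @param init_method \code{"kmeans_warm"} (default: K-means centroids
#'   plus pooled within-cluster diagonal precision) or
#'   \code{"random_responsibility"} (anchored random soft assignment,
#'   weighted means, shrunken diagonal precisions).  At dimensions
#'   comparable to the sample size the penalized likelihood surface has
#'   many spurious optima and the warm start keeps the fit in the basin
#'   of a meaningful clustering; random starts remain useful at low
#'   dimension.
#' @param patience stop a run after this many iterations without an
#'   improvement of the adaptive BIC (default 10); the best-BIC iterate
#'   is what the run returns.
#' @param pi_update \code{"fixed"} (default) holds the mixing weights at
#'   the uniform value 1/K throughout the iteration, the value the
#'   uniform-label sampling design assumes; \code{"em"} re-estimates them
#'   each sweep as the posterior masses \eqn{n_k/n}.  The EM update
#'   creates a positive feedback loop at dimensions comparable to the
#'   sample size (a cluster that loses mass is further down-weighted in
#'   the next E-step until it collapses to a degenerate quasi-singleton),
#'   so the uniform-weight conditional maximization is the default.
#' @param eps empty-cluster floor constant passed to
#'   \code{\link{update_weights}}.
#' @param min_mass minimum posterior mass a cluster may carry before it is
#'   treated as degenerate and re-seeded (once; a second collapse ends the
#'   run, which then returns its best earlier iterate).  \code{NULL}
#'   (default) resolves to \code{max(K + 1, n/(2K))} at fit time: under a
#'   balanced-label design a cluster that has lost more than half its
#'   expected share is already absorbing into a neighbour, and a shrinking
#'   component turns into a quasi-singleton Gaussian whose unpenalized
#'   precision diagonal inflates the likelihood (and the BIC) without
#'   bound.  Lower it explicitly for strongly unbalanced populations.
#' @param admm control list for the ADMM subproblem solver: \code{rho},
#'   \code{abs_tol}, \code{rel_tol}, \code{max_iter}, \code{adapt_rho}.
#' @param verbose print per-iteration objectives?
#' @return A list of class \code{"scan_control"}.
#' @export
scan_control <- function(max_iter = NULL, rel_tol = 0.01, obj_tol = 1e-8,
                         n_restarts = 5L,
                         init_method = c("kmeans_warm",
                                         "random_responsibility"),
                         pi_update = c("fixed", "em"),
                         patience = 10L,
                         eps = 1e-8, min_mass = NULL,
                         admm = list(), verbose = FALSE) {
  stopifnot(is.null(max_iter) || max_iter >= 1, rel_tol > 0)
  admm_defaults <- list(rho = 1, abs_tol = 1e-5, rel_tol = 1e-4,
                        max_iter = 500L, adapt_rho = TRUE)
  structure(list(max_iter = if (!is.null(max_iter)) as.integer(max_iter),
                 rel_tol = rel_tol,
                 obj_tol = obj_tol, n_restarts = as.integer(n_restarts),
                 init_method = match.arg(init_method),
                 pi_update = match.arg(pi_update),
                 patience = as.integer(patience), eps = eps,
                 min_mass = min_mass,
                 admm = modifyList(admm_defaults, admm),
                 verbose = isTRUE(verbose)),
            class = "scan_control")
}

#' Random initialization of the mixture parameters
#'
#' Weights start uniform at 1/K.  The \code{"random_responsibility"} method
#' draws a random soft assignment, takes responsibility-weighted means and
#' shrunken diagonal variances and inverts them; \code{"kmeans_warm"} uses
#' Lloyd centroids and a pooled diagonal precision.  Deterministic given
#' \code{seed}.
#'
#' @param X n x p data matrix.
#' @param K number of clusters.
#' @param seed integer seed.
#' @param init_method see \code{\link{scan_control}}.
#' @return A valid \code{\link{mixture_ggm}}.
#' @export
initialize_scan <- function(X, K,
                            init_method = c("kmeans_warm",
                                            "random_responsibility"),
                            seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (K > n) stop("K exceeds the number of samples")
  init_method <- match.arg(init_method)
  set.seed(seed)
  prec <- array(0, c(p, p, K))
  if (init_method == "random_responsibility") {
    # random soft assignment anchored at K spread-out random samples
    # (k-means++-style sampling), each point assigned mostly to its
    # nearest anchor with a uniform blend; i.i.d. random responsibilities
    # would leave the K components statistically identical (their weighted
    # means all collapse to the grand mean), which high-dimensional ECM
    # cannot recover from
    anchors <- kmeanspp_centers(X, K)
    d2 <- vapply(seq_len(K), function(k)
      colSums((t(X) - anchors[k, ])^2), numeric(n))
    d2 <- matrix(d2, n, K)
    r <- matrix(0.1 / K, n, K)
    r[cbind(seq_len(n), max.col(-d2, ties.method = "first"))] <- 0
    r <- r + 0.9 * (r == 0)
    r <- r / rowSums(r)
    means <- matrix(0, K, p)
    v <- matrix(0, K, p)
    for (k in seq_len(K)) {
      nk <- sum(r[, k])
      means[k, ] <- colSums(r[, k] * X) / nk
      Xc <- sweep(X, 2L, means[k, ], "-")
      v[k, ] <- colSums(r[, k] * Xc^2) / nk
    }
    # shrink towards the pooled within-cluster variance to keep the start
    # well conditioned without washing out between-cluster separation
    vbar <- colMeans(v)
    for (k in seq_len(K))
      prec[, , k] <- diag(1 / pmax(0.5 * v[k, ] + 0.5 * vbar, 1e-8), p)
  } else {
    # variance-screened K-means warm start: under a sparse-mean mixture
    # only a few coordinates carry clustering signal, and their marginal
    # variance is inflated by the between-cluster separation -- screening
    # on marginal variance before K-means removes the noise coordinates
    # that otherwise dominate Euclidean distances at p ~ n.  The K-means
    # partition is then refined by a short full-covariance EM in the
    # screened space (n is large relative to that dimension), which fixes
    # the distance-based errors K-means makes under correlated noise.
    v <- apply(X, 2L, stats::var)
    keep <- which(v > 1.25 * stats::median(v))
    cap <- max(2L, floor(n / 10))
    if (length(keep) > cap) keep <- keep[order(v[keep],
                                               decreasing = TRUE)][1:cap]
    if (length(keep) < 2L) keep <- seq_len(p)
    Xs <- X[, keep, drop = FALSE]
    # rotate restarts over three screened-space partitioners -- raw
    # K-means, K-means refined by a short full-covariance EM, and Ward
    # hierarchical linkage: their failure modes differ (K-means can lock
    # onto a wrong WCSS optimum, the EM refinement can overfit elongated
    # noise, Ward is robust to both but greedier), and the adaptive-BIC
    # comparison across restarts arbitrates
    variant <- seed %% 3L
    if (variant == 2L && n <= 3000L) {
      hc <- stats::hclust(stats::dist(Xs), method = "ward.D2")
      labels <- stats::cutree(hc, K)
      if (length(unique(labels)) < K) variant <- 0L
    }
    if (variant != 2L || n > 3000L) {
      km <- suppressWarnings(stats::kmeans(Xs, K, nstart = 20L,
                                           iter.max = 50L))
      labels <- km$cluster
      if (variant == 1L) {
        r <- refine_screened_em(Xs, km$cluster, K)
        lab2 <- max.col(r, ties.method = "first")
        if (length(unique(lab2)) == K) labels <- lab2
      }
    }
    means <- t(vapply(seq_len(K), function(k)
      colMeans(X[labels == k, , drop = FALSE]), numeric(p)))
    # pooled WITHIN-cluster variances: marginal variances would count the
    # between-cluster mean separation as noise and down-weight exactly the
    # discriminative coordinates in the first E-step
    res <- X - means[labels, , drop = FALSE]
    wv <- pmax(colSums(res^2) / n, 1e-8)
    prec[] <- rep(diag(1 / wv, p), K)
  }
  mixture_ggm(rep(1 / K, K), means, prec, check = FALSE)
}

# Short unpenalized full-covariance EM (uniform weights, ridge-stabilized
# covariances) in the low-dimensional screened space; returns the final
# responsibility matrix.
refine_screened_em <- function(Xs, labels, K, iters = 30L, ridge = 1e-3) {
  n <- nrow(Xs)
  ps <- ncol(Xs)
  mu <- t(vapply(seq_len(K), function(k)
    colMeans(Xs[labels == k, , drop = FALSE]), numeric(ps)))
  Sg <- lapply(seq_len(K), function(k)
    stats::cov(Xs[labels == k, , drop = FALSE]) + ridge * diag(ps))
  r <- NULL
  for (it in seq_len(iters)) {
    lp <- vapply(seq_len(K), function(k) {
      R <- tryCatch(chol(Sg[[k]]), error = function(e) NULL)
      if (is.null(R)) return(rep(-Inf, n))
      Xc <- sweep(Xs, 2L, mu[k, ], "-")
      -sum(log(diag(R))) - 0.5 * rowSums((Xc %*% chol2inv(R)) * Xc)
    }, numeric(n))
    lp <- matrix(lp, n, K)
    r <- exp(lp - apply(lp, 1L, max))
    r <- r / rowSums(r)
    for (k in seq_len(K)) {
      nk <- sum(r[, k])
      if (nk < 1) next
      mu[k, ] <- colSums(r[, k] * Xs) / nk
      Xc <- sweep(Xs, 2L, mu[k, ], "-")
      Sg[[k]] <- crossprod(Xc, Xc * r[, k]) / nk + ridge * diag(ps)
    }
  }
  r
}

# Penalized observed-data objective on the (1/n) likelihood scale.
penalized_objective <- function(X, model, lambda1, lambda2, lambda3) {
  observed_loglik(X, model) / nrow(X) -
    penalty_value(model, lambda1, lambda2, lambda3)
}

#' Fit a sparse Gaussian graphical mixture by penalized ECM
#'
#' Alternates the E-step with conditional maximization of the mixing
#' weights, the lasso-penalized means and the jointly penalized precision
#' matrices (weighted joint graphical lasso via ADMM, followed by
#' min-magnitude symmetrization).  Iterates until the summed relative
#' parameter change
#' \eqn{\sum_k \{\|\Delta\mu_k\|_2/\|\mu_k^{(t)}\|_2 +
#' \|\Delta\Omega_k\|_F/\|\Omega_k^{(t)}\|_F\}} drops below
#' \code{control$rel_tol}, the objective stalls, or \code{max_iter} is
#' reached.  Across \code{n_restarts} initializations the fit with the
#' lowest adaptive BIC is kept.
#'
#' @param x n x p numeric data matrix (samples in rows).
#' @param K number of clusters.
#' @param lambda1,lambda2,lambda3 nonnegative penalty levels (mean lasso,
#'   off-diagonal lasso, cross-cluster group penalty).
#' @param control a \code{\link{scan_control}} list.
#' @param seed integer; restart r uses \code{seed + r - 1}.
#' @return An object of class \code{"scan_ggm"}: the fitted
#'   \code{\link{mixture_ggm}} (\code{$model}), responsibilities
#'   (\code{$resp}), hard labels (\code{$labels}, 1-based), iteration trace
#'   (\code{$trace}: penalized objective and parameter-change statistic per
#'   iteration), convergence flag, BIC (\code{$bic}) and bookkeeping.
#' @examples
#' sc <- scan_scenario("regular", p = 20, n = 90, mu = 1, eta = 0.4, seed = 1)
#' d <- sample_scenario(sc)
#' fit <- scan_ggm(d$X, K = 3, lambda1 = 0.05, lambda2 = 0.05,
#'                 lambda3 = 0.02, seed = 1,
#'                 control = scan_control(n_restarts = 2))
#' clustering_error(fit$labels, d$labels)
#' @export
scan_ggm <- function(x, K, lambda1, lambda2, lambda3,
                     control = scan_control(), seed = 1L) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("'x' contains non-finite entries")
  stopifnot(lambda1 >= 0, lambda2 >= 0, lambda3 >= 0, K >= 1)
  best <- NULL
  failures <- character(0)
  for (r in seq_len(control$n_restarts)) {
    fit <- tryCatch(
      scan_ggm_once(x, K, lambda1, lambda2, lambda3, control,
                    seed = seed + r - 1L),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, conditionMessage(fit))
      next
    }
    # restarts are compared by adaptive BIC, not raw penalized likelihood:
    # at p ~ n a wrong clustering with denser parameters can always buy
    # more likelihood than the sparse truthful one, and only the
    # degrees-of-freedom charge separates the basins
    if (is.null(best) || fit$bic < best$bic) best <- fit
  }
  if (is.null(best))
    stop("all ", control$n_restarts, " restarts failed: ",
         paste(unique(failures), collapse = "; "))
  best$call <- match.call()
  best$bic_report <- scan_bic(x, best)
  best
}

# Adaptive BIC from a known observed log likelihood (avoids recomputing
# densities inside the fit loop).
bic_of <- function(model, loglik, n) {
  s1 <- sum(abs(model$means) > 1e-8)
  up <- upper.tri(matrix(0, model$p, model$p))
  s2 <- 0L
  for (k in seq_len(model$K))
    s2 <- s2 + sum(abs(model$precisions[, , k][up]) > 1e-8)
  -2 * loglik + log(n) * s1 + 2 * s2
}

# One ECM run from one initialization.  The returned fit is the iterate
# with the lowest adaptive BIC along the path: the likelihood keeps
# creeping upward as the cluster-specific precisions absorb noise (p is
# comparable to n), so running the sweep to a fixed point eventually
# degrades the clustering, and the BIC locates the point where extra
# iterations stop buying statistical accuracy.
scan_ggm_once <- function(X, K, lambda1, lambda2, lambda3, control, seed) {
  n <- nrow(X)
  min_mass <- control$min_mass %||% max(K + 1, n / (2 * K))
  max_iter <- control$max_iter %||% (if (ncol(X) >= n / 4) 2L else 200L)
  model <- initialize_scan(X, K, control$init_method, seed = seed)
  resp <- e_step(X, model)
  obj <- resp$loglik / n -
    penalty_value(model, lambda1, lambda2, lambda3)
  trace <- data.frame(iter = 0L, objective = obj, bic = NA_real_,
                      param_change = NA_real_)
  converged <- FALSE
  ascent_violations <- 0L
  reseeded <- FALSE
  warm <- NULL
  best <- NULL
  t <- 0L
  while (t < max_iter) {
    t <- t + 1L
    weights <- if (control$pi_update == "fixed") rep(1 / K, K)
               else update_weights(resp, n, eps = control$eps)
    means <- update_means(X, resp, model, lambda1)
    S <- pseudo_covariances(X, resp, model$means)
    # the conditional objective for the precisions is
    # (1/2) sum_k w_k [log det - tr] - lambda2 P2 - lambda3 P3; the solver
    # works on the unhalved log-likelihood part, so the penalties are
    # doubled to make this an exact conditional maximization of Qn - R
    jgl <- solve_jgl(S, w = resp$masses / n, lambda2 = 2 * lambda2,
                     lambda3 = 2 * lambda3, options = control$admm,
                     warm_start = warm %||% model$precisions)
    prec <- symmetrize_minmag(jgl)
    warm <- prec
    new_model <- mixture_ggm(weights, means, prec, check = FALSE)
    new_resp <- e_step(X, new_model)

    # degenerate-cluster guard: re-seed a collapsing component once from
    # the worst-fit samples (fresh diagonal precision); a second collapse
    # ends the run -- quasi-singleton components inflate the likelihood
    # (and even the BIC) without bound and must never be returned
    dead <- which(new_resp$masses < min_mass)
    if (length(dead)) {
      if (reseeded) break
      reseeded <- TRUE
      ll_rows <- new_resp$loglik_rows
      worst <- order(ll_rows)[seq_along(dead)]
      gv <- pmax(apply(X, 2L, stats::var), 1e-8)
      for (i in seq_along(dead)) {
        new_model$means[dead[i], ] <- X[worst[i], ]
        new_model$precisions[, , dead[i]] <- diag(1 / gv, ncol(X))
      }
      warm <- NULL
      new_resp <- e_step(X, new_model)
      if (any(new_resp$masses < min_mass)) break
    }

    stat <- param_change_stat(new_model, model)
    new_obj <- new_resp$loglik / n -
      penalty_value(new_model, lambda1, lambda2, lambda3)
    bic <- bic_of(new_model, new_resp$loglik, n)
    if (new_obj < obj - 1e-6 * abs(obj)) {
      ascent_violations <- ascent_violations + 1L
      if (control$verbose)
        message("objective decreased at iteration ", t, ": ",
                format(obj), " -> ", format(new_obj))
    }
    trace <- rbind(trace, data.frame(iter = t, objective = new_obj,
                                     bic = bic, param_change = stat))
    if (is.null(best) || bic < best$bic)
      best <- list(model = new_model, resp = new_resp, iter = t,
                   bic = bic, objective = new_obj)
    rel_obj <- abs(new_obj - obj) / max(abs(obj), 1e-12)
    model <- new_model
    resp <- new_resp
    obj <- new_obj
    if (control$verbose)
      message(sprintf("iter %d  obj %.6f  bic %.1f  change %.4g",
                      t, obj, bic, stat))
    if (stat <= control$rel_tol || rel_obj < control$obj_tol) {
      converged <- TRUE
      break
    }
    if (t - best$iter >= control$patience) break
  }
  if (is.null(best))
    stop("no non-degenerate iterate (cluster mass fell below ",
         format(min_mass, digits = 3), ")")
  structure(list(model = best$model, resp = best$resp,
                 labels = max.col(best$resp$matrix, ties.method = "first"),
                 n_iter = t, best_iter = best$iter, converged = converged,
                 trace = trace, objective = best$objective,
                 ascent_violations = ascent_violations,
                 penalty = c(lambda1 = lambda1, lambda2 = lambda2,
                             lambda3 = lambda3),
                 K = K, p = ncol(X), n = n, seed = seed,
                 control = control, bic = best$bic),
            class = "scan_ggm")
}

# Summed relative parameter change between consecutive iterates.
param_change_stat <- function(new, old) {
  s <- 0
  for (k in seq_len(new$K)) {
    dm <- sqrt(sum((new$means[k, ] - old$means[k, ])^2))
    nm <- sqrt(sum(new$means[k, ]^2))
    dO <- sqrt(sum((new$precisions[, , k] - old$precisions[, , k])^2))
    nO <- sqrt(sum(new$precisions[, , k]^2))
    s <- s + dm / max(nm, 1e-12) + dO / max(nO, 1e-12)
  }
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
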