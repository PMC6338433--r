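#' @export
print.scan_ggm <- function(x, ...) {
  cat(sprintf("Gaussian graphical mixture fit: K = %d, p = %d, n = %d\n",
              x$K, x$p, x$n))
  cat(sprintf("penalties: lambda1 = %.4g, lambda2 = %.4g, lambda3 = %.4g\n",
              x$penalty[1], x$penalty[2], x$penalty[3]))
  cat(sprintf("%s after %d sweep(s); penalized objective %.4f\n",
              if (isTRUE(x$converged)) "converged"
              else "stopped at the sweep budget",
              x$n_iter, x$objective))
  if (!is.null(x$best_iter) && x$best_iter != x$n_iter)
    cat(sprintf("returned iterate %d (best adaptive BIC along the path)\n",
                x$best_iter))
  if (is.finite(x$bic)) cat(sprintf("adaptive BIC %.3f\n", x$bic))
  cat("cluster sizes:", paste(tabulate(x$labels, x$K), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.scan_ggm <- function(object, ...) {
  up <- upper.tri(matrix(0, object$p, object$p))
  edges <- vapply(seq_len(object$K), function(k)
    sum(abs(object$model$precisions[, , k][up]) > 1e-8), integer(1))
  nz_means <- vapply(seq_len(object$K), function(k)
    sum(abs(object$model$means[k, ]) > 1e-8), integer(1))
  out <- list(fit = object,
              sizes = tabulate(object$labels, object$K),
              weights = object$model$weights,
              edges = edges, nz_means = nz_means,
              shared_edges = sum(Reduce(`&`, lapply(seq_len(object$K),
                function(k) abs(object$model$precisions[, , k][up]) > 1e-8))))
  class(out) <- "summary.scan_ggm"
  out
}

#' @export
print.summary.scan_ggm <- function(x, ...) {
  print(x$fit)
  tab <- data.frame(cluster = seq_along(x$sizes), size = x$sizes,
                    weight = round(x$weights, 4),
                    nonzero_means = x$nz_means, edges = x$edges)
  print(tab, row.names = FALSE)
  cat("edges shared by all clusters:", x$shared_edges, "\n")
  invisible(x)
}

#' @export
coef.scan_ggm <- function(object, ...) {
  list(weights = object$model$weights, means = object$model$means,
       precisions = object$model$precisions)
}

#' Posterior cluster membership for new data
#'
#' @param object a \code{"scan_ggm"} fit.
#' @param newdata n x p matrix; defaults to refusing (the training data
#'   are not stored).
#' @param type \code{"class"} for hard labels, \code{"prob"} for the
#'   posterior responsibility matrix.
#' @param ... unused.
#' @return Integer labels or an n x K probability matrix.
#' @export
predict.scan_ggm <- function(object, newdata,
                             type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (missing(newdata)) stop("'newdata' is required")
  r <- e_step(as.matrix(newdata), object$model)
  if (type == "prob") r$matrix else max.col(r$matrix, ties.method = "first")
}

#' @export
logLik.scan_ggm <- function(object, ...) {
  b <- object$bic_report
  if (is.null(b)) stop("fit carries no likelihood report")
  structure(b$loglik, df = b$df_mean + b$df_precision,
            nobs = object$n, class = "logLik")
}

#' Simulate from a fitted mixture
#'
#' Draws labels from the fitted mixing weights and samples from the
#' corresponding component Gaussians (via Cholesky factors of the fitted
#' covariances).
#'
#' @param object a \code{"scan_ggm"} fit.
#' @param nsim number of samples.
#' @param seed integer seed.
#' @param ... unused.
#' @return List with \code{X} and \code{labels}.
#' @export
simulate.scan_ggm <- function(object, nsim = object$n, seed = 1L, ...) {
  set.seed(seed)
  m <- object$model
  labels <- sample.int(m$K, nsim, replace = TRUE, prob = m$weights)
  X <- matrix(rnorm(nsim * m$p), nsim, m$p)
  for (k in seq_len(m$K)) {
    idx <- labels == k
    if (!any(idx)) next
    R <- chol(chol2inv(chol(m$precisions[, , k])))
    X[idx, ] <- sweep(X[idx, , drop = FALSE] %*% R, 2L, m$means[k, ], "+")
  }
  list(X = X, labels = labels)
}

#' Residuals of a mixture fit
#'
#' Each sample minus the mean of its hard-assigned cluster.
#'
#' @param object a \code{"scan_ggm"} fit.
#' @param newdata the data matrix the fit was computed on (the fit object
#'   does not store it).
#' @param ... unused.
#' @return n x p matrix of residuals.
#' @export
residuals.scan_ggm <- function(object, newdata, ...) {
  if (missing(newdata)) stop("'newdata' is required")
  as.matrix(newdata) - object$model$means[object$labels, , drop = FALSE]
}

#' Plot the ECM iteration trace
#'
#' Penalized objective per iteration, with the relative parameter-change
#' statistic on a second panel.
#'
#' @param x a \code{"scan_ggm"} fit.
#' @param ... passed to \code{plot.default}.
#' @export
plot.scan_ggm <- function(x, ...) {
  if (is.null(x$trace)) stop("fit carries no iteration trace")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$trace$iter, x$trace$objective, type = "b", pch = 16,
       xlab = "iteration", ylab = "penalized objective", ...)
  plot(x$trace$iter[-1], x$trace$param_change[-1], type = "b", pch = 16,
       log = "y", xlab = "iteration", ylab = "relative parameter change",
       ...)
  graphics::abline(h = x$control$rel_tol, lty = 2)
  invisible(x)
}
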