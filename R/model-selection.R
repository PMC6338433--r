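#' Default penalty tuning grid
#'
#' The 16-point logarithmic grid \eqn{10^{-2 + 2t/15}}, \eqn{t = 0, \dots,
#' 15}, spanning 0.01 to 1, used for all three penalty levels.
#'
#' @return Strictly increasing numeric vector of length 16.
#' @export
tuning_grid <- function() 10^(-2 + 2 * (0:15) / 15)

# Lower median of an ordered grid (index ceiling(m/2) would be the upper
# median for even m; the convention here is the lower one, index m/2 for
# even m counted from t = 0, i.e. element 8 of the default 16-point grid).
grid_median <- function(values) values[[(length(values) + 1L) %/% 2L]]

#' Adaptive BIC of a fitted mixture
#'
#' \eqn{\mathrm{BIC} = -2\sum_i \log(\sum_k \hat\pi_k f_k(x_i)) +
#' \sum_k\{\log(n)\, s_{1k} + 2\, s_{2k}\}} where \eqn{s_{1k}} counts
#' nonzero estimated mean coordinates and \eqn{s_{2k}} nonzero strictly
#' upper-triangular precision entries.  The precision degrees of freedom
#' carry weight 2 rather than \eqn{\log n}; the mixing weights contribute
#' no degrees of freedom.  "Nonzero" means absolute value above
#' \code{1e-8}.
#'
#' @param X n x p data matrix the model was fitted to.
#' @param fit a \code{"scan_ggm"} fit (or any list with a
#'   \code{\link{mixture_ggm}} in \code{$model}).
#' @return A list of class \code{"scan_bic"}: \code{bic}, \code{loglik},
#'   \code{df_mean}, \code{df_precision}.
#' @export
scan_bic <- function(X, fit) {
  model <- fit$model
  X <- as.matrix(X)
  n <- nrow(X)
  ll <- observed_loglik(X, model)
  s1 <- sum(abs(model$means) > 1e-8)
  up <- upper.tri(matrix(0, model$p, model$p))
  s2 <- 0L
  for (k in seq_len(model$K))
    s2 <- s2 + sum(abs(model$precisions[, , k][up]) > 1e-8)
  structure(list(bic = -2 * ll + log(n) * s1 + 2 * s2, loglik = ll,
                 df_mean = s1, df_precision = s2),
            class = "scan_bic")
}

#' @export
print.scan_bic <- function(x, ...) {
  cat(sprintf("adaptive BIC %.3f (loglik %.3f, df mean %d, df precision %d)\n",
              x$bic, x$loglik, x$df_mean, x$df_precision))
  invisible(x)
}

#' Three-stage BIC line search over the penalty levels
#'
#' Stage 1 fixes \eqn{\lambda_2, \lambda_3} at the grid median and scans
#' \eqn{\lambda_1}; stage 2 fixes the stage-1 winner and the \eqn{\lambda_3}
#' median and scans \eqn{\lambda_2}; stage 3 scans \eqn{\lambda_3} with the
#' winners fixed.  Each candidate is fitted with a shared seed schedule and
#' \code{restarts_per_candidate} restarts; the adaptive BIC decides.  The
#' winning configuration is refitted with the full \code{control$n_restarts}.
#'
#' @param x n x p data matrix.
#' @param K number of clusters.
#' @param grid candidate values (shared by the three penalties), default
#'   \code{\link{tuning_grid}}; alternatively a list with components
#'   \code{lambda1}, \code{lambda2}, \code{lambda3}.
#' @param control a \code{\link{scan_control}}.
#' @param seed seed shared by every candidate fit.
#' @param restarts_per_candidate restarts used during the scan (default 1;
#'   the final refit uses \code{control$n_restarts}).
#' @return A list of class \code{"scan_tune"}: \code{lambda} (named vector),
#'   \code{fit} (final refit), \code{table} (one row per candidate fit:
#'   stage, lambdas, loglik, degrees of freedom, BIC).
#' @export
scan_tune <- function(x, K, grid = tuning_grid(), control = scan_control(),
                      seed = 1L, restarts_per_candidate = 1L) {
  x <- as.matrix(x)
  if (is.list(grid)) {
    g1 <- grid$lambda1; g2 <- grid$lambda2; g3 <- grid$lambda3
  } else g1 <- g2 <- g3 <- grid
  if (!length(g1) || !length(g2) || !length(g3)) stop("empty tuning grid")
  scan_ctrl <- control
  scan_ctrl$n_restarts <- as.integer(restarts_per_candidate)

  rows <- list()
  failures <- character(0)
  eval_cand <- function(l1, l2, l3, stage) {
    fit <- tryCatch(scan_ggm(x, K, l1, l2, l3, control = scan_ctrl,
                             seed = seed),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      failures <<- c(failures, sprintf("lambda=(%.4g,%.4g,%.4g): %s",
                                       l1, l2, l3, conditionMessage(fit)))
      return(NULL)
    }
    b <- fit$bic_report
    rows[[length(rows) + 1L]] <<- data.frame(
      stage = stage, lambda1 = l1, lambda2 = l2, lambda3 = l3,
      loglik = b$loglik, df_mean = b$df_mean, df_precision = b$df_precision,
      bic = b$bic)
    b$bic
  }
  pick <- function(values, f, stage) {
    bics <- vapply(values, f, numeric(1) , stage = stage)
    if (all(is.na(bics))) return(NA_real_)
    values[[which.min(bics)]]
  }
  f1 <- function(l1, stage) eval_cand(l1, grid_median(g2), grid_median(g3),
                                      stage) %||% NA_real_
  l1 <- pick(g1, f1, 1L)
  if (is.na(l1)) stop("all stage-1 fits failed: ",
                      paste(unique(failures), collapse = "; "))
  f2 <- function(l2, stage) eval_cand(l1, l2, grid_median(g3), stage) %||%
    NA_real_
  l2 <- pick(g2, f2, 2L)
  if (is.na(l2)) stop("all stage-2 fits failed")
  f3 <- function(l3, stage) eval_cand(l1, l2, l3, stage) %||% NA_real_
  l3 <- pick(g3, f3, 3L)
  if (is.na(l3)) stop("all stage-3 fits failed")

  fit <- scan_ggm(x, K, l1, l2, l3, control = control, seed = seed)
  structure(list(lambda = c(lambda1 = l1, lambda2 = l2, lambda3 = l3),
                 fit = fit, table = do.call(rbind, rows)),
            class = "scan_tune")
}

#' @export
print.scan_tune <- function(x, ...) {
  cat("BIC line search:", nrow(x$table), "fits\n")
  cat(sprintf("selected lambda1 = %.4g, lambda2 = %.4g, lambda3 = %.4g\n",
              x$lambda[1], x$lambda[2], x$lambda[3]))
  cat(sprintf("BIC %.3f\n", x$fit$bic))
  invisible(x)
}

#' Write a tuning table as TSV
#'
#' @param tune a \code{"scan_tune"} result.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_tuning_table <- function(tune, path) {
  write.table(tune$table, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
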