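#' Pairwise clustering error
#'
#' Fraction of the \eqn{\binom{n}{2}} sample pairs on which the estimated
#' and true partitions disagree about co-membership.  Invariant to label
#' permutation.  Computed by contingency-table pair counting in O(nK)
#' rather than pair enumeration.
#'
#' @param est,truth length-n label vectors (any atomic labels).
#' @return Error in [0, 1].
#' @export
clustering_error <- function(est, truth) {
  if (length(est) != length(truth))
    stop("label vectors have different lengths")
  n <- length(est)
  if (n < 2) stop("need at least two samples")
  tab <- table(est, truth)
  pairs <- function(x) sum(x * (x - 1) / 2)
  same_both <- pairs(tab)
  same_est <- pairs(rowSums(tab))
  same_truth <- pairs(colSums(tab))
  # disagreeing pairs: same in exactly one of the two partitions
  (same_est + same_truth - 2 * same_both) / (n * (n - 1) / 2)
}

# all permutations of 1..k (k! rows); k is small (number of clusters)
permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1L)))
  }
  unname(out)
}

#' Optimal cluster alignment between two mixture models
#'
#' Finds the permutation \eqn{\sigma} minimizing \eqn{\sum_k
#' \|\hat\mu_{\sigma(k)} - \mu_k\|_2 + \|\hat\Omega_{\sigma(k)} -
#' \Omega_k\|_F} by exhaustive assignment over the K! permutations (K is
#' the cluster count, so this is cheap); ties break to the
#' lexicographically smallest permutation.
#'
#' @param est_model,true_model \code{\link{mixture_ggm}} objects with equal
#'   K and p.
#' @return Integer permutation \code{sigma}; component k of the truth is
#'   matched by component \code{sigma[k]} of the estimate.
#' @export
align_clusters <- function(est_model, true_model) {
  K <- true_model$K
  if (est_model$K != K) stop("cluster counts differ")
  if (est_model$p != true_model$p) stop("dimensions differ")
  cost <- matrix(0, K, K)  # cost[e, t] = distance(est e, truth t)
  for (e in seq_len(K)) for (t in seq_len(K)) {
    cost[e, t] <-
      sqrt(sum((est_model$means[e, ] - true_model$means[t, ])^2)) +
      sqrt(sum((est_model$precisions[, , e] -
                  true_model$precisions[, , t])^2))
  }
  perms <- permutations_of(K)
  tot <- apply(perms, 1L, function(s) sum(cost[cbind(s, seq_len(K))]))
  perms[which.min(tot), ]  # which.min returns the first (lexicographic) min
}

#' Mean and precision estimation errors after alignment
#'
#' \eqn{\mathrm{CME} = K^{-1}\sum_k \|\hat\mu_{\sigma(k)} - \mu_k\|_2},
#' \eqn{\mathrm{PME} = K^{-1}\sum_k \|\hat\Omega_{\sigma(k)} -
#' \Omega_k\|_F}.
#'
#' @inheritParams align_clusters
#' @param alignment permutation from \code{\link{align_clusters}}.
#' @return Named numeric vector \code{c(cme, pme)}.
#' @export
estimation_errors <- function(est_model, true_model,
                              alignment = align_clusters(est_model,
                                                         true_model)) {
  K <- true_model$K
  cme <- pme <- 0
  for (k in seq_len(K)) {
    e <- alignment[k]
    cme <- cme + sqrt(sum((est_model$means[e, ] -
                             true_model$means[k, ])^2))
    pme <- pme + sqrt(sum((est_model$precisions[, , e] -
                             true_model$precisions[, , k])^2))
  }
  c(cme = cme / K, pme = pme / K)
}

#' Edge true and false positive rates
#'
#' Averages over clusters of the upper-triangle support indicators: TPR is
#' the fraction of true edges recovered, FPR the fraction of non-edges
#' estimated as edges.  An edge is an off-diagonal entry with absolute
#' value above \code{1e-8}.  A cluster whose true graph has no edges has
#' an undefined TPR term; it is skipped with a warning and the average
#' renormalized.
#'
#' @inheritParams estimation_errors
#' @return Named numeric vector \code{c(tpr, fpr)}.
#' @export
edge_rates <- function(est_model, true_model,
                       alignment = align_clusters(est_model, true_model)) {
  K <- true_model$K
  up <- upper.tri(matrix(0, true_model$p, true_model$p))
  tprs <- fprs <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    te <- abs(true_model$precisions[, , k][up]) > 1e-8
    ee <- abs(est_model$precisions[, , alignment[k]][up]) > 1e-8
    if (any(te)) tprs[k] <- sum(te & ee) / sum(te)
    if (any(!te)) fprs[k] <- sum(!te & ee) / sum(!te)
  }
  if (anyNA(tprs))
    warning("cluster(s) ", paste(which(is.na(tprs)), collapse = ", "),
            " have no true edges; their TPR terms are skipped")
  c(tpr = mean(tprs, na.rm = TRUE), fpr = mean(fprs, na.rm = TRUE))
}

#' Full evaluation of a fit against a known truth
#'
#' Combines clustering error, aligned mean/precision errors and edge
#' true/false positive rates into one report row.
#'
#' @param fit a \code{"scan_ggm"} fit (or any list with \code{$model} and
#'   \code{$labels}).
#' @param true_model the generating \code{\link{mixture_ggm}}.
#' @param true_labels length-n true label vector.
#' @return One-row data frame of class \code{"scan_eval"} with columns
#'   \code{ce}, \code{cme}, \code{pme}, \code{tpr}, \code{fpr}; the
#'   alignment permutation is attached as an attribute.
#' @export
evaluate_fit <- function(fit, true_model, true_labels) {
  sigma <- align_clusters(fit$model, true_model)
  err <- estimation_errors(fit$model, true_model, sigma)
  rates <- edge_rates(fit$model, true_model, sigma)
  out <- data.frame(ce = clustering_error(fit$labels, true_labels),
                    cme = err[["cme"]], pme = err[["pme"]],
                    tpr = rates[["tpr"]], fpr = rates[["fpr"]])
  attr(out, "alignment") <- sigma
  class(out) <- c("scan_eval", class(out))
  out
}

#' Append an evaluation row to a TSV file
#'
#' @param eval a \code{"scan_eval"} row.
#' @param path output file; created with a header if absent.
#' @return \code{path}, invisibly.
#' @export
write_eval_row <- function(eval, path) {
  new <- !file.exists(path)
  suppressWarnings(
    write.table(eval, path, sep = "\t", row.names = FALSE,
                col.names = new, quote = FALSE, append = !new))
  invisible(path)
}
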