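#' Lloyd K-means with k-means++ seeding
#'
#' Runs Lloyd's algorithm (through \code{stats::kmeans}) from
#' \code{n_init} k-means++-style seedings and keeps the solution with the
#' smallest within-cluster sum of squares.  A seeding that collapses a
#' cluster is redrawn.  Deterministic given \code{seed}.
#'
#' @param X n x p data matrix.
#' @param K number of clusters.
#' @param seed integer seed.
#' @param n_init number of seedings (default 10).
#' @return List with \code{labels} (1..K), \code{centers} (K x p) and
#'   \code{wcss}.
#' @export
kmeans_lloyd <- function(X, K, seed = 1L, n_init = 10L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < K) stop("fewer samples than clusters")
  set.seed(seed)
  best <- NULL
  for (init in seq_len(n_init)) {
    for (attempt in 1:10) {
      centers <- kmeanspp_centers(X, K)
      km <- tryCatch(stats::kmeans(X, centers = centers,
                                   algorithm = "Lloyd", iter.max = 100L),
                     error = function(e) NULL,
                     warning = function(w) NULL)
      if (!is.null(km)) break
    }
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("every K-means seeding collapsed a cluster")
  list(labels = as.integer(best$cluster), centers = unname(best$centers),
       wcss = best$tot.withinss)
}

# k-means++ seeding: first center uniform, then points with probability
# proportional to squared distance from the nearest chosen center.
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  idx <- integer(K)
  idx[1] <- sample.int(n, 1L)
  d2 <- colSums((t(X) - X[idx[1], ])^2)
  for (k in seq_len(K - 1L)) {
    pr <- d2 / sum(d2)
    idx[k + 1L] <- sample.int(n, 1L, prob = pmax(pr, 0))
    d2 <- pmin(d2, colSums((t(X) - X[idx[k + 1L], ])^2))
  }
  X[idx, , drop = FALSE] + matrix(rnorm(K * ncol(X), sd = 1e-9), K)
}

#' Two-stage baseline: K-means then joint graphical lasso
#'
#' Clusters by \code{\link{kmeans_lloyd}}, takes the centroids as cluster
#' means and the hard-label class covariances as inputs to one weighted
#' joint graphical lasso solve (weights \eqn{n_k/n}).  No iteration.
#'
#' @param x n x p data matrix.
#' @param K number of clusters.
#' @param lambda2,lambda3 penalty levels for the precision estimation.
#' @param control a \code{\link{scan_control}} (only the ADMM options are
#'   used).
#' @param seed integer seed for the K-means stage.
#' @return A \code{"scan_ggm"}-classed object with one-hot
#'   responsibilities and the jointly estimated precisions.
#' @export
two_stage_jgl <- function(x, K, lambda2, lambda3,
                          control = scan_control(), seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  km <- kmeans_lloyd(x, K, seed = seed)
  resp <- matrix(0, n, K)
  resp[cbind(seq_len(n), km$labels)] <- 1
  resp <- structure(list(matrix = resp, masses = colSums(resp)),
                    class = "scan_resp")
  S <- pseudo_covariances(x, resp, km$centers)
  # same doubled-penalty convention as the ECM precision step, so a given
  # (lambda2, lambda3) means the same penalty strength in both methods
  prec <- solve_jgl(S, w = resp$masses / n, lambda2 = 2 * lambda2,
                    lambda3 = 2 * lambda3, options = control$admm)
  prec <- symmetrize_minmag(prec)
  model <- mixture_ggm(resp$masses / n, km$centers, prec, check = FALSE)
  fit <- structure(list(model = model, resp = resp, labels = km$labels,
                        n_iter = 1L, converged = TRUE, trace = NULL,
                        objective = NA_real_, ascent_violations = 0L,
                        penalty = c(lambda1 = 0, lambda2 = lambda2,
                                    lambda3 = lambda3),
                        K = K, p = p, n = n, seed = seed,
                        control = control, bic = NA_real_),
                   class = "scan_ggm")
  fit$bic_report <- scan_bic(x, fit)
  fit$bic <- fit$bic_report$bic
  fit
}

#' Per-cluster graphical lasso baseline
#'
#' The \eqn{\lambda_3 = 0} special case of the penalized ECM fit: each
#' precision matrix is penalized individually inside the same loop, with
#' no cross-cluster coupling.
#'
#' @inheritParams scan_ggm
#' @return A \code{"scan_ggm"} fit.
#' @export
per_cluster_glasso <- function(x, K, lambda1, lambda2,
                               control = scan_control(), seed = 1L) {
  scan_ggm(x, K, lambda1, lambda2, lambda3 = 0, control = control,
           seed = seed)
}

# scenario parameters for the nine benchmark models
model_config <- function(model_id) {
  stopifnot(model_id %in% 1:9)
  if (model_id <= 3) {
    list(family = "regular",
         mu = c(0.8, 1, 1)[model_id], eta = c(0.3, 0.3, 0.4)[model_id])
  } else if (model_id <= 6) {
    list(family = "powerlaw", mu = c(0.7, 0.8, 0.9)[model_id - 3], eta = NA)
  } else {
    list(family = "chain", mu = c(0.7, 0.8, 0.9)[model_id - 6], eta = NA)
  }
}

#' Replicated benchmark of all methods on one simulation model
#'
#' For each replicate: generate the scenario and a dataset, run K-means,
#' the two-stage K-means + joint graphical lasso, the per-cluster
#' graphical lasso and the simultaneous fit, and score each against the
#' truth.  Penalties are BIC line-search tuned on replicate 1 and reused
#' (set \code{retune_each = TRUE} to retune per replicate); the same
#' \eqn{\lambda_1, \lambda_2} are shared with the per-cluster baseline and
#' the same \eqn{\lambda_2, \lambda_3} with the two-stage baseline.
#'
#' @param model_id integer 1..9: models 1-3 are the regular (tridiagonal)
#'   family, 4-6 power-law, 7-9 chain.
#' @param n_reps number of replicates.
#' @param seed base seed; replicate r uses \code{seed + r}.
#' @param p,n problem size (defaults 100, 300).
#' @param lambda optional named vector \code{c(lambda1, lambda2, lambda3)}
#'   to skip tuning.
#' @param control a \code{\link{scan_control}}.
#' @param grid tuning grid for the line search.
#' @param retune_each retune on every replicate?
#' @param methods subset of \code{c("kmeans", "kmeans_jgl", "glasso",
#'   "scan")} to run.
#' @return An object of class \code{"scan_bench"}: \code{$results} (one
#'   row per replicate and method with ce/cme/pme/tpr/fpr), \code{$summary}
#'   (mean and standard error per method), \code{$lambda}, and the failed
#'   replicates, if any, in \code{$failures}.
#' @export
scan_bench <- function(model_id, n_reps = 10L, seed = 1L, p = 100L,
                       n = 300L, lambda = NULL,
                       control = scan_control(), grid = tuning_grid(),
                       retune_each = FALSE,
                       methods = c("kmeans", "kmeans_jgl", "glasso",
                                   "scan")) {
  cfg <- model_config(model_id)
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  failures <- character(0)
  for (r in seq_len(n_reps)) {
    rep_seed <- seed + r
    sc <- scan_scenario(cfg$family, p = p, n = n, mu = cfg$mu,
                        eta = cfg$eta, seed = rep_seed)
    d <- sample_scenario(sc, seed = rep_seed)
    if (is.null(lambda) || (retune_each && r > 1L)) {
      tn <- scan_tune(d$X, sc$K, grid = grid, control = control,
                      seed = rep_seed)
      lambda <- tn$lambda
    }
    for (m in methods) {
      res <- tryCatch({
        fit <- switch(m,
          kmeans = {
            km <- kmeans_lloyd(d$X, sc$K, seed = rep_seed)
            kmeans_as_fit(d$X, km)
          },
          kmeans_jgl = two_stage_jgl(d$X, sc$K, lambda[["lambda2"]],
                                     lambda[["lambda3"]],
                                     control = control, seed = rep_seed),
          glasso = per_cluster_glasso(d$X, sc$K, lambda[["lambda1"]],
                                      lambda[["lambda2"]],
                                      control = control, seed = rep_seed),
          scan = scan_ggm(d$X, sc$K, lambda[["lambda1"]],
                          lambda[["lambda2"]], lambda[["lambda3"]],
                          control = control, seed = rep_seed))
        ev <- evaluate_fit(fit, sc$true_model, d$labels)
        if (m == "kmeans") ev$pme <- ev$tpr <- ev$fpr <- NA_real_
        cbind(data.frame(replicate = r, method = m), ev)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures,
                      sprintf("replicate %d, %s: %s", r, m,
                              conditionMessage(res)))
      } else rows[[length(rows) + 1L]] <- res
    }
  }
  results <- do.call(rbind, rows)
  metric_cols <- c("ce", "cme", "pme", "tpr", "fpr")
  summ <- do.call(rbind, lapply(split(results, results$method), function(g) {
    means <- colMeans(g[metric_cols], na.rm = TRUE)
    ses <- vapply(g[metric_cols], function(v) {
      v <- v[!is.na(v)]
      if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
    }, numeric(1))
    data.frame(method = g$method[1], n_reps = nrow(g),
               t(setNames(means, metric_cols)),
               t(setNames(ses, paste0(metric_cols, "_se"))))
  }))
  rownames(summ) <- NULL
  structure(list(model_id = model_id, results = results, summary = summ,
                 lambda = lambda, failures = failures),
            class = "scan_bench")
}

# wrap a K-means solution as a fit object so it can be scored;
# the precision slot is the identity (K-means carries no graph estimate)
kmeans_as_fit <- function(X, km) {
  K <- nrow(km$centers)
  p <- ncol(X)
  n <- nrow(X)
  resp <- matrix(0, n, K)
  resp[cbind(seq_len(n), km$labels)] <- 1
  prec <- array(0, c(p, p, K))
  for (k in seq_len(K)) prec[, , k] <- diag(1, p)
  structure(list(model = mixture_ggm(colSums(resp) / n, km$centers, prec,
                                     check = FALSE),
                 resp = structure(list(matrix = resp,
                                       masses = colSums(resp)),
                                  class = "scan_resp"),
                 labels = km$labels, K = K, p = p, n = n),
            class = "scan_ggm")
}

#' @export
print.scan_bench <- function(x, ...) {
  cat("benchmark model", x$model_id, "--",
      max(x$summary$n_reps), "replicates\n")
  print(x$summary, digits = 3)
  if (length(x$failures))
    cat(length(x$failures), "failed runs (see $failures)\n")
  invisible(x)
}

#' Write a benchmark summary as TSV
#'
#' @param bench a \code{"scan_bench"} result.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_bench_table <- function(bench, path) {
  write.table(bench$summary, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Precision estimation error as a function of sample size
#'
#' Error-scaling harness: at fixed low dimension, draws replicated
#' datasets from a single-block tridiagonal scenario at increasing sample
#' sizes, fits the penalized mixture at fixed penalties, and reports the
#' mean aligned precision estimation error per sample size.  The expected
#' pattern is a monotone decrease of PME with n, mirroring the
#' \eqn{\sqrt{\log p / n}} statistical error scaling.
#'
#' @param n_values increasing sample sizes (default 400 to 2000).
#' @param p dimension (default 10).
#' @param n_seeds replicates per sample size (default 20).
#' @param lambda penalties \code{c(lambda1, lambda2, lambda3)}; the
#'   default \code{NULL} scales them with the statistical rate,
#'   \code{c(0.5, 0.5, 0.2) * sqrt(log(p)/n)} -- a fixed penalty leaves
#'   an n-independent shrinkage bias that masks the error decay.
#' @param mu,eta scenario parameters (defaults 1, 0.4).
#' @param control a \code{\link{scan_control}}.
#' @param seed base seed.
#' @return Data frame with columns \code{n}, \code{pme}, \code{pme_se}.
#' @export
pme_scaling <- function(n_values = seq(400, 2000, by = 400), p = 10L,
                        n_seeds = 20L,
                        lambda = NULL, mu = 1, eta = 0.4,
                        control = scan_control(n_restarts = 1), seed = 1L) {
  rows <- lapply(n_values, function(n) {
    lam <- lambda %||% (c(0.5, 0.5, 0.2) * sqrt(log(p) / n))
    pmes <- vapply(seq_len(n_seeds), function(r) {
      sc <- scan_scenario("regular", p = p, n = n, mu = mu, eta = eta,
                          n_blocks = 1L, seed = seed + r)
      d <- sample_scenario(sc, seed = seed + r)
      fit <- scan_ggm(d$X, sc$K, lam[1], lam[2], lam[3],
                      control = control, seed = seed + r)
      estimation_errors(fit$model, sc$true_model)[["pme"]]
    }, numeric(1))
    data.frame(n = n, pme = mean(pmes),
               pme_se = sd(pmes) / sqrt(n_seeds))
  })
  do.call(rbind, rows)
}

#' Read a sample-by-feature matrix from TSV/CSV
#'
#' Auto-detects the separator (tab or comma), a header row (non-numeric
#' first line) and a row-name column (non-numeric first field), all
#' overridable.  Malformed numeric cells are reported with their line
#' numbers.
#'
#' @param path file path.
#' @param sep field separator; default auto-detect.
#' @param header logical or \code{NA} (auto-detect).
#' @param row_names logical or \code{NA} (auto-detect).
#' @return List with \code{X} (numeric matrix) and \code{ids} (row names,
#'   possibly \code{NULL}).
#' @export
read_matrix <- function(path, sep = NULL, header = NA, row_names = NA) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (is.null(sep))
    sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) ","
           else ""
  fields <- strsplit(first, if (sep == "") "[[:space:]]+" else sep,
                     fixed = (sep != ""))[[1]]
  nonnum <- function(x) is.na(suppressWarnings(as.numeric(x)))
  if (is.na(header)) header <- any(nonnum(fields[-1]))
  raw <- read.table(path, sep = sep, header = header,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", comment.char = "")
  if (is.na(row_names)) row_names <- any(nonnum(raw[[1]]))
  ids <- NULL
  if (row_names) {
    ids <- raw[[1]]
    raw <- raw[, -1, drop = FALSE]
  }
  X <- suppressWarnings(
    matrix(as.numeric(as.matrix(raw)), nrow(raw), ncol(raw)))
  if (anyNA(X)) {
    bad <- unique(which(is.na(X), arr.ind = TRUE)[, 1])
    stop("non-numeric cell(s) at data line(s) ",
         paste(bad + as.integer(header), collapse = ", "))
  }
  colnames(X) <- if (header) colnames(raw) else NULL
  rownames(X) <- ids
  list(X = X, ids = ids)
}

#' Write estimated networks as edge lists
#'
#' One TSV per cluster with the nonzero upper-triangular precision entries
#' (feature_i, feature_j, weight), plus \code{shared_edges.tsv} listing
#' the edges present in every cluster.
#'
#' @param fit a \code{"scan_ggm"} fit.
#' @param dir output directory (created if needed).
#' @param feature_names optional feature names; defaults to V1..Vp.
#' @return \code{dir}, invisibly.
#' @export
write_networks <- function(fit, dir, feature_names = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- fit$p
  if (is.null(feature_names)) feature_names <- paste0("V", seq_len(p))
  up <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  shared <- rep(TRUE, nrow(up))
  for (k in seq_len(fit$K)) {
    O <- fit$model$precisions[, , k]
    v <- O[up]
    keep <- abs(v) > 1e-8
    shared <- shared & keep
    write.table(data.frame(feature_i = feature_names[up[keep, 1]],
                           feature_j = feature_names[up[keep, 2]],
                           weight = v[keep]),
                file.path(dir, sprintf("network_cluster%d.tsv", k)),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write.table(data.frame(feature_i = feature_names[up[shared, 1]],
                         feature_j = feature_names[up[shared, 2]]),
              file.path(dir, "shared_edges.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Write hard cluster labels as a two-column TSV
#'
#' @param fit a \code{"scan_ggm"} fit.
#' @param path output file path.
#' @param sample_ids optional sample identifiers.
#' @return \code{path}, invisibly.
#' @export
write_labels <- function(fit, path, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- seq_along(fit$labels)
  write.table(data.frame(sample = sample_ids, cluster = fit$labels),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the penalty levels, seed, iteration count, convergence flag and
#' BIC of a fit so a run can be reproduced exactly.
#'
#' @param fit a \code{"scan_ggm"} fit.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(fit, path) {
  manifest <- list(K = fit$K, p = fit$p, n = fit$n,
                   lambda = as.list(fit$penalty), seed = fit$seed,
                   n_iter = fit$n_iter, converged = fit$converged,
                   bic = fit$bic)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), path)
  invisible(path)
}
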