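test_that("Lloyd K-means separates well-separated blobs deterministically", {
  set.seed(40)
  X <- rbind(matrix(rnorm(40, -5), 20, 2), matrix(rnorm(40, 5), 20, 2))
  truth <- rep(1:2, each = 20)
  km <- kmeans_lloyd(X, 2, seed = 1)
  expect_equal(clustering_error(km$labels, truth), 0)
  km2 <- kmeans_lloyd(X, 2, seed = 1)
  expect_identical(km$labels, km2$labels)
  # K = n puts every point in its own cluster with zero WCSS
  X6 <- matrix(rnorm(12), 6, 2)
  kmn <- kmeans_lloyd(X6, 6, seed = 2)
  expect_equal(sort(kmn$labels), 1:6)
  expect_lt(kmn$wcss, 1e-10)
  expect_error(kmeans_lloyd(X6, 10), "fewer samples")
})

test_that("two-stage baseline reduces to the inverse covariance at K = 1", {
  set.seed(41)
  X <- matrix(rnorm(200), 50, 4)
  fit <- two_stage_jgl(X, 1, 0, 0, seed = 1)
  S <- crossprod(sweep(X, 2, colMeans(X))) / 50
  expect_equal(fit$model$precisions[, , 1], solve(S), tolerance = 1e-2)
  expect_equal(drop(fit$model$means), colMeans(X))
  expect_equal(fit$K, 1)
  # perfectly separated data: equals the oracle-label joint fit
  Xs <- rbind(matrix(rnorm(60, -10), 20, 3), matrix(rnorm(60, 10), 20, 3))
  truth <- rep(1:2, each = 20)
  f2 <- two_stage_jgl(Xs, 2, 0.1, 0.05, seed = 2)
  expect_equal(clustering_error(f2$labels, truth), 0)
  resp <- matrix(0, 40, 2)
  resp[cbind(1:40, truth)] <- 1
  resp <- structure(list(matrix = resp, masses = colSums(resp)),
                    class = "scan_resp")
  centers <- rbind(colMeans(Xs[1:20, ]), colMeans(Xs[21:40, ]))
  S2 <- pseudo_covariances(Xs, resp, centers)
  oracle <- symmetrize_minmag(solve_jgl(S2, c(0.5, 0.5), 0.2, 0.1))
  sig <- align_clusters(f2$model,
                        mixture_ggm(c(0.5, 0.5), centers, oracle,
                                    check = FALSE))
  expect_equal(f2$model$precisions[, , sig], oracle, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("matrix round-trips through TSV and CSV with autodetection", {
  set.seed(42)
  X <- matrix(round(rnorm(30), 6), 10, 3)
  colnames(X) <- c("g1", "g2", "g3")
  rownames(X) <- paste0("s", 1:10)
  tsv <- tempfile(fileext = ".tsv")
  write.table(X, tsv, sep = "\t", quote = FALSE, col.names = NA)
  got <- read_matrix(tsv)
  expect_equal(unname(got$X), unname(X))
  expect_equal(got$ids, rownames(X))
  expect_equal(colnames(got$X), colnames(X))
  csv <- tempfile(fileext = ".csv")
  write.table(X, csv, sep = ",", quote = FALSE, row.names = FALSE)
  got2 <- read_matrix(csv)
  expect_equal(unname(got2$X), unname(X))
  # bare matrix without header or row names
  bare <- tempfile(fileext = ".tsv")
  write.table(X, bare, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_equal(unname(read_matrix(bare)$X), unname(X))
  # malformed cells are reported with a line number
  writeLines(c("1\t2", "3\tx"), bad <- tempfile())
  expect_error(read_matrix(bad), "line")
})

test_that("network and label writers emit the declared schemas", {
  sc <- scan_scenario("regular", p = 10, n = 80, mu = 1, eta = 0.3,
                      n_blocks = 1, seed = 8)
  d <- sample_scenario(sc)
  fit <- scan_ggm(d$X, 3, 0.05, 0.1, 0.05,
                  control = scan_control(n_restarts = 1), seed = 1)
  dir <- tempfile()
  write_networks(fit, dir)
  up <- upper.tri(matrix(0, 10, 10))
  shared <- rep(TRUE, sum(up))
  for (k in 1:3) {
    el <- read.delim(file.path(dir, sprintf("network_cluster%d.tsv", k)))
    expect_named(el, c("feature_i", "feature_j", "weight"))
    nz <- abs(fit$model$precisions[, , k][up]) > 1e-8
    expect_equal(nrow(el), sum(nz))
    shared <- shared & nz
  }
  se <- read.delim(file.path(dir, "shared_edges.tsv"))
  expect_equal(nrow(se), sum(shared))
  lab <- tempfile(fileext = ".tsv")
  write_labels(fit, lab)
  tab <- read.delim(lab)
  expect_named(tab, c("sample", "cluster"))
  expect_equal(tab$cluster, fit$labels)
  mf <- tempfile(fileext = ".json")
  write_manifest(fit, mf)
  man <- jsonlite::fromJSON(mf)
  expect_equal(man$lambda$lambda2, 0.1)
  expect_equal(man$seed, fit$seed)
})

test_that("benchmark table has the reporting schema and NA single-rep se", {
  b <- scan_bench(1, n_reps = 1, seed = 3, p = 20, n = 90,
                  lambda = c(lambda1 = 0.05, lambda2 = 0.1,
                             lambda3 = 0.05),
                  control = scan_control(n_restarts = 1))
  expect_setequal(b$summary$method,
                  c("kmeans", "kmeans_jgl", "glasso", "scan"))
  expect_true(all(is.na(b$summary$ce_se)))
  expect_named(b$results,
               c("replicate", "method", "ce", "cme", "pme", "tpr", "fpr"))
  # K-means carries no graph estimate
  expect_true(is.na(b$results$pme[b$results$method == "kmeans"]))
  path <- tempfile(fileext = ".tsv")
  write_bench_table(b, path)
  expect_equal(nrow(read.delim(path)), 4)
})
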