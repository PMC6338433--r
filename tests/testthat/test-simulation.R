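test_that("mean pattern follows the sparse three-class design", {
  m <- make_mean_vectors(12, 3, 1)
  expect_equal(m[2, ], c(rep(1, 10), 0, 0))
  expect_equal(m[1, 1:10], c(rep(1, 5), rep(-1, 5)))
  expect_equal(m[3, ], -m[2, ])
  expect_equal(rowSums(m != 0), rep(10, 3), ignore_attr = TRUE)
  expect_error(make_mean_vectors(8, 3, 1), "at least 10")
})

test_that("regular scenario builds tridiagonal block precisions", {
  sc <- scan_scenario("regular", p = 20, n = 60, mu = 1, eta = 0.3,
                      seed = 1)
  om1 <- sc$true_model$precisions[, , 1]
  expect_equal(diag(om1), rep(1, 20))
  expect_equal(om1[1, 2], 0.3)
  # block boundary (block size 4): no coupling across blocks
  expect_equal(om1[4, 5], 0)
  # class scaling eta, 0.99 eta, 1.01 eta
  expect_equal(sc$true_model$precisions[1, 2, 2], 0.99 * 0.3)
  expect_equal(sc$true_model$precisions[1, 2, 3], 1.01 * 0.3)
  # eta = 0 gives the identity
  sc0 <- scan_scenario("regular", p = 10, n = 30, mu = 1, eta = 0,
                       seed = 1)
  for (k in 1:3)
    expect_equal(sc0$true_model$precisions[, , k], diag(10))
  # minimum eigenvalue agrees with direct eigendecomposition
  B <- diag(10)
  i <- 1:9
  B[cbind(i, i + 1)] <- B[cbind(i + 1, i)] <- 0.3
  sc1 <- scan_scenario("regular", p = 10, n = 30, mu = 1, eta = 0.3,
                       n_blocks = 1, seed = 1)
  expect_equal(min(eigen(sc1$true_model$precisions[, , 1])$values),
               min(eigen(B)$values))
})

test_that("power-law scenario has unit diagonal, block resets, dominance", {
  for (seed in 1:5) {
    sc <- scan_scenario("powerlaw", p = 30, n = 60, mu = 0.9, seed = seed)
    expect_equal(diag(sc$sigma[, , 1]), rep(1, 30))
    # class 2 resets the last block of Sigma to the identity; class 3
    # additionally resets the one before it
    idx10 <- 28:30
    idx9 <- 25:27
    expect_equal(sc$sigma[idx10, idx10, 2], diag(3))
    expect_equal(sc$sigma[idx9, idx9, 3], diag(3))
    expect_equal(sc$sigma[idx9, idx9, 2], sc$sigma[idx9, idx9, 1])
    # shared blocks identical across classes
    shared <- 1:24
    expect_equal(sc$sigma[shared, shared, 2], sc$sigma[shared, shared, 1])
    expect_equal(sc$sigma[shared, shared, 3], sc$sigma[shared, shared, 1])
  }
  # the rescaled seed matrices are strictly diagonally dominant
  for (seed in 1:20) {
    set.seed(seed)
    W <- scanggm:::powerlaw_block(8)
    expect_identical(W, t(W))
    offsums <- rowSums(abs(W)) - diag(W)
    expect_true(all(offsums < 1))
  }
})

test_that("chain scenario is an AR-decay block model", {
  sc <- scan_scenario("chain", p = 30, n = 60, mu = 0.9, seed = 2)
  s1 <- sc$sigma[, , 1]
  expect_equal(diag(s1), rep(1, 30))
  # entries decay monotonically away from the diagonal within a block
  expect_true(all(diff(s1[1, 1:3]) < 0))
  expect_gt(s1[1, 2], s1[1, 3])
  # the block precision is tridiagonal (AR Markov property)
  om1 <- sc$true_model$precisions[1:3, 1:3, 1]
  full <- sc$true_model$precisions[, , 1]
  off <- full[1:3, 1:3]
  expect_lt(abs(full[1, 3]), 1e-8)
  expect_gt(abs(full[1, 2]), 1e-8)
  # block-diagonal across blocks
  expect_true(all(abs(full[1:3, 4:30]) < 1e-8))
})

test_that("generated precision and covariance stacks are exact inverses", {
  for (fam in c("regular", "powerlaw", "chain")) {
    sc <- scan_scenario(fam, p = 20, n = 50,
                        mu = 1, eta = 0.3, seed = 7)
    for (k in 1:3) {
      prod <- sc$true_model$precisions[, , k] %*% sc$sigma[, , k]
      expect_lt(max(abs(prod - diag(20))), 1e-8)
    }
  }
})

test_that("scenarios and samples are deterministic given the seed", {
  a <- scan_scenario("powerlaw", p = 20, n = 40, mu = 0.8, seed = 5)
  b <- scan_scenario("powerlaw", p = 20, n = 40, mu = 0.8, seed = 5)
  expect_identical(a$sigma, b$sigma)
  da <- sample_scenario(a)
  db <- sample_scenario(b)
  expect_identical(da$X, db$X)
  expect_identical(da$labels, db$labels)
})

test_that("sampling matches the scenario law", {
  sc <- scan_scenario("regular", p = 10, n = 300, mu = 1, eta = 0.3,
                      seed = 4)
  d <- sample_scenario(sc)
  # uniform class proportions within the stated LLN bound
  props <- tabulate(d$labels, 3) / 300
  expect_true(all(abs(props - 1 / 3) < 3 / sqrt(300)))
  # with vanishing covariance the samples collapse onto the class means
  sc0 <- sc
  sc0$sigma <- sc$sigma * 1e-12
  d0 <- sample_scenario(sc0)
  expect_lt(max(abs(d0$X - sc$true_model$means[d0$labels, ])), 1e-4)
  # per-class sample covariance converges entrywise to Sigma_k
  dbig <- sample_scenario(sc, n = 30000, seed = 11)
  for (k in 1:3) {
    idx <- dbig$labels == k
    emp <- cov(dbig$X[idx, ]) * (sum(idx) - 1) / sum(idx)
    expect_lt(max(abs(emp - sc$sigma[, , k])), 5 / sqrt(sum(idx)))
  }
})

test_that("two-dimensional illustration has the stated geometry", {
  d <- make_illustration_2d(seed = 6)
  expect_equal(nrow(d$X), 1000)
  expect_equal(tabulate(d$labels, 2), c(500, 500))
  # pooled within-class residual correlation near 0.8
  res <- d$X - d$true_model$means[d$labels, ]
  expect_lt(abs(cor(res[, 1], res[, 2]) - 0.8), 0.05)
  expect_equal(d$true_model$precisions[, , 1],
               matrix(c(1, -0.8, -0.8, 1), 2) / 0.36)
})

test_that("scenario truth exports as plain-text files", {
  sc <- scan_scenario("chain", p = 20, n = 40, mu = 0.7, seed = 3)
  dir <- tempfile()
  export_scenario(sc, dir)
  expect_true(file.exists(file.path(dir, "means.tsv")))
  expect_true(file.exists(file.path(dir, "scenario.json")))
  up <- upper.tri(matrix(0, 20, 20))
  for (k in 1:3) {
    el <- read.delim(file.path(dir, sprintf("network_class%d.tsv", k)))
    truth_edges <- sum(abs(sc$true_model$precisions[, , k][up]) > 1e-8)
    expect_equal(nrow(el), truth_edges)
  }
  meta <- jsonlite::fromJSON(file.path(dir, "scenario.json"))
  expect_equal(meta$family, "chain")
  expect_equal(meta$p, 20)
})
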