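test_that("penalty value matches hand evaluation", {
  # zero means + diagonal precisions carry no penalty
  m0 <- mixture_ggm(c(0.5, 0.5), matrix(0, 2, 3),
                    array(rep(diag(3), 2), c(3, 3, 2)))
  expect_equal(penalty_value(m0, 1, 1, 1), 0)
  # lambda2 = lambda3 = 0 reduces to the mean lasso
  m1 <- random_model(2, 3, seed = 2)
  expect_equal(penalty_value(m1, 0.7, 0, 0), 0.7 * sum(abs(m1$means)))
  # single off-diagonal pair, both triangles counted
  prec <- array(rep(diag(2), 2), c(2, 2, 2))
  prec[1, 2, 1] <- prec[2, 1, 1] <- 3
  prec[1, 2, 2] <- prec[2, 1, 2] <- 4
  m2 <- mixture_ggm(c(0.5, 0.5), matrix(0, 2, 2), prec, check = FALSE)
  expect_equal(penalty_value(m2, 0, 1, 1), 2 * (3 + 4) + 2 * 5)
})

test_that("mean update reduces to weighted averages when unpenalized", {
  set.seed(7)
  X <- matrix(rnorm(40), 20, 2)
  labels <- rep(1:2, each = 10)
  resp <- hard_resp(labels, 2)
  prev <- mixture_ggm(c(0.5, 0.5), matrix(0, 2, 2),
                      array(rep(diag(2), 2), c(2, 2, 2)))
  mu <- update_means(X, resp, prev, 0)
  expect_equal(mu[1, ], colMeans(X[1:10, ]))
  expect_equal(mu[2, ], colMeans(X[11:20, ]))
  # a huge penalty zeroes every coordinate (the 'otherwise' branch)
  expect_equal(update_means(X, resp, prev, 100), matrix(0, 2, 2))
  # nonpositive precision diagonal is an error
  bad <- prev
  bad$precisions[1, 1, 1] <- -1
  expect_error(update_means(X, resp, bad, 0), "diagonal")
})

test_that("mean update agrees with coordinatewise numeric maximization", {
  set.seed(11)
  X <- matrix(rnorm(10, sd = 1.2), 5, 2)
  omega <- matrix(c(2, 0.5, 0.5, 2), 2)
  prev <- mixture_ggm(1, matrix(c(0.4, -0.2), 1, 2),
                      array(omega, c(2, 2, 1)))
  resp <- hard_resp(rep(1, 5), 1)
  for (lambda1 in c(0, 0.05, 0.3)) {
    mu_pkg <- update_means(X, resp, prev, lambda1)
    mu_orc <- mean_update_numeric(X, resp, prev, lambda1)
    expect_equal(mu_pkg, mu_orc, tolerance = 1e-4)
  }
  # soft-responsibility two-cluster case
  set.seed(12)
  X2 <- matrix(rnorm(24), 12, 2)
  r <- matrix(rgamma(24, 1), 12, 2)
  r <- r / rowSums(r)
  resp2 <- structure(list(matrix = r, masses = colSums(r)),
                     class = "scan_resp")
  prev2 <- mixture_ggm(c(0.5, 0.5), rbind(c(0.5, 0), c(-0.3, 0.2)),
                       array(rep(omega, 2), c(2, 2, 2)))
  expect_equal(update_means(X2, resp2, prev2, 0.2),
               mean_update_numeric(X2, resp2, prev2, 0.2),
               tolerance = 1e-4)
})

test_that("pseudo covariances are responsibility-weighted outer products", {
  set.seed(3)
  X <- matrix(rnorm(6), 3, 2)
  r <- rbind(c(1, 0), c(0.5, 0.5), c(0, 1))
  resp <- structure(list(matrix = r, masses = colSums(r)),
                    class = "scan_resp")
  means <- rbind(c(0.2, -0.1), c(0, 0.3))
  S <- pseudo_covariances(X, resp, means)
  for (k in 1:2) {
    direct <- matrix(0, 2, 2)
    for (i in 1:3) {
      d <- X[i, ] - means[k, ]
      direct <- direct + r[i, k] * tcrossprod(d)
    }
    expect_equal(S[, , k], direct / sum(r[, k]))
  }
  # hard labels with their own means give the ML class covariance
  labels <- c(1, 1, 2)
  resph <- hard_resp(labels, 2)
  mh <- rbind(colMeans(X[1:2, , drop = FALSE]), X[3, ])
  Sh <- pseudo_covariances(X, resph, mh)
  expect_equal(Sh[, , 1],
               crossprod(sweep(X[1:2, ], 2, mh[1, ])) / 2)
  # PSD by construction
  expect_gte(min(eigen(Sh[, , 1], symmetric = TRUE)$values), -1e-12)
})

test_that("symmetrization keeps the entry of smaller magnitude", {
  s <- array(0, c(2, 2, 1))
  s[, , 1] <- matrix(c(1, 0.5, 0.3, 1), 2, byrow = TRUE)
  out <- symmetrize_minmag(s)
  expect_equal(out[, , 1], matrix(c(1, 0.3, 0.3, 1), 2))
  s[, , 1] <- matrix(c(1, -0.7, 0.2, 1), 2, byrow = TRUE)
  out <- symmetrize_minmag(s)
  expect_equal(out[, , 1], matrix(c(1, 0.2, 0.2, 1), 2))
  # symmetric input is unchanged; output always exactly symmetric
  set.seed(2)
  A <- crossprod(matrix(rnorm(16), 4))
  expect_equal(symmetrize_minmag(array(A, c(4, 4, 1)))[, , 1], A)
  B <- matrix(rnorm(16), 4)
  out2 <- symmetrize_minmag(array(B, c(4, 4, 2)))
  for (k in 1:2) expect_identical(out2[, , k], t(out2[, , k]))
})

test_that("initialization is deterministic, uniform-weighted and PD", {
  set.seed(20)
  X <- rbind(matrix(rnorm(60, -2), 20, 3), matrix(rnorm(60, 2), 20, 3))
  for (method in c("kmeans_warm", "random_responsibility")) {
    m1 <- initialize_scan(X, 2, method, seed = 9)
    m2 <- initialize_scan(X, 2, method, seed = 9)
    expect_identical(m1, m2)
    expect_equal(m1$weights, c(0.5, 0.5))
    for (k in 1:2)
      expect_gt(min(eigen(m1$precisions[, , k], symmetric = TRUE,
                          only.values = TRUE)$values), 0)
  }
  expect_error(initialize_scan(X[1:2, ], 3), "exceeds")
})
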