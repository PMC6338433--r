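test_that("component log density matches closed forms and rejects non-PD", {
  expect_equal(log_component_density(0, 0, matrix(1)), -0.5 * log(2 * pi))
  expect_equal(log_component_density(c(1, 2), c(1, 2), diag(2)),
               -log(2 * pi))
  expect_equal(log_component_density(c(1, 2), c(1, 2), 2 * diag(2)),
               -log(2 * pi) + log(2))
  # general point cross-checked against the covariance parameterization
  omega <- matrix(c(2, 0.5, 0.5, 1), 2)
  x <- c(0.3, -1)
  mu <- c(1, 0.5)
  direct <- -log(2 * pi) - 0.5 * log(det(solve(omega))) -
    0.5 * drop(t(x - mu) %*% omega %*% (x - mu))
  expect_equal(log_component_density(x, mu, omega), direct)
  expect_error(log_component_density(0, 0, matrix(-1)),
               "not positive definite")
})

test_that("observed log likelihood agrees with direct summation", {
  # two-point univariate toy evaluated without log-sum-exp
  m <- mixture_ggm(c(0.5, 0.5), matrix(c(-1, 1), 2, 1),
                   array(1, c(1, 1, 2)))
  X <- matrix(c(0, 0), 2, 1)
  direct <- sum(log(0.5 * dnorm(0, -1, 1) + 0.5 * dnorm(0, 1, 1)),
                log(0.5 * dnorm(0, -1, 1) + 0.5 * dnorm(0, 1, 1)))
  expect_equal(observed_loglik(X, m), direct)
  # K = 1 degenerates to a sum of component densities
  m1 <- random_model(1, 3, seed = 4)
  X3 <- matrix(rnorm(15), 5, 3)
  expect_equal(observed_loglik(X3, m1),
               sum(vapply(1:5, function(i)
                 log_component_density(X3[i, ], m1$means[1, ],
                                       m1$precisions[, , 1]),
                 numeric(1))))
  # invariant under component permutation
  m2 <- random_model(3, 2, seed = 5)
  perm <- c(2, 3, 1)
  m2p <- mixture_ggm(m2$weights[perm], m2$means[perm, ],
                     m2$precisions[, , perm])
  X2 <- matrix(rnorm(20), 10, 2)
  expect_equal(observed_loglik(X2, m2), observed_loglik(X2, m2p))
  expect_error(observed_loglik(matrix(0, 0, 2), m2), "empty")
})

test_that("E-step responsibilities are softmax posteriors", {
  m1 <- random_model(1, 2, seed = 1)
  X <- matrix(rnorm(10), 5, 2)
  expect_equal(unname(e_step(X, m1)$matrix), matrix(1, 5, 1))
  # symmetric two-component case: equidistant point gets (0.5, 0.5)
  m2 <- mixture_ggm(c(0.5, 0.5), rbind(c(-1, 0), c(1, 0)),
                    array(rep(diag(2), 2), c(2, 2, 2)))
  r <- e_step(matrix(c(0, 3), 1, 2), m2)
  expect_equal(unname(r$matrix[1, ]), c(0.5, 0.5))
  # scalar softmax check
  m3 <- mixture_ggm(c(0.5, 0.5), matrix(c(0, 1), 2, 1),
                    array(1, c(1, 1, 2)))
  r3 <- e_step(matrix(0, 1, 1), m3)
  ld <- c(dnorm(0, 0, 1, log = TRUE), dnorm(0, 1, 1, log = TRUE))
  expect_equal(unname(r3$matrix[1, ]), exp(ld) / sum(exp(ld)))
})

test_that("E-step rows sum to one and are relabeling-equivariant", {
  for (seed in 1:5) {
    m <- random_model(3, 4, seed = seed)
    X <- draw_mixture(m, 40, seed = seed)$X
    r <- e_step(X, m)
    expect_lt(max(abs(rowSums(r$matrix) - 1)), 1e-10)
    expect_equal(sum(r$masses), 40)
    perm <- sample(3)
    mp <- mixture_ggm(m$weights[perm], m$means[perm, ],
                      m$precisions[, , perm])
    rp <- e_step(X, mp)
    expect_equal(rp$matrix, r$matrix[, perm], tolerance = 1e-10)
    expect_true(all(is.finite(observed_loglik(X, m))))
  }
})

test_that("weight update is the normalized posterior mass", {
  resp <- hard_resp(c(1, 1, 2, 2, 2, 2), 2)
  expect_equal(update_weights(resp, 6), c(2, 4) / 6)
  resp2 <- structure(list(matrix = matrix(1 / 3, 9, 3),
                          masses = rep(3, 3)), class = "scan_resp")
  expect_equal(update_weights(resp2, 9), rep(1 / 3, 3))
  r <- rbind(c(1, 0), c(0.5, 0.5), c(0, 1))
  expect_equal(update_weights(structure(list(matrix = r,
                                             masses = colSums(r)),
                                        class = "scan_resp"), 3),
               c(0.5, 0.5))
  # empty-cluster floor keeps the output on the simplex with a warning
  re <- hard_resp(rep(1, 5), 1)
  re$matrix <- cbind(re$matrix, 0)
  re$masses <- c(5, 0)
  expect_warning(w <- update_weights(re, 5), "near-empty")
  expect_equal(sum(w), 1)
  expect_true(all(w > 0))
})

test_that("weight update stays on the simplex for random inputs", {
  for (seed in 1:10) {
    set.seed(seed)
    r <- matrix(rgamma(60, 1), 20, 3)
    r <- r / rowSums(r)
    w <- update_weights(structure(list(matrix = r, masses = colSums(r)),
                                  class = "scan_resp"), 20)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
})

test_that("mixture_ggm validates its invariants", {
  expect_error(mixture_ggm(c(0.6, 0.6), matrix(0, 2, 2),
                           array(rep(diag(2), 2), c(2, 2, 2))),
               "sum to 1")
  bad <- array(rep(diag(2), 2), c(2, 2, 2))
  bad[1, 2, 1] <- 0.5
  expect_error(mixture_ggm(c(0.5, 0.5), matrix(0, 2, 2), bad),
               "not symmetric")
  npd <- array(rep(diag(2), 2), c(2, 2, 2))
  npd[, , 2] <- matrix(c(1, 2, 2, 1), 2)
  expect_error(mixture_ggm(c(0.5, 0.5), matrix(0, 2, 2), npd),
               "not positive definite")
})
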