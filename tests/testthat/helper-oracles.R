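# Independent oracles used across the suite.  Each is deliberately naive
# (enumeration, generic numeric optimization, proximal gradient written
# from scratch) so that agreement with the package's fast paths is
# meaningful.

# O(n^2) pairwise clustering error by direct enumeration.
ce_brute <- function(est, truth) {
  n <- length(est)
  bad <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if ((est[i] == est[j]) != (truth[i] == truth[j])) bad <- bad + 1L
  }
  bad / (n * (n - 1) / 2)
}

# numeric minimizer of 0.5||z - a||^2 + t2 ||z||_1 + t3 ||z||_2 by
# Nelder-Mead from several starts
prox_numeric <- function(a, t2, t3) {
  f <- function(z) 0.5 * sum((z - a)^2) + t2 * sum(abs(z)) +
    t3 * sqrt(sum(z^2))
  best <- NULL
  for (start in list(a, 0 * a, 0.5 * a)) {
    o <- optim(start, f, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 20000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # polish: restart the simplex at the incumbent until it stalls, then
  # solve the smooth restricted problem on the incumbent's support
  repeat {
    o <- optim(best$par, f, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 20000))
    if (o$value > best$value - 1e-14) break
    best <- o
  }
  z <- best$par
  supp <- abs(z) > 1e-7
  if (any(supp)) {
    g <- function(zs) {
      full <- numeric(length(a))
      full[supp] <- zs
      f(full)
    }
    o2 <- optim(z[supp], g, method = "BFGS",
                control = list(reltol = 1e-15, maxit = 10000))
    if (o2$value <= best$value) {
      z <- numeric(length(a))
      z[supp] <- o2$par
    }
  }
  z
}

# conditional expected complete-data objective (1/n scale) for a single
# model, evaluated directly from densities; used by the mean-update oracle
qn_value <- function(X, resp, model) {
  n <- nrow(X)
  total <- 0
  for (k in seq_len(model$K)) {
    lk <- vapply(seq_len(n), function(i)
      log_component_density(X[i, ], model$means[k, ],
                            model$precisions[, , k]), numeric(1))
    total <- total + sum(resp$matrix[, k] *
                           (log(model$weights[k]) + lk))
  }
  total / n
}

# coordinatewise numeric maximization of Qn - lambda1 * sum|mu|: each
# mean coordinate in turn is maximized by golden-section search with the
# other coordinates held at their current (partially updated) values,
# responsibilities and precisions at the previous iterate
mean_update_numeric <- function(X, resp, prev, lambda1) {
  cur <- prev
  for (k in seq_len(prev$K)) {
    for (j in seq_len(prev$p)) {
      f <- function(m) {
        mod <- cur
        mod$means[k, j] <- m
        qn_value(X, resp, mod) - lambda1 * sum(abs(mod$means[k, ]))
      }
      cur$means[k, j] <- optimize(f, c(-10, 10), maximum = TRUE,
                                  tol = 1e-10)$maximum
    }
  }
  cur$means
}

# proximal-gradient (ISTA) solver for the weighted joint graphical lasso,
# with its own inline sparse-group prox and backtracking line search --
# an algorithm and code path independent of the package ADMM
jgl_ista <- function(S, w, lambda2, lambda3, iters = 4000) {
  p <- dim(S)[1]
  K <- dim(S)[3]
  omega <- array(0, c(p, p, K))
  for (k in 1:K) omega[, , k] <- diag(1 / diag(S[, , k]), p)
  smooth <- function(om) {
    v <- 0
    for (k in 1:K)
      v <- v + w[k] * (sum(S[, , k] * om[, , k]) -
                         determinant(om[, , k])$modulus)
    as.numeric(v)
  }
  grad <- function(om) {
    g <- array(0, dim(om))
    for (k in 1:K)
      g[, , k] <- w[k] * (S[, , k] - solve(om[, , k]))
    g
  }
  prox <- function(om, t2, t3) {
    for (i in 1:p) for (j in 1:p) {
      if (i == j) next
      z <- om[i, j, ]
      z <- sign(z) * pmax(abs(z) - t2, 0)
      nz <- sqrt(sum(z^2))
      z <- if (nz > t3) z * (1 - t3 / nz) else 0 * z
      om[i, j, ] <- z
    }
    om
  }
  step <- 0.5
  for (it in 1:iters) {
    g <- grad(omega)
    repeat {
      cand <- prox(omega - step * g, step * lambda2, step * lambda3)
      ok <- all(vapply(1:K, function(k)
        min(eigen(cand[, , k], symmetric = TRUE,
                  only.values = TRUE)$values) > 1e-10, logical(1)))
      if (ok && smooth(cand) <= smooth(omega) +
            sum(g * (cand - omega)) +
            sum((cand - omega)^2) / (2 * step)) break
      step <- step / 2
      if (step < 1e-12) break
    }
    if (max(abs(cand - omega)) < 1e-9) { omega <- cand; break }
    omega <- cand
    step <- min(step * 1.5, 1)
  }
  omega
}

# small well-conditioned random mixture model
random_model <- function(K, p, seed = 1) {
  set.seed(seed)
  means <- matrix(rnorm(K * p), K, p)
  prec <- array(0, c(p, p, K))
  for (k in 1:K) {
    A <- matrix(rnorm(p * p, sd = 0.2), p, p)
    prec[, , k] <- crossprod(A) + diag(p)
  }
  w <- rgamma(K, 2)
  mixture_ggm(w / sum(w), means, prec)
}

# draw from a mixture model
draw_mixture <- function(model, n, seed = 1) {
  set.seed(seed)
  labels <- sample.int(model$K, n, replace = TRUE, prob = model$weights)
  X <- matrix(rnorm(n * model$p), n, model$p)
  for (k in seq_len(model$K)) {
    idx <- labels == k
    if (!any(idx)) next
    R <- chol(chol2inv(chol(model$precisions[, , k])))
    X[idx, ] <- sweep(X[idx, , drop = FALSE] %*% R, 2,
                      model$means[k, ], "+")
  }
  list(X = X, labels = labels)
}

# hard responsibilities from labels
hard_resp <- function(labels, K) {
  n <- length(labels)
  m <- matrix(0, n, K)
  m[cbind(seq_len(n), labels)] <- 1
  structure(list(matrix = m, masses = colSums(m)), class = "scan_resp")
}
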