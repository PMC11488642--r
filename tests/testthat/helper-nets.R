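# Shared fixtures and independent numerical oracles for the test suite.

# Random symmetric network with unit-norm, pairwise-distinct binding rows.
random_symmetric_net <- function(E = 4, T_ = 6, beta = 30, seed = 1,
                                 weights = NULL) {
  set.seed(seed)
  repeat {
    Xi <- matrix(stats::runif(E * T_), E, T_)
    Xi <- Xi / sqrt(rowSums(Xi^2))
    g <- tcrossprod(Xi)
    if (E < 2 || max(g[upper.tri(g)]) < 0.95) break
  }
  fatenet(Xi, beta = beta, weights = weights)
}

# K orthonormal patterns embedded in T_ >= K dimensions.
orthogonal_net <- function(K = 3, T_ = K, beta = 30, weights = NULL) {
  Xi <- diag(K)
  if (T_ > K) Xi <- cbind(Xi, matrix(0, K, T_ - K))
  fatenet(Xi, beta = beta, weights = weights)
}

# Random sparse patterns: each of E cell types is active on k_active of T_
# TFs (random positive levels, unit norm), so types keep private TFs and
# moderate pairwise similarity -- the regime where reprogramming recipes
# have discriminating factors.
sparse_random_net <- function(E = 5, T_ = 10, k_active = 3, beta = 40,
                              seed = 1) {
  set.seed(seed)
  repeat {
    Xi <- matrix(0, E, T_)
    for (i in seq_len(E)) {
      Xi[i, sample(T_, k_active)] <- runif(k_active, 0.5, 1)
    }
    Xi <- Xi / sqrt(rowSums(Xi^2))
    g <- tcrossprod(Xi)
    if (max(g[upper.tri(g)]) < 0.8 && nrow(unique(Xi)) == E) break
  }
  fatenet(Xi, beta = beta)
}

# Two unit-norm patterns with exact cosine similarity A (plus optional
# near-orthogonal extras).
pair_net <- function(A, beta = 10, T_ = 4) {
  x1 <- c(1, 0, rep(0, T_ - 2))
  x2 <- c(A, sqrt(1 - A^2), rep(0, T_ - 2))
  fatenet(rbind(p1 = x1, p2 = x2), beta = beta)
}

# Central-difference gradient and Jacobian oracles (no matrix calculus).
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

fd_jac <- function(f, x, h = 1e-6) {
  n <- length(f(x))
  J <- matrix(NA_real_, n, length(x))
  for (j in seq_along(x)) {
    e <- numeric(length(x)); e[j] <- h
    J[, j] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  J
}

# Plain Euler integration, independent of the package's integrators; used
# as a trajectory oracle at small step size.
euler_path <- function(net, x0, t_end, dt = 0.002, beta = NULL) {
  x <- x0
  for (i in seq_len(ceiling(t_end / dt))) {
    x <- pmax(x + dt * drift(net, x, beta = beta), 0)
  }
  x
}

expect_cosine_near <- function(x, y, tol = 1e-3) {
  expect_lt(1 - sum(x * y) / sqrt(sum(x^2) * sum(y^2)), tol)
}
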