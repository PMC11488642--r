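# Constant-similarity family: K unit-norm rows sharing an m0-block, each
# with a private m-block; every pairwise inner product equals m0/(m0+m)
# exactly, which makes closed forms exactly comparable to potential().
make_const_A <- function(K, m0, m) {
  T_ <- m0 + K * m
  Xi <- matrix(0, K, T_)
  for (k in 1:K) {
    Xi[k, seq_len(m0)] <- 1
    Xi[k, m0 + (k - 1) * m + seq_len(m)] <- 1
  }
  Xi / sqrt(m0 + m)
}

test_that("pattern families are constructed as specified", {
  fam <- pattern_family(K = 12, N = 30, eta = 0.2, N_prime = 3,
                        N_doubleprime = 5, K_prime = 4, seed = 1)
  smp <- sample_pattern_family(fam)
  Xi <- smp$binding
  expect_equal(dim(Xi), c(16L, 38L))
  # every row: exactly round(eta*N) + N' active entries, each equal to a
  for (k in 1:16) {
    nz <- Xi[k, Xi[k, ] > 0]
    expect_length(nz, 6 + 3)
    expect_true(all(abs(nz - fam$a) < 1e-12))
    expect_equal(sum(Xi[k, ]^2), 1, tolerance = 1e-12)
  }
  # related rows all carry the always-active block
  expect_true(all(Xi[1:12, 31:33] > 0))
  # rows are pairwise distinct
  expect_equal(nrow(unique(Xi)), 16L)
  # reproducible from the seed
  expect_identical(sample_pattern_family(fam)$binding, Xi)

  # forced collision: eta = 1 with no shared block cannot give K >= 2
  expect_error(sample_pattern_family(pattern_family(K = 3, N = 5, eta = 1)),
               "distinct")
  expect_error(pattern_family(K = 5, N = 20, eta = 0.01), "eta \\* N")
})

test_that("analytic similarity statistics match their construction", {
  fam <- pattern_family(K = 10, N = 40, eta = 0.25, N_prime = 10, seed = 2)
  st <- similarity_stats(fam)
  expect_equal(st$C, 1 - 1 / (10 + 10), tolerance = 1e-12)
  # eta = 1: identical related patterns, A = 1
  expect_equal(similarity_stats(pattern_family(1, 10, 1))$A, 1)
  # dominant always-active block drives A toward 1
  big <- similarity_stats(pattern_family(5, 10, 0.5, N_prime = 1000))
  expect_gt(big$A, 0.99)
  # continuous vs discrete agree when eta*N is an integer
  st2 <- similarity_stats(fam, discrete = FALSE)
  expect_equal(st$A, st2$A, tolerance = 1e-12)
})

test_that("empirical family statistics agree with the analytic forms", {
  fam <- fixture_celegans_family()
  A_emp <- vapply(1:50, function(s) {
    empirical_similarity_stats(sample_pattern_family(fam, seed = s)$binding)$A
  }, numeric(1))
  st <- similarity_stats(fam)
  se <- stats::sd(A_emp) / sqrt(length(A_emp))
  expect_lt(abs(mean(A_emp) - st$A), 3 * se)

  # cross-family inner products on a family with unrelated members
  fam2 <- pattern_family(K = 30, N = 40, eta = 0.25, K_prime = 30,
                         N_doubleprime = 20, seed = 3)
  B_emp <- vapply(1:30, function(s) {
    smp <- sample_pattern_family(fam2, seed = s)
    empirical_similarity_stats(smp$binding, smp$family)$B
  }, numeric(1))
  stB <- similarity_stats(fam2)
  seB <- stats::sd(B_emp) / sqrt(length(B_emp))
  expect_lt(abs(mean(B_emp) - stB$B), 3 * seB)
})

test_that("averaged-pattern energy matches potential() on explicit families", {
  Xi <- make_const_A(K = 8, m0 = 1, m = 7)
  A <- sum(Xi[1, ] * Xi[2, ])
  net <- fatenet(Xi, beta = 1)
  for (n in c(1, 2, 4, 8)) for (beta in c(2, 8, 30)) {
    xbar <- colMeans(Xi[seq_len(n), , drop = FALSE])
    expect_equal(averaged_pattern_energy(A, A, n, beta, K = 8),
                 potential(net, xbar, beta = beta), tolerance = 1e-10)
  }
  # subset of size 1 reduces to the single-pattern energy
  expect_equal(averaged_pattern_energy(A, A, 1, 50, K = 8),
               potential(net, Xi[1, ], beta = 50), tolerance = 1e-10)
  # at fixed beta the energy rises as the background similarity B drops
  V <- vapply(c(0.5, 0.3, 0.1, 0), function(B) {
    averaged_pattern_energy(0.5, B, 3, beta = 4, K = 10)
  }, numeric(1))
  expect_true(all(diff(V) > 0))
})

test_that("bipotent critical temperatures bracket the numeric crossings", {
  expect_true(is.infinite(critical_beta_bipotent(1)))
  A_seq <- c(0.1, 0.4, 0.7)
  expect_true(all(diff(critical_beta_bipotent(A_seq)) > 0))

  for (A in A_seq) {
    net <- fatenet(rbind(c(1, 0, 0), c(A, sqrt(1 - A^2), 0)), beta = 1)
    xbar <- colMeans(net$binding)
    f <- function(b) {
      potential(net, xbar, beta = b) - potential(net, net$binding[1, ], beta = b)
    }
    bc_num <- stats::uniroot(f, c(0.5, 300))$root
    # the exact crossing solves u = 4 log(2 / (1 + exp(-u))) with
    # u = beta (1 - A); its asymptotic form (dropping the exp term) is the
    # commitment value 4 log(2) / (1 - A)
    u_star <- stats::uniroot(function(u) u - 4 * log(2 / (1 + exp(-u))),
                             c(1, 4))$root
    expect_equal(bc_num * (1 - A), u_star, tolerance = 1e-4)
    bc_ana <- critical_beta_bipotent(A, "commitment")
    expect_lt(abs(bc_num - bc_ana) / bc_ana, 0.15)
    expect_gt(bc_ana, bc_num)  # the asymptotic form overshoots, consistently
  }
})

test_that("global-average critical temperature matches the numeric crossing", {
  for (cfg in list(c(8, 1, 7), c(12, 2, 6), c(20, 1, 9))) {
    K <- cfg[1]
    Xi <- make_const_A(K, cfg[2], cfg[3])
    A <- sum(Xi[1, ] * Xi[2, ])
    net <- fatenet(Xi, beta = 1)
    xbar <- colMeans(Xi)
    f <- function(b) {
      potential(net, xbar, beta = b) - potential(net, Xi[1, ], beta = b)
    }
    bc_num <- stats::uniroot(f, c(0.5, 500))$root
    bc_ana <- critical_beta_global(A, K)
    expect_lt(abs(bc_num - bc_ana) / bc_ana, 0.05)
  }
})

test_that("specification gain: value, invariance, compositional consistency", {
  chi <- specification_gain_chi(K = 118, N = 68, eta = 0.1)
  expect_equal(round(chi, 1), 1.8)
  expect_equal(chi, 2 * log(2) * 0.1 * 0.9 * 68 / log(118), tolerance = 1e-12)

  # invariant to the always-active block at fixed (K, N, eta)
  for (np in c(0, 5, 50)) {
    fam <- pattern_family(K = 118, N = 68, eta = 0.1, N_prime = np)
    expect_equal(specification_gain_chi(fam), chi, tolerance = 1e-12)
  }

  # chi equals the ratio of the two critical temperatures (continuous
  # stats, up to the 1 - 1/K finite-size factor)
  st <- similarity_stats(fixture_celegans_family(), discrete = FALSE)
  ratio <- critical_beta_bipotent(st$C) / critical_beta_global(st$A, 118)
  expect_equal(ratio, chi * (1 - 1 / 118), tolerance = 1e-10)
})

test_that("chi is close to the measured potential-crossing ratio", {
  # explicit family: 16 related patterns at constant A, plus a two-bit
  # variant of pattern 1; both transitions measured from potential() alone
  K <- 16
  Xi <- make_const_A(K, m0 = 1, m = 7)
  A <- sum(Xi[1, ] * Xi[2, ])
  v <- Xi[1, ]
  act <- which(v > 0); inact <- which(v == 0)
  v[act[2]] <- 0; v[inact[1]] <- Xi[1, act[2]]
  C <- sum(Xi[1, ] * v)
  Xi_f <- rbind(Xi, v)
  rownames(Xi_f) <- c(paste0("rel", 1:K), "variant")
  net_f <- fatenet(Xi_f, beta = 1)

  xbar_K <- colMeans(Xi)
  f1 <- function(b) {
    potential(net_f, xbar_K, beta = b) - potential(net_f, Xi[2, ], beta = b)
  }
  b1 <- stats::uniroot(f1, c(0.5, 400))$root
  pair <- (Xi[1, ] + v) / 2
  f2 <- function(b) {
    potential(net_f, pair, beta = b) - potential(net_f, v, beta = b)
  }
  b2 <- stats::uniroot(f2, c(0.5, 400))$root

  chi_ana <- critical_beta_bipotent(C) / critical_beta_global(A, K)
  expect_lt(abs(b2 / b1 - chi_ana), 0.5)
})

test_that("two-threshold scan brackets both operational temperatures", {
  # orthogonal control: the global average destabilizes at beta = K exactly
  XiO <- diag(6)
  scO <- two_threshold_scan(XiO, beta_grid = c(1, 2, 3, 4, 5, 5.5, 6, 6.5,
                                               7, 8, 10, 14))
  expect_lt(abs(scO$beta_destabilize - 6) / 6, 0.1)
  expect_true(is.finite(scO$beta_full_specification))
  expect_gt(scO$beta_full_specification, 0)

  # small sparse family: variant-pair specification needs a sharper
  # competition than the observed classes alone
  fam <- pattern_family(K = 10, N = 20, eta = 0.25, seed = 4)
  Xi <- sample_pattern_family(fam)$binding
  grid <- c(1, 2, 4, 6, 9, 14, 20, 30, 45)
  sc_cls <- two_threshold_scan(Xi, grid, scope = "classes")
  sc_var <- two_threshold_scan(Xi, grid, scope = "variant_pair")
  expect_true(is.finite(sc_cls$beta_full_specification))
  expect_gte(sc_var$beta_full_specification, sc_cls$beta_full_specification)
  expect_equal(sc_var$beta_destabilize, sc_cls$beta_destabilize,
               tolerance = 0.2)
})
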