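test_that("refine_fixed_point polishes patterns, averages and saddles", {
  net <- random_symmetric_net(4, 6, beta = 200, seed = 1)
  fp <- refine_fixed_point(net, net$binding[2, ])
  expect_true(fp$converged && fp$stable)
  expect_lt(fp$residual, 1e-10)
  expect_lt(sqrt(sum((unname(fp$x) - net$binding[2, ])^2)), 1e-6)
  expect_identical(fp$label, "pattern:EN2")

  # beta = 0: the row average of Q is the unique stable fixed point
  fp0 <- refine_fixed_point(net, colMeans(net$coupling), beta = 0)
  expect_true(fp0$converged && fp0$stable)
  expect_equal(unname(fp0$x), unname(colMeans(net$coupling)), tolerance = 1e-8)

  # a pair average above its critical beta is a converged saddle
  net2 <- orthogonal_net(2, beta = 6)   # pitchfork at beta = 2
  fps <- refine_fixed_point(net2, c(0.5, 0.5), pre_relax = 0)
  expect_true(fps$converged)
  expect_false(fps$stable)
  expect_gt(fps$leading_eigenvalue, 0)
})

test_that("orthogonal patterns yield exactly K attractors at high beta", {
  net <- orthogonal_net(4, T_ = 5, beta = 200)
  aset <- enumerate_attractors(net, n_random_restarts = 40, seed = 2)
  expect_equal(nrow(aset$summary), 4L)
  expect_setequal(aset$summary$label, paste0("pattern:EN", 1:4))
  expect_true(all(aset$summary$stable))
  expect_true(all(aset$summary$residual < 1e-8))
})

test_that("enumeration agrees with a dense-restart oracle on a random net", {
  net <- random_symmetric_net(5, 7, beta = 100, seed = 3)
  aset <- enumerate_attractors(net, n_random_restarts = 60, seed = 4)

  # oracle: 200 uniform seeds, plain Euler integration, naive dedup
  set.seed(5)
  finals <- matrix(NA_real_, 200, 7)
  for (i in 1:200) {
    finals[i, ] <- euler_path(net, runif(7, 0, max(net$coupling)),
                              t_end = 60, dt = 0.02)
  }
  reps <- finals[1, , drop = FALSE]
  for (i in 2:200) {
    d <- sqrt(rowSums(sweep(reps, 2, finals[i, ])^2))
    if (min(d) > 1e-2) reps <- rbind(reps, finals[i, ])
  }
  expect_equal(nrow(aset$summary), nrow(reps))
  for (i in seq_len(nrow(reps))) {
    d <- sqrt(rowSums(sweep(aset$states, 2, reps[i, ])^2))
    expect_lt(min(d), 1e-2)
  }
})

test_that("attractor count is 1 at beta ~ 0 and K at large beta", {
  net <- random_symmetric_net(4, 6, beta = 300, seed = 6)
  a0 <- enumerate_attractors(net, beta = 1e-3, n_random_restarts = 20, seed = 7)
  expect_equal(nrow(a0$summary), 1L)
  expect_equal(unname(a0$states[1, ]), unname(colMeans(net$coupling)),
               tolerance = 1e-4)
  aK <- enumerate_attractors(net, n_random_restarts = 40, seed = 8)
  expect_equal(nrow(aK$summary), 4L)
})

test_that("stable attractors capture a 1%-perturbed restart cloud", {
  net <- random_symmetric_net(3, 5, beta = 120, seed = 9)
  aset <- enumerate_attractors(net, n_random_restarts = 20, seed = 10)
  set.seed(11)
  for (i in seq_len(nrow(aset$states))) {
    x <- aset$states[i, ]
    for (r in 1:20) {
      z <- pmax(x * (1 + 0.01 * rnorm(5)), 0)
      xf <- euler_path(net, z, t_end = 40, dt = 0.02)
      expect_lt(sqrt(sum((xf - x)^2)), 1e-3)
    }
  }
})

test_that("pattern stability report flags dominated and misaligned patterns", {
  net <- random_symmetric_net(4, 6, beta = 200, seed = 12)
  rep1 <- pattern_stability_report(net)
  expect_true(all(rep1$is_stable))
  expect_true(all(rep1$cosine_condition_ok))

  # duplicate a row at doubled norm: the weaker twin is dominated
  Xi <- net$binding
  Xi2 <- rbind(Xi, weak = Xi[1, ] / 2)   # twin of EN1 at half norm
  Xi2[1, ] <- Xi[1, ] * 1               # EN1 keeps unit norm (the stronger twin)
  net2 <- fatenet(Xi2, beta = 200)
  for (b in c(50, 200, 1000)) {
    r <- pattern_stability_report(net2, beta = b)
    expect_false(r$is_stable[r$pattern == "weak"])
    expect_false(r$cosine_condition_ok[r$pattern == "weak"])
  }

  # permuted coupling rows: misaligned patterns flagged
  net3 <- fatenet(net$binding, coupling = net$binding[c(2, 1, 3, 4), ],
                  beta = 200)
  r3 <- pattern_stability_report(net3)
  expect_false(r3$cosine_condition_ok[1])
  expect_false(r3$cosine_condition_ok[2])
  expect_true(all(r3$cosine_condition_ok[3:4]))
})

test_that("subset averages behave as progenitors", {
  # global average at beta ~ 0 is stable
  net <- random_symmetric_net(4, 6, beta = 50, seed = 13)
  g <- subset_average_stability(net, 1:4, beta = 0.01)
  expect_true(g$is_fixed_point && g$is_stable)

  # similar pair + near-orthogonal third: pair average stable at
  # intermediate beta, unstable at large beta
  Xi <- rbind(a = c(1, 0, 0, 0),
              b = c(0.8, 0.6, 0, 0),      # cos(a, b) = 0.8
              c = c(0, 0, 1, 0))
  net2 <- fatenet(Xi, beta = 1)
  mid <- subset_average_stability(net2, c(1, 2), beta = 6)
  expect_true(mid$is_fixed_point && mid$is_stable)
  hi <- subset_average_stability(net2, c(1, 2), beta = 40)
  expect_false(hi$is_stable)

  # singleton subset at high beta is the pattern itself
  s <- subset_average_stability(net2, 2, beta = 40)
  expect_true(s$is_fixed_point && s$is_stable)
  expect_cosine_near(unname(s$fixed_point$x), Xi[2, ], 1e-3)

  expect_error(subset_average_stability(net2, integer(0)), "non-empty")
})

test_that("bifurcation scan recovers the analytic stability windows", {
  # two patterns at cosine A plus a near-orthogonal third
  A <- 0.6
  Xi <- rbind(p1 = c(1, 0, 0, 0), p2 = c(A, sqrt(1 - A^2), 0, 0),
              p3 = c(0, 0, 1, 0))
  net <- fatenet(Xi, beta = 1)
  grid <- c(0.2, 0.5, 1, 2, 3, 4, 5, 6, 8, 10, 14, 20, 30)
  sc <- bifurcation_scan_beta(net, grid)

  # global average: stability interval starts at the bottom of the grid
  gl <- sc[sc$label == "average:p1,p2,p3", ]
  expect_equal(gl$beta_lo[1], grid[1])

  # each pattern: stable up to the top of the grid
  for (p in c("pattern:p1", "pattern:p2", "pattern:p3")) {
    rows <- sc[sc$label == p, ]
    expect_equal(rows$beta_hi[nrow(rows)], grid[length(grid)])
  }

  # the bipotent pair destabilizes at 2/(1-A) within 5%
  pr <- sc[sc$label == "average:p1,p2", ]
  expect_gt(nrow(pr), 0)
  beta_num <- pr$beta_hi[nrow(pr)]
  beta_ana <- critical_beta_bipotent(A, type = "destabilization")
  expect_lt(abs(beta_num - beta_ana) / beta_ana, 0.05)
})

test_that("pattern stability intervals are contiguous in beta", {
  net <- random_symmetric_net(3, 5, beta = 1, seed = 14)
  grid <- c(1, 2, 5, 10, 20, 50, 100, 200)
  sc <- bifurcation_scan_beta(net, grid)
  for (p in paste0("pattern:EN", 1:3)) {
    rows <- sc[sc$label == p, ]
    expect_equal(nrow(rows), 1L)  # a single run: once stable, stays stable
    expect_equal(rows$beta_hi, grid[length(grid)])
  }
})
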