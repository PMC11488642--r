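# Two orthogonal-ish fates sharing one TF: A = {TF1, TF2}, B = {TF2, TF3};
# TF3 is private to B, TF2 is shared.
shared_tf_net <- function(beta = 15) {
  Xi <- rbind(A = c(1, 1, 0), B = c(0, 1, 1)) / sqrt(2)
  fatenet(Xi, beta = beta)
}

test_that("recipe construction validates its fields", {
  expect_error(recipe(character(0)), "at least one factor")
  expect_error(recipe("TF1", delta = -1), "nonnegative")
  expect_error(recipe("TF1", delta = 0), "positive")
  expect_error(recipe("TF1", duration = 0), "duration")
  r <- recipe(c("TF1", "TF3"), delta = c(1, 2))
  expect_s3_class(r, "fatenet_recipe")
})

test_that("near-zero forcing leaves the source attractor in place", {
  net <- shared_tf_net()
  res <- apply_recipe(net, net$coupling[1, ], recipe("TF3", delta = 1e-9))
  expect_identical(res$final, res$source)
  expect_false(res$success)
})

test_that("overexpressing a private target TF reprograms; a shared TF does not", {
  net <- shared_tf_net()
  # TF3: maximal binding to B, zero to A -> transition A -> B
  res <- apply_recipe(net, net$coupling[1, ], recipe("TF3", delta = 1))
  expect_identical(res$source, "A")
  expect_identical(res$final, "B")
  expect_true(res$success)
  # TF2 is bound equally by both: no transition
  res2 <- apply_recipe(net, net$coupling[1, ], recipe("TF2", delta = 1))
  expect_identical(res2$final, "A")
  expect_false(res2$success)
  # the withdrawn landscape is intact: final state is an unforced fixed point
  xf <- res$trajectory$states[nrow(res$trajectory$states), ]
  expect_lt(sqrt(sum(drift(net, xf)^2)), 1e-6)
  # and the network parameters were never modified
  expect_identical(net$weights, c(0, 0))
})

test_that("recipe scores are the binding-weighted forcing with its margin", {
  net <- random_symmetric_net(4, 6, beta = 40, seed = 1)
  # unit delta on one TF: scores are that binding column
  sc <- recipe_score(net, 2, recipe("TF3", delta = 1))
  expect_equal(unname(sc$scores), unname(net$binding[, 3]), tolerance = 1e-12)
  expect_equal(sc$margin,
               unname(net$binding[2, 3] - max(net$binding[-2, 3])),
               tolerance = 1e-12)
  # vanishing delta: all scores ~ 0, margin ~ 0
  sc0 <- recipe_score(net, 1, recipe("TF1", delta = 1e-300))
  expect_lt(max(abs(sc0$scores)), 1e-250)
})

test_that("the greedy first factor matches the exhaustive single-TF optimum", {
  for (seed in 1:4) {
    net <- random_symmetric_net(5, 8, beta = 60, seed = seed)
    k <- 1 + (seed %% 5)
    # independent arithmetic oracle over all single-TF recipes
    margins <- vapply(seq_len(8), function(j) {
      s <- net$binding[, j]
      s[k] - max(s[-k])
    }, numeric(1))
    best_oracle <- max(margins)
    ranked <- rank_candidate_factors(net, k, max_factors = 1)
    expect_equal(ranked$margin[1], best_oracle, tolerance = 1e-12)
    best_tfs <- net$tf_names[margins == best_oracle]
    expect_true(ranked$factors[1] %in% best_tfs)
  }
})

test_that("greedy selection beats or ties all two-factor recipes on a near-twin target", {
  # two near-identical patterns: only TF4 discriminates them
  Xi <- rbind(a = c(1, 1, 1, 0.2, 0), b = c(1, 1, 1, 0, 0.2))
  Xi <- Xi / sqrt(rowSums(Xi^2))
  net <- fatenet(Xi, beta = 80)
  ranked <- rank_candidate_factors(net, "a", max_factors = 2)
  expect_true("TF4" %in% strsplit(ranked$factors[nrow(ranked)], ",")[[1]])
  expect_gt(ranked$margin[1], 0)
  # margins are non-decreasing in recipe size
  expect_true(all(diff(ranked$margin) >= 0))
  # brute force over all <= 2-TF unit recipes
  best2 <- -Inf
  for (j in 1:5) for (l in j:5) {
    d <- numeric(5); d[j] <- d[j] + 1; d[l] <- d[l] + 1
    s <- drop(net$binding %*% d)
    best2 <- max(best2, s[1] - s[2])
  }
  expect_gte(ranked$margin[nrow(ranked)] + 1e-12, best2 / 2)  # delta = 1 scale
})

test_that("greedy margins are non-decreasing on the shipped fixtures", {
  for (net in list(fixture_progenitor_toy()$net,
                   random_symmetric_net(5, 8, beta = 60, seed = 7))) {
    for (k in seq_len(nrow(net$binding))) {
      rk <- rank_candidate_factors(net, k, max_factors = 3)
      expect_true(all(diff(rk$margin) >= -1e-12))
    }
  }
})

test_that("verification: top recipes succeed under noise, weak recipes fail", {
  set.seed(2)
  net <- random_symmetric_net(5, 10, beta = 40, seed = 11)
  k <- 3
  rec <- attr(rank_candidate_factors(net, k, max_factors = 2), "recipes")
  rec <- rec[[length(rec)]]
  src <- which.min(tcrossprod(net$binding)[k, -k])  # most distant source
  src <- setdiff(seq_len(5), k)[src]
  v <- verify_recipe(net, src, k, rec, n_noise_replicates = 5, sigma = 0.01,
                     seed = 3)
  expect_equal(v$success_rate, 1.0)

  # a vanishing recipe reaches nothing
  v0 <- verify_recipe(net, src, k, recipe(rec$factors, delta = 1e-9),
                      n_noise_replicates = 2, sigma = 0.01, seed = 4)
  expect_equal(v0$success_rate, 0.0)

  # a recipe with negative margin for the target fails as well
  worst_tf <- which.min(net$binding[k, ] - apply(net$binding[-k, ], 2, max))
  bad <- recipe(net$tf_names[worst_tf], delta = 1)
  expect_lt(recipe_score(net, k, bad)$margin, 0)
  vb <- verify_recipe(net, src, k, bad, n_noise_replicates = 2, sigma = 0.01,
                      seed = 5)
  expect_equal(vb$success_rate, 0.0)
})
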