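test_that("staged annealing walks the progenitor hierarchy to the induced fate", {
  fx <- fixture_progenitor_toy()
  tr <- anneal(fx$net, fx$x0, fx$schedule)
  fin <- assign_identity(fx$net, tr$states[nrow(tr$states), ])
  expect_identical(fin$label, "EN5")
  expect_lt(fin$distance, 1e-3)

  pl <- detect_plateaus(tr, fx$net)
  expect_equal(nrow(pl), 2L)
  expect_identical(pl$label[1], "average:EN1,EN2,EN3,EN4,EN5,EN6")
  expect_identical(pl$label[2], "average:EN5,EN6")
  expect_true(all(pl$distance < 0.05))
})

test_that("beta held at zero converges to the global average with no plateaus", {
  fx <- fixture_progenitor_toy()
  sch0 <- anneal_schedule(0, 0, duration = 60)
  tr <- anneal(fx$net, fx$x0, sch0)
  xT <- tr$states[nrow(tr$states), ]
  gavg <- unname(colMeans(fx$net$coupling))
  # beta = 0 fixed point: softmax(w) weighted average (w5 = 0.05 biases it
  # slightly); it stays within a hair of the plain global average
  expect_cosine_near(xT, gavg, 1e-3)
  pl <- detect_plateaus(tr, fx$net)
  expect_equal(nrow(pl), 0L)   # the terminal rest is not a progenitor
})

test_that("annealing with noise is reproducible under a fixed seed", {
  fx <- fixture_progenitor_toy()
  sch <- anneal_schedule(0, 20, duration = 30)
  a <- anneal(fx$net, fx$x0, sch, noise = noise_spec(0.01, seed = 5))
  b <- anneal(fx$net, fx$x0, sch, noise = noise_spec(0.01, seed = 5))
  expect_identical(a$states, b$states)
})

test_that("two orthogonal fates: one multipotent plateau before commitment", {
  net <- orthogonal_net(2, T_ = 4, beta = 12)
  sch <- anneal_schedule(0, 12, duration = 60, hold_start = 20)
  tr <- anneal(net, x0 = c(0.9, 0.1, 0, 0), sch,
               noise = noise_spec(0.005, seed = 3))
  pl <- detect_plateaus(tr, net, speed_threshold = 0.03)
  expect_gte(nrow(pl), 1L)
  expect_identical(pl$label[1], "average:EN1,EN2")
  fin <- assign_identity(net, tr$states[nrow(tr$states), ])
  expect_lt(fin$distance, 0.05)  # committed to a single fate
})

test_that("identity assignment is exact, tie-aware and noise-tolerant", {
  net <- orthogonal_net(3, T_ = 5, beta = 20)
  for (k in 1:3) {
    id <- assign_identity(net, net$coupling[k, ])
    expect_identical(id$label, paste0("EN", k))
    expect_equal(id$distance, 0, tolerance = 1e-12)
    expect_false(id$tie)
  }
  mid <- assign_identity(net, colMeans(net$coupling[1:2, ]))
  expect_true(mid$tie)
  expect_identical(mid$label, "EN1")  # lowest index wins

  set.seed(6)
  for (r in 1:50) {
    x <- pmax(0.9 * net$coupling[2, ] + abs(rnorm(5, sd = 0.05 * 0.9 / sqrt(5))), 0)
    expect_identical(assign_identity(net, x)$label, "EN2")
  }
})

test_that("balanced differentiation applies the stated weight feedback", {
  net <- orthogonal_net(3, beta = 50)
  res <- balanced_differentiation(net, k_max = 1, sigma = 0.01, seed = 2)
  expect_equal(sum(res$counts), 1)
  committed <- names(res$counts)[res$counts == 1]
  if (committed != "uncommitted") {
    i <- match(committed, net$enhancer_names)
    w_expect <- numeric(3); w_expect[i] <- -0.5
    w_expect <- w_expect - mean(w_expect)
    expect_equal(res$weights, w_expect, tolerance = 1e-12)
  }

  # without noise all runs are identical: the outcome set degenerates
  res0 <- balanced_differentiation(net, k_max = 3, sigma = 0, seed = 1)
  expect_equal(length(unique(res0$labels)), 1L)
})

test_that("feedback balances lineage production on a short run", {
  net <- orthogonal_net(2, beta = 50)
  res <- balanced_differentiation(net, k_max = 10, sigma = 0.01, seed = 8)
  expect_equal(unname(res$counts[["uncommitted"]]), 0)
  expect_gte(min(res$counts[c("EN1", "EN2")]), 2)
  # binding and coupling are untouched; only w moves
  expect_equal(length(res$weights), 2L)
})

test_that("lineage trees cluster by cosine similarity with deterministic ties", {
  # duplicated profile merges first at height ~ 0
  prof <- rbind(a1 = c(1, 0, 0), a2 = c(1, 0, 0), b = c(0, 1, 0))
  tree <- lineage_tree(prof)
  expect_equal(tree$hclust$height[1], 0, tolerance = 1e-12)
  nwk <- tree_to_newick(tree)
  expect_match(nwk, "\\(a1:0,a2:0\\)|\\(a2:0,a1:0\\)")

  # exhaustive 3-leaf case: cos(1,2) = 0.8 >> cos(*, 3) = 0.1
  p1 <- c(1, 0, 0); p2 <- c(0.8, 0.6, 0)
  p3 <- 0.1 * p1 + 0.1 * p2; p3[3] <- sqrt(1 - sum(p3^2))
  pr <- rbind(t1 = p1, t2 = p2, t3 = p3)
  tw <- lineage_tree(pr)
  expect_match(tree_to_newick(tw), "\\(t1:[0-9.e-]+,t2:")

  expect_error(lineage_tree(rbind(a = c(0, 0), b = c(1, 0))), "zero-norm")
  expect_error(lineage_tree(pr[1, , drop = FALSE]), "at least 2")
})

test_that("newick output round-trips through a standard parser", {
  # two leaves: branch lengths equal the merge height
  prof <- rbind(A = c(1, 0.2, 0), B = c(0, 0.2, 1))
  tr <- lineage_tree(prof)
  h <- tr$hclust$height[1]
  expect_identical(tree_to_newick(tr),
                   sprintf("(A:%s,B:%s);", format(h, digits = 10),
                           format(h, digits = 10)))

  set.seed(9)
  prof10 <- matrix(runif(10 * 12), 10,
                   dimnames = list(paste0("L", 1:10), NULL))
  tr10 <- lineage_tree(prof10)
  ph <- ape::read.tree(text = tree_to_newick(tr10))
  expect_setequal(ph$tip.label, paste0("L", 1:10))
  # clade sets of the parsed tree match the hclust clusters
  clades_ph <- lapply(ape::prop.part(ph), function(i) sort(ph$tip.label[i]))
  clades_hc <- lapply(2:9, function(k) {
    ct <- stats::cutree(tr10$hclust, k)
    lapply(split(names(ct), ct), sort)
  })
  clades_hc <- unique(do.call(c, clades_hc))
  for (cl in clades_ph) {
    if (length(cl) %in% 2:9) expect_true(list(cl) %in% clades_hc)
  }
  # leaf-to-root distance equals the root height (branch lengths are
  # height differences)
  depths <- ape::node.depth.edgelength(ph)
  expect_equal(unname(depths[1:10]),
               rep(max(tr10$hclust$height), 10), tolerance = 1e-8)
})

test_that("nested-block profiles recover the generating hierarchy", {
  ref <- ape::read.tree(text = synthetic_hematopoiesis_profiles(1)$newick)
  ref_clades <- lapply(ape::prop.part(ref), function(i) sort(ref$tip.label[i]))
  for (seed in 1:20) {
    syn <- synthetic_hematopoiesis_profiles(seed)
    tr <- lineage_tree(syn$profiles)
    ph <- ape::read.tree(text = tree_to_newick(tr))
    got <- lapply(ape::prop.part(ph), function(i) sort(ph$tip.label[i]))
    expect_setequal(got, ref_clades)
  }
})
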