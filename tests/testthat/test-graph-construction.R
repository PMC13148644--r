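test_that("every construction method satisfies the weight-matrix invariants", {
  map <- build_tonotopic_map(12)
  set <- generate_stimulus_set(15, seed = 31)
  X <- build_signal_matrix(set, map)
  graphs <- list(learn_graph_smooth(X),
                 correlation_graph(X),
                 frequency_graph(map),
                 linear_graph(map))
  for (g in graphs) {
    expect_equal(g$W, t(g$W))
    expect_equal(diag(g$W), rep(0, g$n))
    expect_true(all(g$W >= 0))
    expect_equal(as.numeric(g$L %*% rep(1, g$n)), rep(0, g$n),
                 tolerance = 1e-10)
    expect_gte(min(eigen(g$L, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("identical signal rows attract the maximal learned weight", {
  set.seed(41)
  X <- matrix(rnorm(5 * 40), 5, 40)
  X[2, ] <- X[1, ]   # zero distance pair (1,2)
  g <- learn_graph_smooth(X, smooth_learn_config(beta = 0.5))
  expect_equal(max(g$W), g$W[1, 2])
  # with beta = 0 the same instance is unbounded and must be refused
  expect_error(learn_graph_smooth(X, smooth_learn_config(beta = 0)),
               "unbounded")
})

test_that("learner on planted two-block signals recovers the blocks", {
  n <- 20
  block <- rep(1:2, each = n / 2)
  within_frac <- vapply(1:10, function(s) {
    set.seed(s)
    base <- matrix(rnorm(2 * 60), 2, 60)   # one latent signal per block
    X <- base[block, ] + matrix(rnorm(n * 60, sd = 0.2), n, 60)
    g <- learn_graph_smooth(X)
    same <- outer(block, block, "==")
    sum(g$W[same]) / sum(g$W)
  }, numeric(1))
  expect_true(all(within_frac >= 0.70))
})

test_that("training signals are smoother on the learned graph than on random rewirings", {
  map <- build_tonotopic_map(15)
  set <- generate_stimulus_set(20, seed = 51)
  X <- build_signal_matrix(set, map)
  g <- learn_graph_smooth(X)
  Xs <- (X$values - rowMeans(X$values)) / apply(X$values, 1, sd)
  energy <- function(W) {
    L <- diag(rowSums(W)) - W
    sum(diag(t(Xs) %*% L %*% Xs)) / sum(W)
  }
  e_learned <- energy(g$W)
  ut <- which(upper.tri(g$W))
  w <- g$W[ut]
  set.seed(99)
  e_random <- vapply(1:100, function(k) {
    Wr <- matrix(0, g$n, g$n)
    Wr[sample(ut)] <- w          # same weight multiset, random placement
    Wr <- Wr + t(Wr)
    energy(Wr)
  }, numeric(1))
  expect_true(all(e_learned < e_random))
})

test_that("correlation graph matches its closed-form cases", {
  set.seed(61)
  X <- matrix(rnorm(3 * 10000), 3, 10000)
  X[2, ] <- X[1, ] * 2 + 5        # perfectly correlated with node 1
  g <- correlation_graph(X)
  expect_equal(g$W[1, 2], 1)
  expect_lt(g$W[1, 3], 0.05)      # independent rows
  expect_equal(g$W, t(g$W))
  expect_equal(diag(g$W), rep(0, 3))
  Xbad <- X
  Xbad[3, ] <- 7
  expect_error(correlation_graph(Xbad), "node 3")
})

test_that("frequency graph weights are max-normalized inverse CF differences", {
  g <- frequency_graph(toy_map(c(400, 200, 100)))
  # adjacent pair with the smallest gap carries weight 1
  expect_equal(g$W[2, 3], 1)            # |200-100| = 100 -> max raw weight
  expect_equal(g$W[1, 2], 0.5)          # |400-200| = 200
  expect_equal(g$W[1, 3], 1 / 3)        # |400-100| = 300
  expect_equal(max(g$W), 1)
  expect_error(frequency_graph(toy_map(c(300, 200, 200))), "same CF")
})

test_that("linear graph is the tonotopic path", {
  g <- linear_graph(build_tonotopic_map(100))
  expect_equal(sum(g$W[upper.tri(g$W)] > 0), 99)
  expect_equal(graph_density(g), 2 / 100)
  ig <- igraph::graph_from_adjacency_matrix(g$W, mode = "undirected",
                                            weighted = TRUE)
  for (e in c(1, 50, 99)) {
    cut <- igraph::delete_edges(ig, e)
    expect_equal(igraph::components(cut)$no, 2)   # every edge is a bridge
  }
})

test_that("density thresholding keeps the largest weights deterministically", {
  map <- build_tonotopic_map(100)
  g <- frequency_graph(map)
  gt <- threshold_to_density(g, 0.25)
  expect_equal(sum(gt$W[upper.tri(gt$W)] > 0), 1237)  # floor(0.25 * 4950)
  kept <- gt$W[gt$W > 0]
  expect_true(all(kept %in% g$W))
  expect_gte(min(kept), max(g$W[g$W > 0 & gt$W == 0]))

  full <- complete_graph(6)
  expect_equal(threshold_to_density(full, 1)$W, full$W)

  path <- linear_graph(10)
  sub <- threshold_to_density(path, 0.1)
  expect_true(all(sub$W[path$W == 0] == 0))
  expect_lt(sum(sub$W > 0), sum(path$W > 0))
  expect_error(threshold_to_density(path, 1e-6), "zero edges")
})
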