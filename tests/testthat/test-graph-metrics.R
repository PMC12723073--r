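test_that("connectivity strength is the mean off-diagonal weight", {
  W <- matrix(0.5, 4, 4); diag(W) <- 0
  expect_equal(connectivity_strength(W), 0.5)

  W3 <- matrix(0, 3, 3)
  W3[1, 2] <- W3[2, 1] <- 0.2
  W3[1, 3] <- W3[3, 1] <- 0.4
  W3[2, 3] <- W3[3, 2] <- 0.6
  expect_equal(connectivity_strength(W3), 0.4)

  set.seed(4)
  W10 <- random_weights(10)
  acc <- 0
  for (i in 1:9) for (j in (i + 1):10) acc <- acc + W10[i, j]
  expect_equal(connectivity_strength(W10), acc / 45, tolerance = 1e-12)

  expect_error(connectivity_strength(matrix(0, 1, 1)))
})

test_that("clustering coefficient follows the strength-denominator formula", {
  # complete graph of ones collapses to 1
  W1 <- matrix(1, 5, 5); diag(W1) <- 0
  expect_equal(clustering_coefficient(W1), 1)
  expect_equal(clustering_coefficient(W1, denominator = "degree"), 1)

  # 3-node triangle, w = 0.75: t_i = 0.75, s_i = 1.5 -> ClC = 2
  Wt <- matrix(0.75, 3, 3); diag(Wt) <- 0
  expect_equal(clustering_coefficient(Wt), 2.0, tolerance = 1e-12)

  # degenerate strength guard names the node
  Wd <- matrix(0.2, 3, 3); diag(Wd) <- 0
  expect_error(clustering_coefficient(Wd), class = "plvnet_degenerate")
  expect_error(clustering_coefficient(Wd), regexp = "Node 1")
  # ... while the degree form remains defined
  expect_equal(clustering_coefficient(Wd, denominator = "degree"), 0.2,
               tolerance = 1e-12)

  # random graphs match the triple-loop oracle
  set.seed(5)
  for (r in 1:10) {
    n <- sample(5:8, 1)
    W <- random_weights(n, lo = 0.3, hi = 1)
    expect_equal(clustering_coefficient(W), clc_loop_strength(W),
                 tolerance = 1e-10)
    expect_equal(clustering_coefficient(W, denominator = "degree"),
                 clc_loop_degree(W), tolerance = 1e-10)
  }
})

test_that("path length uses inverse-weight distances and true shortest paths", {
  W <- matrix(0.5, 4, 4); diag(W) <- 0
  expect_equal(characteristic_path_length(W), 2)

  # indirect two-hop route beats a weak direct edge
  W3 <- matrix(0, 3, 3)
  W3[1, 2] <- W3[2, 1] <- 1
  W3[2, 3] <- W3[3, 2] <- 1
  W3[1, 3] <- W3[3, 1] <- 0.1
  expect_equal(characteristic_path_length(W3), 4 / 3, tolerance = 1e-12)

  # random graphs match Floyd-Warshall, and igraph agrees
  set.seed(6)
  for (r in 1:10) {
    n <- sample(5:8, 1)
    W <- random_weights(n)
    expect_equal(characteristic_path_length(W), pl_floyd(W),
                 tolerance = 1e-10)
  }
  if (requireNamespace("igraph", quietly = TRUE)) {
    W <- random_weights(8)
    g <- igraph::graph_from_adjacency_matrix(1 / W * upper.tri(W),
                                             mode = "upper",
                                             weighted = TRUE, diag = FALSE)
    L <- igraph::distances(g)
    expect_equal(characteristic_path_length(W),
                 sum(L[upper.tri(L)]) * 2 / (8 * 7), tolerance = 1e-10)
  }

  # one-minus distance variant
  expect_equal(characteristic_path_length(W3 * 0 + (diag(3) == 0) * 0.5,
                                          distance = "one_minus"), 0.5)

  # zero weight disconnects a 2-node graph
  W0 <- matrix(0, 2, 2)
  expect_error(characteristic_path_length(W0),
               class = "plvnet_disconnected")
})

test_that("metrics_for bundles the triplet with its closed forms", {
  W <- matrix(1, 8, 8); diag(W) <- 0
  g <- metrics_for(W)
  expect_equal(c(g$cs, g$clc, g$pl), c(1, 1, 1))
  expect_equal(g$n_nodes, 8)

  Wu <- matrix(0.5, 8, 8); diag(Wu) <- 0
  gu <- metrics_for(Wu)
  expect_equal(gu$cs, 0.5)
  expect_equal(gu$pl, 2)
  # ClC at uniform w from direct evaluation of the strength formula:
  # t_i = (1/2) * (N-1)(N-2) * w, s_i = (N-1) w
  tu <- 0.5 * 7 * 6 * 0.5
  su <- 7 * 0.5
  expect_equal(gu$clc, 2 * tu / (su * (su - 1)), tolerance = 1e-12)

  # shrinking every weight lowers strength and lengthens paths
  g9 <- metrics_for(Wu * 0.9)
  expect_lt(g9$cs, gu$cs)
  expect_gt(g9$pl, gu$pl)
})

test_that("metrics are invariant under node relabelling", {
  set.seed(7)
  W <- random_weights(7, lo = 0.3, hi = 1)
  p <- sample(7)
  Wp <- W[p, p]
  expect_equal(connectivity_strength(W), connectivity_strength(Wp),
               tolerance = 1e-12)
  expect_equal(clustering_coefficient(W), clustering_coefficient(Wp),
               tolerance = 1e-12)
  expect_equal(characteristic_path_length(W),
               characteristic_path_length(Wp), tolerance = 1e-12)
})

test_that("raising any single weight never lengthens paths", {
  set.seed(11)
  for (r in 1:20) {
    W <- random_weights(6)
    pl0 <- characteristic_path_length(W)
    i <- sample(5, 1); j <- sample((i + 1):6, 1)
    W[i, j] <- W[j, i] <- min(1, W[i, j] * 1.5)
    expect_lte(characteristic_path_length(W), pl0 + 1e-12)
  }
})

test_that("malformed weight matrices are rejected", {
  W <- random_weights(4)
  Wa <- W; Wa[1, 2] <- Wa[1, 2] + 0.1
  expect_error(connectivity_strength(Wa), regexp = "symmetric")
  Wn <- W; Wn[1, 2] <- Wn[2, 1] <- -0.1
  expect_error(connectivity_strength(Wn), regexp = "nonnegative")
  Wd <- W; diag(Wd) <- 1
  expect_error(connectivity_strength(Wd), regexp = "diagonal")
})
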