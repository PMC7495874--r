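test_that("k = N-1 gives the complete graph", {
  X <- matrix(c(0, 1, 5), ncol = 1)
  D <- as.matrix(dist(X))
  G <- neighborhood_graph(D, X, k = 2)
  expect_equal(nrow(G$edges), 3)
  expect_equal(max(G$components), 1)
})

test_that("k-NN union symmetrisation and the epsilon rule behave as specified", {
  # line 0, 1, 2, 10 with k = 1: 1<->2, 2<->3 mutual-ish picks, and node 4
  # selects node 3, so the union rule links them too
  X <- matrix(c(0, 1, 2, 10), ncol = 1)
  D <- as.matrix(dist(X))
  G <- neighborhood_graph(D, X, k = 1)
  expect_edge_sets_equal(G$edges, data.frame(i = c(1, 2, 3), j = c(2, 3, 4)))
  expect_equal(max(G$components), 1)

  # nearest-neighbour tie of the middle point broken to the smaller index
  Xt <- matrix(c(0, 1, 2), ncol = 1)
  Gt <- neighborhood_graph(as.matrix(dist(Xt)), Xt, k = 1)
  expect_edge_sets_equal(Gt$edges, data.frame(i = c(1, 2), j = c(2, 3)))

  # two separated pairs with k = 1 stay disconnected...
  X2 <- matrix(c(0, 1, 10, 11), ncol = 1)
  D2 <- as.matrix(dist(X2))
  G2 <- neighborhood_graph(D2, X2, k = 1)
  expect_equal(max(G2$components), 2)
  # ...until the epsilon rule bridges the 9-unit gap
  G2e <- neighborhood_graph(D2, X2, k = 1, epsilon = 9.5)
  expect_equal(max(G2e$components), 1)
  expect_true(any(G2e$edges$i == 2 & G2e$edges$j == 3))
  # edge weights are always dissimilarities, never Euclidean distances
  expect_equal(G2e$W[2, 3], D2[2, 3])
})

test_that("k out of range is rejected", {
  D <- as.matrix(dist(matrix(1:4, ncol = 1)))
  expect_error(neighborhood_graph(D, k = 0), "k must be")
  expect_error(neighborhood_graph(D, k = 4), "k must be")
})

test_that("repair_connectivity adds minimal bridging edges and is idempotent", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  D <- as.matrix(dist(X))
  G <- neighborhood_graph(D, X, k = 1)
  expect_warning(Gr <- repair_connectivity(G, D), "1 bridging edge")
  expect_equal(max(Gr$components), 1)
  # the one added edge is the min-dissimilarity cross pair (2,3)
  expect_equal(nrow(Gr$edges), nrow(G$edges) + 1)
  expect_true(any(Gr$edges$i == 2 & Gr$edges$j == 3))
  # idempotent on a connected graph, no warning
  expect_warning(Gr2 <- repair_connectivity(Gr, D), regexp = NA)
  expect_identical(Gr$W, Gr2$W)

  # three singletons at mutual distances 1, 2, 3: repair builds the MST
  W <- matrix(Inf, 3, 3); diag(W) <- 0
  Gs <- manual_graph(W)
  Ds <- as.matrix(dist(matrix(c(0, 1, 3), ncol = 1)))
  expect_warning(Gsr <- repair_connectivity(Gs, Ds), "2 bridging edge")
  expect_equal(sum(Gsr$edges$w), 3)  # 1 + 2, the minimum spanning total
  # never removes edges, reduces component count per edge
  expect_equal(nrow(Gsr$edges), 2)
})

test_that("geodesics match hand-enumerable cases", {
  # triangle with weights 1, 1, 3: the two-hop route beats the direct edge
  W <- matrix(c(0, 1, 3,
                1, 0, 1,
                3, 1, 0), 3, 3)
  DG <- geodesic_distances(manual_graph(W))
  expect_equal(DG[1, 3], 2)
  expect_equal(DG[1, 2], 1)

  # a single edge is its own geodesic
  W1 <- matrix(c(0, 7, 7, 0), 2, 2)
  expect_equal(geodesic_distances(manual_graph(W1))[1, 2], 7)

  # disconnected input is rejected
  W2 <- matrix(Inf, 3, 3); diag(W2) <- 0; W2[1, 2] <- W2[2, 1] <- 1
  expect_error(geodesic_distances(manual_graph(W2)), "disconnected")
})

test_that("geodesics equal the exhaustive-path oracle on random graphs", {
  for (seed in 1:25) {
    n <- sample(3:8, 1)
    W <- random_connected_graph(n, seed)
    DG <- geodesic_distances(manual_graph(W))
    expect_identical(DG, oracle_shortest_paths(W))
    # triangle inequality and edge-dominance invariants
    for (l in seq_len(n))
      expect_true(all(DG <= outer(DG[, l], DG[l, ], `+`) + 1e-12))
    expect_true(all(DG[is.finite(W)] <= W[is.finite(W)]))
  }
})
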