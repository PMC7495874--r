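# Independent oracles, deliberately naive: these re-derive expected
# values by brute force and must never share code with the package.

# all-pairs shortest paths by exhaustive enumeration of simple paths
oracle_shortest_paths <- function(W) {
  n <- nrow(W)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  walk <- function(path, cost) {
    i <- path[1]; v <- path[length(path)]
    if (cost < best[i, v]) best[i, v] <<- cost
    for (u in seq_len(n)) {
      if (is.finite(W[v, u]) && u != v && !(u %in% path))
        walk(c(path, u), cost + W[v, u])
    }
  }
  for (s in seq_len(n)) walk(s, 0)
  best
}

# random connected undirected graph with integer weights (so path sums
# are exact in floating point and equality can be tested exactly)
random_connected_graph <- function(n, seed) {
  set.seed(seed)
  repeat {
    W <- matrix(Inf, n, n)
    diag(W) <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.45) W[i, j] <- W[j, i] <- sample(1:10, 1)
    }
    # connectivity by reachability of node 1
    reach <- c(TRUE, rep(FALSE, n - 1))
    repeat {
      new <- reach
      for (v in which(reach)) new <- new | is.finite(W[v, ])
      if (identical(new, reach)) break
      reach <- new
    }
    if (all(reach)) return(W)
  }
}

# literal transcription of the metric formulas, kept separate from the
# package implementation on purpose
oracle_metrics <- function(TP, FP, TN, FN) {
  list(SEN = TP / (TP + FN),
       SPE = TN / (TN + FP),
       PRE = TP / (TP + FP),
       F1 = 2 * (TP / (TP + FN)) * (TP / (TP + FP)) /
         ((TP / (TP + FN)) + (TP / (TP + FP))),
       ACC = (TP + TN) / (TP + TN + FP + FN),
       MCC = (TP * TN - FP * FN) /
         sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)))
}

# AUC by exhaustive positive-negative pair counting (ties = 1/2)
oracle_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# build an nbr_graph by hand from a weight matrix (for repair tests)
manual_graph <- function(W) {
  structure(list(W = W,
                 edges = pdhotspot:::edge_list(W),
                 components = pdhotspot:::components_of(W),
                 k = 1L, epsilon = 0),
            class = "nbr_graph")
}

# small labelled Gaussian fixture used across tests
gaussian_fixture <- function(n_per = 20, dim = 10, separation = 6, seed = 11) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * dim), n_per, dim),
             matrix(rnorm(n_per * dim, mean = separation / sqrt(dim)),
                    n_per, dim))
  feature_table(X, y = rep(c(1L, 0L), each = n_per))
}

expect_edge_sets_equal <- function(a, b) {
  key <- function(e) paste(pmin(e$i, e$j), pmax(e$i, e$j), sep = "-")
  expect_setequal(key(a), key(b))
}
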