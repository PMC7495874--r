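#' Build the neighbourhood graph
#'
#' Undirected weighted graph over the samples: an edge (i, j) exists iff
#' j is among the k nearest neighbours of i by dissimilarity, or i among
#' the k nearest of j (symmetric union), or — when `epsilon > 0` — the
#' raw Euclidean distance d(x_i, x_j) is below `epsilon`. Edge weights
#' are always the dissimilarity `D[i, j]`. Nearest-neighbour ties are
#' broken towards the smaller sample index.
#'
#' @param D symmetric dissimilarity matrix (from [pairwise_dissimilarity]
#'   or plain Euclidean distances).
#' @param X feature matrix; required when `epsilon > 0` (the epsilon rule
#'   is defined on Euclidean distance, not on `D`).
#' @param k neighbour count, 1 <= k <= N - 1.
#' @param epsilon Euclidean cutoff for the auxiliary epsilon rule;
#'   0 (default) disables it.
#' @return An object of class `nbr_graph`: list with `W` (N x N weight
#'   matrix, `Inf` where no edge, 0 diagonal), `edges` (data frame
#'   i < j, w), `components` (integer membership vector), `k`, `epsilon`.
#' @export
neighborhood_graph <- function(D, X = NULL, k, epsilon = 0) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (k < 1 || k > n - 1) stop("k must be in [1, N-1]")
  if (epsilon < 0) stop("epsilon must be >= 0")
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(D[i, -i])           # stable: ties to smaller index
    nb <- (seq_len(n)[-i])[ord[seq_len(k)]]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)                # symmetric union
  if (epsilon > 0) {
    if (is.null(X)) stop("X is required when epsilon > 0")
    de <- as.matrix(stats::dist(X))
    adj <- adj | (de < epsilon)
  }
  diag(adj) <- FALSE
  W <- matrix(Inf, n, n)
  W[adj] <- D[adj]
  diag(W) <- 0
  structure(list(W = W, edges = edge_list(W), components = components_of(W),
                 k = k, epsilon = epsilon),
            class = "nbr_graph")
}

edge_list <- function(W) {
  idx <- which(is.finite(W) & upper.tri(W), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], w = W[idx])
}

# connected components by BFS over the finite entries of W
components_of <- function(W) {
  n <- nrow(W)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(is.finite(W[v, ]) & comp == 0L)
      nb <- setdiff(nb, v)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' @export
print.nbr_graph <- function(x, ...) {
  cat("nbr_graph:", nrow(x$W), "nodes,", nrow(x$edges), "edges,",
      max(x$components), "component(s); k =", x$k, "epsilon =", x$epsilon, "\n")
  invisible(x)
}

#' Repair a disconnected neighbourhood graph
#'
#' Geodesics require a connected graph. While more than one component
#' remains, the single minimum-dissimilarity edge between two distinct
#' components is added (ties towards smaller indices). A warning reports
#' how many edges were added; connected graphs pass through unchanged.
#'
#' @param G an `nbr_graph`.
#' @param D the full dissimilarity matrix used to pick bridging edges.
#' @return A connected `nbr_graph`.
#' @export
repair_connectivity <- function(G, D) {
  D <- as.matrix(D)
  W <- G$W
  comp <- components_of(W)
  added <- 0L
  while (max(comp) > 1L) {
    cross <- outer(comp, comp, `!=`) & upper.tri(D)
    cand <- which(cross, arr.ind = TRUE)
    best <- cand[order(D[cand], cand[, 1], cand[, 2])[1], , drop = TRUE]
    W[best[1], best[2]] <- W[best[2], best[1]] <- D[best[1], best[2]]
    added <- added + 1L
    comp <- components_of(W)
  }
  if (added > 0L)
    warning("neighbourhood graph was disconnected; added ", added,
            " bridging edge(s)")
  structure(list(W = W, edges = edge_list(W), components = comp,
                 k = G$k, epsilon = G$epsilon),
            class = "nbr_graph")
}

#' All-pairs geodesic distances
#'
#' Exact shortest-path distances over the neighbourhood graph, by
#' Floyd-Warshall on the dense weight matrix (compiled). The graph must
#' be connected; run [repair_connectivity] first if it is not.
#'
#' @param G a connected `nbr_graph`.
#' @return A symmetric N x N matrix of finite geodesic distances.
#' @export
geodesic_distances <- function(G) {
  if (max(G$components) > 1L)
    stop("graph is disconnected; run repair_connectivity() first")
  .floyd_warshall(G$W)
}
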