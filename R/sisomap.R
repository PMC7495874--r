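#' S-ISOMAP parameters
#'
#' Bundles the tunable parameters of the supervised embedding. Defaults
#' follow common S-ISOMAP practice: `alpha = 0.5` offsets between-class
#' dissimilarities, `beta = "auto"` resolves to the mean squared pairwise
#' Euclidean distance of the fitting data (keeping exponents O(1)),
#' `k = 7` nearest neighbours with the epsilon rule disabled, and a
#' 3-dimensional target embedding (the dimension used by the hot-spot
#' model).
#'
#' @param k neighbour count (positive integer).
#' @param epsilon Euclidean cutoff of the auxiliary epsilon rule; 0 disables.
#' @param alpha between-class offset, `alpha <= 1`.
#' @param beta positive scale for d^2, or `"auto"`.
#' @param d target embedding dimension.
#' @param standardize z-score features on the training data (and apply
#'   the training transform at test time). Off by default.
#' @return A list of class `sisomap_params`.
#' @export
sisomap_params <- function(k = 7, epsilon = 0, alpha = 0.5, beta = "auto",
                           d = 3, standardize = FALSE) {
  stopifnot(k >= 1, epsilon >= 0, d >= 1)
  if (alpha > 1) stop("alpha must be <= 1")
  if (!identical(beta, "auto") && (!is.numeric(beta) || beta <= 0))
    stop("beta must be positive or \"auto\"")
  structure(list(k = as.integer(k), epsilon = epsilon, alpha = alpha,
                 beta = beta, d = as.integer(d),
                 standardize = isTRUE(standardize)),
            class = "sisomap_params")
}

# shared fitting core; `D` already holds the pairwise weights
fit_embedding <- function(X, D, params, supervised, ids) {
  n <- nrow(X)
  if (params$d > n - 1) stop("d must be < N")
  if (params$k > n - 1) stop("k must be <= N - 1")
  G <- neighborhood_graph(D, X = X, k = params$k, epsilon = params$epsilon)
  G <- repair_connectivity(G, D)
  DG <- geodesic_distances(G)
  mds <- classical_mds(DG, params$d)
  structure(list(Y = mds$Y, eigenvalues = mds$eigenvalues,
                 eigenvectors = mds$eigenvectors,
                 row_means = mds$row_means, grand_mean = mds$grand_mean,
                 params = params, supervised = supervised,
                 train_X = X, train_DG = DG, graph = G, ids = ids),
            class = "sisomap")
}

#' Fit a supervised isometric feature mapping
#'
#' The full S-ISOMAP pipeline: label-aware pairwise dissimilarity
#' ([pairwise_dissimilarity]) -> k-nearest-neighbour graph
#' ([neighborhood_graph], connectivity repaired if needed) -> all-pairs
#' geodesics ([geodesic_distances]) -> classical MDS ([classical_mds]).
#' Deterministic given its inputs. Within-class distances are compressed
#' and between-class distances inflated, so classes separate in the
#' embedding.
#'
#' @param table a [feature_table] with labels present.
#' @param params a [sisomap_params].
#' @return Object of class `sisomap`, holding the coordinates `Y`
#'   (N x d), the retained spectral data, the centring statistics, the
#'   resolved parameters, and references to the training data needed by
#'   [predict.sisomap].
#' @seealso [isomap_fit] for the unsupervised special case.
#' @export
sisomap_fit <- function(table, params = sisomap_params()) {
  if (!inherits(table, "feature_table")) stop("table must be a feature_table")
  if (is.null(table$y)) stop("sisomap_fit needs labels; use isomap_fit otherwise")
  X <- table$X
  if (nrow(X) < 2) stop("need at least 2 samples")
  if (params$standardize) {
    ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    X <- scale(X, ctr, scl)
    attr(X, "scaled:center") <- NULL; attr(X, "scaled:scale") <- NULL
    std <- list(center = ctr, scale = scl)
  } else std <- NULL
  beta <- if (identical(params$beta, "auto")) resolve_beta(X) else params$beta
  params$beta <- beta
  D <- pairwise_dissimilarity(X, table$y, alpha = params$alpha, beta = beta)
  fit <- fit_embedding(X, D, params, supervised = TRUE, ids = table$ids)
  fit$standardizer <- std
  fit$train_y <- table$y
  fit
}

#' Fit an unsupervised ISOMAP embedding
#'
#' The label-free special case: raw Euclidean distances serve as edge
#' weights, otherwise the pipeline (neighbourhood graph, geodesics,
#' classical MDS) is identical to [sisomap_fit].
#'
#' @param table a [feature_table] (labels, if any, are ignored).
#' @param k neighbour count.
#' @param epsilon Euclidean cutoff; 0 disables.
#' @param d target dimension.
#' @return A `sisomap` object with `supervised = FALSE`.
#' @export
isomap_fit <- function(table, k = 7, epsilon = 0, d = 2) {
  if (!inherits(table, "feature_table")) stop("table must be a feature_table")
  X <- table$X
  if (nrow(X) < 2) stop("need at least 2 samples")
  params <- sisomap_params(k = k, epsilon = epsilon, d = d)
  params$beta <- NA_real_  # unused in the Euclidean special case
  D <- as.matrix(stats::dist(X))
  fit_embedding(X, D, params, supervised = FALSE, ids = table$ids)
}

#' @export
print.sisomap <- function(x, ...) {
  cat(if (x$supervised) "S-ISOMAP" else "ISOMAP", "embedding:",
      nrow(x$Y), "samples ->", ncol(x$Y), "dims; k =", x$params$k)
  if (x$supervised)
    cat(", alpha =", x$params$alpha,
        ", beta =", formatC(x$params$beta, digits = 4))
  cat("\n  eigenvalues:", paste(formatC(x$eigenvalues, digits = 4),
                                collapse = " "), "\n")
  invisible(x)
}

# dissimilarity of new points to the training points, in the metric the
# model was fitted with (label-free branch for supervised models, since
# test labels are unknown; plain Euclidean for ISOMAP models).
# Returns both the dissimilarity and the squared Euclidean distances
# (the latter for coincidence detection).
new_point_dissimilarity <- function(model, X_new) {
  d2 <- outer(rowSums(X_new^2), rowSums(model$train_X^2), `+`) -
    2 * X_new %*% t(model$train_X)
  d2 <- pmax(d2, 0)
  W <- if (model$supervised) sqrt(pmax(1 - exp(-d2 / model$params$beta), 0))
       else sqrt(d2)
  list(W = W, d2 = d2)
}

#' Map new points into a fitted embedding (Nystrom extension)
#'
#' Out-of-sample extension: each new point is linked to its `k` nearest
#' training points by label-free dissimilarity, its geodesic distance to
#' every training point is taken as the minimum over those entry points
#' of (entry weight + training geodesic), and the coordinates follow
#' from the Nystrom projection
#' \deqn{y_a = \frac{1}{2\sqrt{\lambda_a}} \sum_i u_a[i]\,(\mu_i - s[i])}
#' where \eqn{\mu_i} are the stored row means of the squared training
#' geodesics and \eqn{s} the new point's squared geodesics. A new point
#' that coincides with a training point (dissimilarity 0) inherits that
#' node's geodesic column, so training rows map back onto their fitted
#' coordinates.
#'
#' @param object a fitted `sisomap`.
#' @param newdata matrix (or [feature_table]) with the training feature
#'   columns; may have zero rows.
#' @param ... unused.
#' @return M x d coordinate matrix.
#' @export
predict.sisomap <- function(object, newdata, ...) {
  X_new <- if (inherits(newdata, "feature_table")) newdata$X else as.matrix(newdata)
  if (ncol(X_new) != ncol(object$train_X))
    stop("newdata has ", ncol(X_new), " columns; model was fitted with ",
         ncol(object$train_X))
  d <- ncol(object$Y)
  if (nrow(X_new) == 0)
    return(matrix(0, 0, d, dimnames = list(NULL, colnames(object$Y))))
  if (!is.null(object$standardizer))
    X_new <- scale(X_new, object$standardizer$center, object$standardizer$scale)
  nd <- new_point_dissimilarity(object, X_new)
  W <- nd$W
  n <- nrow(object$train_X)
  k <- min(object$params$k, n)
  DG <- object$train_DG
  # coincidence tolerance on squared distance, scaled to the data (the
  # expansion-based distance computation leaves O(eps * |x|^2) residue)
  co_tol <- 1e-9 * (1 + mean(rowSums(object$train_X^2)))
  S_new <- matrix(0, nrow(X_new), n)
  for (m in seq_len(nrow(X_new))) {
    w <- W[m, ]
    if (min(nd$d2[m, ]) < co_tol) {  # coincides with a training point
      geo <- DG[which.min(nd$d2[m, ]), ]
    } else {
      nb <- order(w)[seq_len(k)]   # stable ties -> smaller index
      geo <- apply(DG[nb, , drop = FALSE] + w[nb], 2, min)
    }
    S_new[m, ] <- geo^2
  }
  centered <- sweep(-S_new, 2, -object$row_means)   # mu_i - s[i]
  Y_new <- 0.5 * centered %*%
    sweep(object$eigenvectors, 2, sqrt(object$eigenvalues), `/`)
  colnames(Y_new) <- colnames(object$Y)
  Y_new
}

#' @rdname predict.sisomap
#' @param model a fitted `sisomap`.
#' @param X_new matrix of new points.
#' @export
sisomap_transform <- function(model, X_new) predict(model, X_new)

#' Transductive S-ISOMAP over a train/test pair
#'
#' Alternative to the inductive [predict.sisomap]: refits the embedding
#' on the concatenation of training and test rows, using the supervised
#' dissimilarity among training pairs and the label-free branch for any
#' pair involving a test row (test labels are never consulted). Returns
#' the joint embedding split back into train and test coordinates.
#'
#' @param train labelled [feature_table].
#' @param test [feature_table] (labels ignored).
#' @param params a [sisomap_params].
#' @return list with `Y_train`, `Y_test`, and the underlying `fit`.
#' @export
sisomap_fit_transductive <- function(train, test, params = sisomap_params()) {
  if (is.null(train$y)) stop("train table needs labels")
  if (ncol(test$X) != ncol(train$X)) stop("feature columns differ")
  X <- rbind(train$X, test$X)
  n_tr <- nrow(train$X)
  beta <- if (identical(params$beta, "auto")) resolve_beta(X) else params$beta
  params$beta <- beta
  # supervised branch among train pairs only; label-free elsewhere
  D <- pairwise_dissimilarity(X, y = NULL, alpha = params$alpha, beta = beta)
  D_tr <- pairwise_dissimilarity(train$X, train$y, alpha = params$alpha,
                                 beta = beta)
  D[seq_len(n_tr), seq_len(n_tr)] <- D_tr
  ids <- make.unique(c(train$ids, test$ids))
  fit <- fit_embedding(X, D, params, supervised = TRUE, ids = ids)
  list(Y_train = fit$Y[seq_len(n_tr), , drop = FALSE],
       Y_test = fit$Y[-seq_len(n_tr), , drop = FALSE],
       fit = fit)
}
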