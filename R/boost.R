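#' Gradient-boosted tree parameters
#'
#' Defaults are the tuned values of the hot-spot model: 500 trees,
#' learning rate 0.1, maximum depth 30. The ensemble itself uses no
#' row/column subsampling, so `seed` only documents the run; fitting is
#' deterministic regardless.
#'
#' @param n_trees number of boosting rounds (positive integer).
#' @param learning_rate shrinkage applied to each tree (positive).
#' @param max_depth maximum tree depth (positive integer).
#' @param seed integer recorded with the model.
#' @return A list of class `gbt_params`.
#' @export
gbt_params <- function(n_trees = 500, learning_rate = 0.1, max_depth = 30,
                       seed = 1L) {
  stopifnot(n_trees >= 1, learning_rate > 0, max_depth >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 seed = as.integer(seed)),
            class = "gbt_params")
}

#' Fit a gradient-boosted decision-tree classifier
#'
#' Second-order boosting on the logistic loss: each round fits a
#' regression tree to the gradient/hessian of the current margin by
#' exact greedy split search (gain with L2 leaf penalty lambda = 1,
#' minimum child hessian 1), and adds the shrunken Newton-step leaf
#' weights to the ensemble. Prediction is the logistic transform of the
#' accumulated raw score. Fitting is fully deterministic: refitting on
#' the same data reproduces the ensemble bit for bit.
#'
#' @param coords numeric matrix of predictors (embedded coordinates).
#' @param y 0/1 labels; both classes must be present.
#' @param params a [gbt_params].
#' @return Object of class `gbt` with the flattened trees, the base raw
#'   score, the parameters, and `feature_dim`.
#' @export
gbt_fit <- function(coords, y, params = gbt_params()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != length(y)) stop("nrow(coords) must equal length(y)")
  if (any(!is.finite(coords))) stop("non-finite values in coords")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(y)) < 2) stop("both classes must be present to fit")
  fit <- .gbt_fit_cpp(coords, as.numeric(y), params$n_trees,
                      params$learning_rate, params$max_depth,
                      lambda = 1.0, min_child_weight = 1.0, base_score = 0.5)
  structure(list(trees = fit$trees, base_raw = fit$base_raw,
                 params = params, feature_dim = ncol(coords)),
            class = "gbt")
}

#' Predict hot-spot probabilities from a boosted ensemble
#'
#' @param object a fitted `gbt`.
#' @param newdata matrix with `feature_dim` columns; may have zero rows.
#' @param type `"prob"` for P(hot spot), `"class"` for 0/1 labels at
#'   `threshold`.
#' @param threshold decision threshold on the probability (default 0.5).
#' @param ... unused.
#' @return Numeric vector of probabilities in [0, 1], or integer labels.
#' @export
predict.gbt <- function(object, newdata, type = c("prob", "class"),
                        threshold = 0.5, ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0) {
    return(if (type == "prob") numeric(0) else integer(0))
  }
  if (ncol(newdata) != object$feature_dim)
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         object$feature_dim)
  storage.mode(newdata) <- "double"
  p <- .gbt_predict_cpp(object$trees, object$base_raw, newdata)
  if (type == "prob") p else as.integer(p >= threshold)
}

#' @export
print.gbt <- function(x, ...) {
  cat("gbt: ", length(x$trees), " trees, lr = ", x$params$learning_rate,
      ", max_depth = ", x$params$max_depth, ", ", x$feature_dim,
      " feature(s)\n", sep = "")
  invisible(x)
}

#' Grid search over boosting hyperparameters
#'
#' Exhaustive evaluation of a parameter grid by stratified k-fold
#' cross-validated mean AUC. Ties are broken towards fewer trees, then
#' shallower depth, then grid order; the search is deterministic given
#' `seed`.
#'
#' @param coords predictor matrix.
#' @param y 0/1 labels, both classes present.
#' @param grid data frame with columns `n_trees`, `learning_rate`,
#'   `max_depth` (one row per candidate).
#' @param folds number of CV folds (>= 2).
#' @param seed fold-assignment seed.
#' @return The winning [gbt_params]; the evaluated grid (with a
#'   `mean_auc` column) is attached as attribute `"grid"`.
#' @export
gbt_tune <- function(coords, y, grid, folds = 10, seed = 1L) {
  if (nrow(grid) < 1) stop("grid must be non-empty")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (folds < 2) stop("folds must be >= 2")
  coords <- as.matrix(coords)
  fold_id <- stratified_folds(y, folds, seed)
  aucs <- vapply(seq_len(nrow(grid)), function(g) {
    p <- gbt_params(grid$n_trees[g], grid$learning_rate[g], grid$max_depth[g],
                    seed = seed)
    fold_auc <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      m <- gbt_fit(coords[tr, , drop = FALSE], y[tr], p)
      s <- predict(m, coords[!tr, , drop = FALSE])
      if (length(unique(y[!tr])) < 2) return(NA_real_)
      roc_auc(y[!tr], s)
    }, numeric(1))
    mean(fold_auc, na.rm = TRUE)
  }, numeric(1))
  ord <- order(-aucs, grid$n_trees, grid$max_depth)
  best <- ord[1]
  out <- gbt_params(grid$n_trees[best], grid$learning_rate[best],
                    grid$max_depth[best], seed = seed)
  attr(out, "grid") <- cbind(grid, mean_auc = aucs)
  out
}
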