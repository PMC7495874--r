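#' Cross-validation configuration
#'
#' Defaults mirror the hot-spot model's protocol: stratified 10-fold
#' cross-validation repeated 20 times, repeat r using seed
#' `base_seed + r - 1` for its fold assignment.
#'
#' @param folds number of folds (>= 2).
#' @param repeats number of repetitions (>= 1).
#' @param base_seed integer seed of the first repeat.
#' @param stratified preserve the class ratio within folds (default TRUE).
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(folds = 10, repeats = 20, base_seed = 1L,
                      stratified = TRUE) {
  stopifnot(folds >= 2, repeats >= 1)
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 base_seed = as.integer(base_seed),
                 stratified = isTRUE(stratified)),
            class = "cv_config")
}

#' Deterministic (stratified) fold assignment
#'
#' Within each class, sample order is shuffled under `seed` and dealt
#' round-robin into folds, so fold class ratios match the overall ratio
#' as closely as integer counts allow. Unstratified assignment shuffles
#' all samples together.
#'
#' @param y 0/1 labels.
#' @param folds number of folds.
#' @param seed shuffle seed.
#' @param stratified stratify by class (default TRUE).
#' @return Integer vector of fold ids in `1:folds`.
#' @export
stratified_folds <- function(y, folds, seed, stratified = TRUE) {
  n <- length(y)
  if (folds > n) stop("more folds than samples")
  fold_id <- integer(n)
  with_local_seed(seed, {
    if (stratified) {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        if (length(idx) < folds)
          stop("stratification infeasible: class ", cls, " has ",
               length(idx), " samples for ", folds, " folds")
        idx <- idx[sample.int(length(idx))]
        fold_id[idx] <- rep_len(seq_len(folds), length(idx))
      }
    } else {
      idx <- sample.int(n)
      fold_id[idx] <- rep_len(seq_len(folds), n)
    }
  })
  fold_id
}

# one leakage-safe fold: embed on the training portion only, map the
# held-out portion through the out-of-sample extension, classify
fold_predictions <- function(table, tr, sparams, bparams) {
  emb <- sisomap_fit(table[tr], sparams)
  clf <- gbt_fit(emb$Y, table$y[tr], bparams)
  Y_te <- predict(emb, table$X[!tr, , drop = FALSE])
  predict(clf, Y_te)
}

#' Repeated stratified cross-validation of the full pipeline
#'
#' Within every fold the S-ISOMAP embedding is fitted on the training
#' portion only and held-out samples are mapped in through the Nystrom
#' extension, so no information leaks from the evaluation fold. Per
#' repeat, fold predictions are pooled and one metrics bundle computed;
#' repeats are then averaged (with standard deviations). Fully
#' reproducible from `cv$base_seed`.
#'
#' @param table labelled [feature_table].
#' @param sparams a [sisomap_params].
#' @param bparams a [gbt_params].
#' @param cv a [cv_config].
#' @param threshold probability decision threshold (default 0.5).
#' @return Object of class `cv_result`: list with `mean` and `sd`
#'   (named numeric over SEN/SPE/PRE/F1/ACC/MCC/AUC), `per_repeat`
#'   (data frame, one row per repeat), and `config`.
#' @export
cross_validate <- function(table, sparams = sisomap_params(),
                           bparams = gbt_params(), cv = cv_config(),
                           threshold = 0.5) {
  if (is.null(table$y)) stop("cross_validate needs labels")
  if (length(unique(table$y)) < 2) stop("both classes must be present")
  metric_names <- c("SEN", "SPE", "PRE", "F1", "ACC", "MCC", "AUC")
  per_repeat <- matrix(NA_real_, cv$repeats, length(metric_names),
                       dimnames = list(NULL, metric_names))
  n <- nrow(table$X)
  for (r in seq_len(cv$repeats)) {
    seed_r <- cv$base_seed + r - 1L
    fold_id <- stratified_folds(table$y, cv$folds, seed_r, cv$stratified)
    scores <- numeric(n)
    for (f in seq_len(cv$folds)) {
      tr <- fold_id != f
      scores[!tr] <- fold_predictions(table, tr, sparams, bparams)
    }
    rep_metrics <- metrics_from_scores(table$y, scores, threshold)
    per_repeat[r, ] <- unlist(rep_metrics[metric_names])
  }
  per_repeat <- as.data.frame(per_repeat)
  structure(list(mean = colMeans(per_repeat),
                 sd = vapply(per_repeat, stats::sd, numeric(1)),
                 per_repeat = cbind(repeat_ = seq_len(cv$repeats), per_repeat),
                 config = cv),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, digits = 3, ...) {
  cat("cross-validation:", x$config$folds, "folds x", x$config$repeats,
      "repeat(s), base_seed =", x$config$base_seed, "\n")
  m <- formatC(x$mean, digits = digits, format = "f")
  s <- formatC(x$sd, digits = digits, format = "f")
  cat(paste(sprintf("%s = %s (sd %s)", names(x$mean), m, s),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Train/test evaluation of the full pipeline
#'
#' Fits S-ISOMAP and the boosted classifier on the training table, maps
#' the test table through the out-of-sample extension (or, with
#' `transductive = TRUE`, re-embeds train + test jointly with label-free
#' distances for test rows), and reports the seven metrics on the test
#' labels. With a single-class test set the AUC is omitted with a
#' warning; the count-based metrics are still reported.
#'
#' @param train labelled [feature_table].
#' @param test labelled [feature_table] with matching feature columns.
#' @param sparams a [sisomap_params].
#' @param bparams a [gbt_params].
#' @param threshold probability decision threshold (default 0.5).
#' @param transductive use the joint re-embedding instead of the
#'   inductive Nystrom mapping (default FALSE).
#' @return A `metrics_report`, with the test scores attached as
#'   attribute `"scores"`.
#' @export
evaluate_holdout <- function(train, test, sparams = sisomap_params(),
                             bparams = gbt_params(), threshold = 0.5,
                             transductive = FALSE) {
  if (is.null(train$y) || is.null(test$y)) stop("both tables need labels")
  if (ncol(test$X) != ncol(train$X)) stop("feature columns differ")
  if (transductive) {
    td <- sisomap_fit_transductive(train, test, sparams)
    clf <- gbt_fit(td$Y_train, train$y, bparams)
    scores <- predict(clf, td$Y_test)
  } else {
    emb <- sisomap_fit(train, sparams)
    clf <- gbt_fit(emb$Y, train$y, bparams)
    scores <- predict(clf, predict(emb, test$X))
  }
  rep <- metrics_from_scores(test$y, scores, threshold)
  attr(rep, "scores") <- scores
  rep
}
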