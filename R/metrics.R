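#' Confusion counts from binary predictions
#'
#' Positive class = hot spot = 1. Empty inputs give all-zero counts.
#'
#' @param y_true 0/1 vector of reference labels.
#' @param y_pred 0/1 vector of predicted labels, same length.
#' @return Object of class `confusion_counts`: list TP, FP, TN, FN.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop("labels must be 0/1")
  structure(list(TP = sum(y_true == 1 & y_pred == 1),
                 FP = sum(y_true == 0 & y_pred == 1),
                 TN = sum(y_true == 0 & y_pred == 0),
                 FN = sum(y_true == 1 & y_pred == 0)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' The standard binary bundle:
#' SEN = TP/(TP+FN), SPE = TN/(TN+FP), PRE = TP/(TP+FP),
#' F1 = 2*SEN*PRE/(SEN+PRE), ACC = (TP+TN)/total,
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' Any zero denominator yields 0 for that metric, with a warning; this
#' keeps aggregation over folds total.
#'
#' @param counts a [confusion_counts].
#' @return Object of class `metrics_report`: list with SEN, SPE, PRE,
#'   F1, ACC, MCC, `AUC` (NA here; see [roc_auc]) and `counts`.
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total == 0) stop("no evaluated samples")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; returning 0")
      return(0)
    }
    num / den
  }
  SEN <- safe_div(TP, TP + FN, "SEN")
  SPE <- safe_div(TN, TN + FP, "SPE")
  PRE <- safe_div(TP, TP + FP, "PRE")
  F1 <- if (SEN + PRE == 0) {
    warning("zero denominator for F1; returning 0"); 0
  } else 2 * SEN * PRE / (SEN + PRE)
  ACC <- (TP + TN) / total
  mcc_den2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  MCC <- if (mcc_den2 == 0) {
    warning("zero denominator for MCC; returning 0"); 0
  } else (TP * TN - FP * FN) / sqrt(mcc_den2)
  structure(list(SEN = SEN, SPE = SPE, PRE = PRE, F1 = F1, ACC = ACC,
                 MCC = MCC, AUC = NA_real_, counts = counts),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  v <- unlist(x[c("SEN", "SPE", "PRE", "F1", "ACC", "MCC", "AUC")])
  cat(paste(sprintf("%s = %s", names(v),
                    ifelse(is.na(v), "-", formatC(v, digits = digits,
                                                  format = "f"))),
            collapse = "  "), "\n")
  c <- x$counts
  cat(sprintf("TP = %d  FP = %d  TN = %d  FN = %d\n", c$TP, c$FP, c$TN, c$FN))
  invisible(x)
}

#' ROC coordinates for a score vector
#'
#' One ROC vertex per distinct score value (ties grouped), anchored at
#' (0, 0) and (1, 1), thresholds descending.
#'
#' @param y_true 0/1 labels, both classes present.
#' @param scores numeric scores, higher = more hot-spot-like.
#' @return data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(y_true, scores) {
  if (length(y_true) != length(scores)) stop("length mismatch")
  if (length(unique(y_true)) < 2) stop("both classes must be present")
  n_pos <- sum(y_true == 1); n_neg <- sum(y_true == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- cumsum(vapply(thr, function(t) sum(y_true == 1 & scores == t),
                      numeric(1)))
  fp <- cumsum(vapply(thr, function(t) sum(y_true == 0 & scores == t),
                      numeric(1)))
  data.frame(threshold = c(Inf, thr),
             fpr = c(0, fp / n_neg),
             tpr = c(0, tp / n_pos))
}

#' Area under the ROC curve
#'
#' `method = "rank"` (default) uses the Mann-Whitney formulation with
#' average ranks, so tied positive/negative scores count 1/2.
#' `method = "trapezoid"` integrates [roc_curve] by the trapezoidal
#' rule; the two agree to numerical precision by construction of the
#' tie handling.
#'
#' @param y_true 0/1 labels, both classes present.
#' @param scores numeric scores.
#' @param method `"rank"` or `"trapezoid"`.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(y_true, scores, method = c("rank", "trapezoid")) {
  method <- match.arg(method)
  if (length(y_true) != length(scores)) stop("length mismatch")
  if (length(unique(y_true)) < 2) stop("both classes must be present")
  if (method == "rank") {
    r <- rank(scores, ties.method = "average")
    n_pos <- sum(y_true == 1); n_neg <- sum(y_true == 0)
    (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  } else {
    rc <- roc_curve(y_true, scores)
    sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
  }
}

# metrics bundle from labels + scores; AUC filled when possible
metrics_from_scores <- function(y_true, scores, threshold = 0.5) {
  rep <- compute_metrics(confusion_counts(y_true, as.integer(scores >= threshold)))
  if (length(unique(y_true)) >= 2) rep$AUC <- roc_auc(y_true, scores)
  else warning("single-class reference labels; AUC not computed")
  rep
}
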