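#' Resolve the dissimilarity scale parameter beta from data
#'
#' The "auto" rule for beta: the mean of squared pairwise Euclidean
#' distances d^2(x_i, x_j) over all i < j pairs of the fitting data.
#' Keeping beta on the scale of d^2 keeps the exponents in the
#' dissimilarity O(1).
#'
#' @param X numeric matrix, N >= 2 rows.
#' @return A positive scalar.
#' @export
resolve_beta <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows to resolve beta")
  b <- mean(stats::dist(X)^2)
  if (!is.finite(b) || b <= 0)
    stop("all points are identical; beta cannot be resolved from the data")
  b
}

#' Label-aware pairwise dissimilarity
#'
#' The supervised distance underlying S-ISOMAP. With Euclidean distance
#' d = d(x_i, x_j):
#' \deqn{D_{ij} = \sqrt{1 - e^{-d^2/\beta}}}{D = sqrt(1 - exp(-d^2/beta))}
#' when the two points share a class (or labels are absent), and
#' \deqn{D_{ij} = e^{d^2/(2\beta)} - \alpha}{D = exp(d^2/(2 beta)) - alpha}
#' when classes differ. The same-class branch is bounded by 1; the
#' different-class branch grows without bound and is at least
#' `1 - alpha`, so between-class distances are inflated relative to
#' within-class ones. The different-class form is the algebraic rewrite
#' of sqrt(exp(d^2/beta)) - alpha that halves the exponent and hence the
#' overflow risk.
#'
#' With `y = NULL` the same-class branch is used for every pair: this is
#' the label-free mode used for unsupervised embedding and at test time.
#'
#' @param X numeric matrix of N >= 2 rows.
#' @param y optional 0/1 labels of length N.
#' @param alpha between-class offset, must satisfy `alpha <= 1`
#'   (at d = 0 the between-class value is 1 - alpha, which must stay
#'   non-negative). Default 0.5.
#' @param beta positive scale on d^2, or `"auto"` for [resolve_beta].
#' @return A symmetric N x N matrix with zero diagonal and attributes
#'   `supervised`, `alpha`, `beta`.
#' @export
pairwise_dissimilarity <- function(X, y = NULL, alpha = 0.5, beta = "auto") {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 rows")
  if (any(!is.finite(X))) {
    bad <- which(apply(X, 1, function(r) any(!is.finite(r))))
    stop("non-finite feature values in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  if (!is.numeric(alpha) || alpha > 1) stop("alpha must be a number <= 1")
  if (identical(beta, "auto")) beta <- resolve_beta(X)
  if (!is.numeric(beta) || beta <= 0) stop("beta must be positive or \"auto\"")
  supervised <- !is.null(y)
  if (supervised && !all(y %in% c(0, 1))) stop("labels must be 0/1")

  d2 <- as.matrix(stats::dist(X))^2
  D <- sqrt(pmax(1 - exp(-d2 / beta), 0))  # pmax keeps dim from 1st arg
  if (supervised) {
    diff_cls <- outer(y, y, `!=`)
    if (any(diff_cls)) {
      expo <- d2 / (2 * beta)
      if (max(expo[diff_cls]) > log(.Machine$double.xmax))
        stop("between-class exponent d^2/(2*beta) exceeds the floating-point ",
             "range; use a larger beta")
      D[diff_cls] <- exp(expo[diff_cls]) - alpha
    }
  }
  diag(D) <- 0
  D <- (D + t(D)) / 2  # enforce exact symmetry
  attr(D, "supervised") <- supervised
  attr(D, "alpha") <- alpha
  attr(D, "beta") <- beta
  D
}
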