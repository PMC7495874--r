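#' Classical multidimensional scaling of a distance matrix
#'
#' Embeds a distance (geodesic) matrix by the classical Torgerson
#' construction: form the squared-distance matrix S, double-centre it
#' with H = I - 11'/N into tau = -HSH/2, and take the top-d eigenpairs.
#' Coordinates are `Y[, a] = sqrt(lambda_a) * u_a`, columns ordered by
#' descending eigenvalue. Only strictly positive eigenvalues are
#' retained; if fewer than `d` are positive, `d` is reduced with a
#' warning (negative eigenvalues of tau carry no metric embedding).
#'
#' Sign convention: each eigenvector is flipped so that its
#' largest-magnitude entry is positive (ties to the first such entry),
#' making output reproducible across platforms.
#'
#' The centring statistics (row means and grand mean of S) are retained
#' for the Nystrom out-of-sample extension.
#'
#' @param DG symmetric matrix of distances (typically geodesics).
#' @param d target dimension, 1 <= d <= N - 1.
#' @return Object of class `classical_mds`: list with `Y` (N x d),
#'   `eigenvalues`, `eigenvectors`, `row_means`, `grand_mean`, `d`.
#' @export
classical_mds <- function(DG, d) {
  DG <- as.matrix(DG)
  n <- nrow(DG)
  if (d < 1) stop("d must be >= 1")
  if (d >= n) stop("d must be < N")
  S <- DG^2
  rm_ <- rowMeans(S)
  gm <- mean(S)
  tau <- -0.5 * (S - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm)
  eig <- eigen(tau, symmetric = TRUE)
  tol <- max(abs(eig$values)) * sqrt(.Machine$double.eps)
  pos <- which(eig$values > tol)
  if (length(pos) == 0) stop("no positive eigenvalues; cannot embed")
  if (length(pos) < d) {
    warning("only ", length(pos), " positive eigenvalue(s); reducing d from ",
            d, " to ", length(pos))
    d <- length(pos)
  }
  lambda <- eig$values[seq_len(d)]
  U <- eig$vectors[, seq_len(d), drop = FALSE]
  for (a in seq_len(d)) {
    top <- which.max(abs(U[, a]))
    if (U[top, a] < 0) U[, a] <- -U[, a]
  }
  Y <- sweep(U, 2, sqrt(lambda), `*`)
  colnames(Y) <- paste0("dim_", seq_len(d))
  structure(list(Y = Y, eigenvalues = lambda, eigenvectors = U,
                 row_means = rm_, grand_mean = gm, d = d),
            class = "classical_mds")
}
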