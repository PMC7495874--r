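#' Benchmark-mimicking two-class feature tables
#'
#' Seeded generator emulating the shape of the hot-spot benchmark:
#' a training table of 62 positives / 88 negatives and a test table of
#' 26 positives / 38 negatives, 114 features arranged in four correlated
#' blocks (mimicking grouped solvent-accessibility / sequence /
#' structure / network feature families; within-block equicorrelation
#' `rho`, independence across blocks). The class signal is a mean shift
#' of Euclidean length `separation` (in units of the within-class
#' standard deviation) along a random direction spread over
#' `n_informative` randomly chosen feature dimensions; all remaining
#' dimensions are pure noise. Output is byte-identical per seed and the
#' caller's RNG stream is left untouched.
#'
#' @param n_pos,n_neg training class counts (defaults 62 / 88).
#' @param n_pos_test,n_neg_test test class counts (defaults 26 / 38).
#' @param dim feature count (default 114).
#' @param separation distance between class means, in within-class SD
#'   units. Default 2: moderately overlapping classes, the regime the
#'   real benchmark lives in.
#' @param n_informative dimensions carrying the separation (default 10).
#' @param blocks number of correlated feature blocks (default 4).
#' @param rho within-block equicorrelation (default 0.6).
#' @param seed integer seed.
#' @return list with `train` and `test` [feature_table]s.
#' @export
make_benchmark_mimic <- function(n_pos = 62, n_neg = 88,
                                 n_pos_test = 26, n_neg_test = 38,
                                 dim = 114, separation = 2,
                                 n_informative = 10, blocks = 4,
                                 rho = 0.6, seed = 1L) {
  if (n_informative > dim) stop("n_informative must be <= dim")
  if (separation < 0) stop("separation must be >= 0")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  with_local_seed(seed, {
    block_of <- rep_len(seq_len(blocks), dim)   # near-equal block sizes
    inf_dims <- sample.int(dim, n_informative)
    u <- rnorm(n_informative)
    mu <- numeric(dim)
    mu[inf_dims] <- separation * u / sqrt(sum(u^2))
    draw <- function(n_p, n_n, prefix) {
      n <- n_p + n_n
      # within-block equicorrelation via a shared factor per block
      common <- matrix(rnorm(n * blocks), n, blocks)
      X <- sqrt(rho) * common[, block_of, drop = FALSE] +
        sqrt(1 - rho) * matrix(rnorm(n * dim), n, dim)
      y <- c(rep(1L, n_p), rep(0L, n_n))
      X <- X + outer(y, mu)
      colnames(X) <- paste0("f", seq_len(dim))
      feature_table(X, y, sprintf("%s_%04d", prefix, seq_len(n)))
    }
    list(train = draw(n_pos, n_neg, "train"),
         test = draw(n_pos_test, n_neg_test, "test"))
  })
}

#' Swiss-roll manifold fixture
#'
#' Standard validation surface for geodesic embeddings: points
#' (t cos t, h, t sin t) with t in [1.5 pi, 4.5 pi] and height h uniform
#' on [0, 21], plus optional isotropic Gaussian noise. Points are
#' sampled uniformly ON the manifold (uniform in arc length, not in t;
#' uniform-in-t thins the outer coil ~14-fold and lets k-NN graphs
#' short-circuit between coils). The intrinsic 2-D parameterisation
#' (arc length along the spiral, height) is returned so embedded
#' distances can be checked against the true unrolled geometry: the arc
#' length is s(t) = (t sqrt(1 + t^2) + asinh(t)) / 2.
#'
#' @param n number of points (>= 10).
#' @param noise_sd standard deviation of additive 3-D Gaussian noise.
#' @param seed integer seed.
#' @param labels attach binary labels by thresholding t at its range
#'   midpoint (3 pi), for supervised-embedding tests. Default FALSE.
#' @return list with `table` (a [feature_table] of the 3-D coordinates)
#'   and `intrinsic` (n x 2 matrix: arc length, height).
#' @export
make_swiss_roll <- function(n, noise_sd = 0, seed = 1L, labels = FALSE) {
  if (n < 10) stop("n must be >= 10")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  arc_of <- function(t) (t * sqrt(1 + t^2) + asinh(t)) / 2
  with_local_seed(seed, {
    # uniform in arc length; invert s(t) by monotone interpolation
    t_grid <- seq(1.5 * pi, 4.5 * pi, length.out = 4096)
    s <- runif(n, arc_of(1.5 * pi), arc_of(4.5 * pi))
    t <- stats::approx(arc_of(t_grid), t_grid, xout = s)$y
    h <- runif(n, 0, 21)
    X <- cbind(x = t * cos(t), y = h, z = t * sin(t))
    if (noise_sd > 0) X <- X + matrix(rnorm(3 * n, sd = noise_sd), n, 3)
    arc <- arc_of(t)
    y <- if (labels) as.integer(t > 3 * pi) else NULL
    list(table = feature_table(X, y, sprintf("sr_%04d", seq_len(n))),
         intrinsic = cbind(arc = arc, height = h))
  })
}
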