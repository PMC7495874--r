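make_ratio <- function(Y, y) {
  D <- as.matrix(dist(Y))
  same <- outer(y, y, `==`) & upper.tri(D)
  diff <- outer(y, y, `!=`) & upper.tri(D)
  mean(D[diff]) / mean(D[same])
}

test_that("supervision increases the between/within distance ratio", {
  tab <- gaussian_fixture(n_per = 20, dim = 10, separation = 6, seed = 11)
  fit <- suppressWarnings(
    sisomap_fit(tab, sisomap_params(k = 5, alpha = 0.5, beta = "auto", d = 3)))
  expect_gt(make_ratio(fit$Y, tab$y), make_ratio(tab$X, tab$y))
})

test_that("uniform labels reproduce the unsupervised edge set", {
  set.seed(14)
  tab <- feature_table(matrix(rnorm(60), 20, 3), y = rep(1L, 20))
  sup <- sisomap_fit(tab, sisomap_params(k = 4, d = 2))
  uns <- isomap_fit(tab, k = 4, d = 2)
  expect_edge_sets_equal(sup$graph$edges, uns$graph$edges)
})

test_that("N = 2 embeds at +/- D/2", {
  tab <- feature_table(matrix(c(0, 3), ncol = 1), y = c(0, 1))
  fit <- sisomap_fit(tab, sisomap_params(k = 1, d = 1, beta = 9))
  D <- pairwise_dissimilarity(tab$X, tab$y, alpha = 0.5, beta = 9)
  expect_equal(sort(as.vector(fit$Y)), c(-1, 1) * D[1, 2] / 2,
               tolerance = 1e-10)

  iso <- isomap_fit(tab, k = 1, d = 1)
  expect_equal(sort(as.vector(iso$Y)), c(-1.5, 1.5), tolerance = 1e-10)
})

test_that("the full embedding is deterministic and permutation-equivariant", {
  tab <- gaussian_fixture(n_per = 10, dim = 5, separation = 4, seed = 3)
  p <- sisomap_params(k = 4, d = 2)
  f1 <- suppressWarnings(sisomap_fit(tab, p))
  f2 <- suppressWarnings(sisomap_fit(tab, p))
  expect_identical(f1$Y, f2$Y)
  perm <- sample(20)
  fp <- suppressWarnings(sisomap_fit(tab[perm], p))
  expect_equal(fp$Y, f1$Y[perm, ], tolerance = 1e-9)
})

test_that("points in an affine subspace are reproduced exactly with a complete graph", {
  set.seed(4)
  basis <- qr.Q(qr(matrix(rnorm(5 * 2), 5, 2)))
  P <- matrix(rnorm(24), 12, 2) %*% t(basis)  # 12 points in a 2-D plane of R^5
  tab <- feature_table(P)
  fit <- isomap_fit(tab, k = 11, d = 2)       # k = N-1: geodesic = Euclidean
  expect_lt(max(abs(dist(fit$Y) - dist(P))), 1e-6)
})

test_that("out-of-sample mapping is self-consistent and geometrically sane", {
  tab <- gaussian_fixture(n_per = 20, dim = 10, separation = 6, seed = 11)
  fit <- suppressWarnings(sisomap_fit(tab, sisomap_params(k = 5, d = 3)))
  expect_lt(max(abs(predict(fit, tab$X) - fit$Y)), 1e-6)

  # a midpoint of two adjacent same-class points lands between their images
  line <- feature_table(matrix(seq(0, 3, by = 0.1), ncol = 1),
                        y = rep(1L, 31))
  lfit <- sisomap_fit(line, sisomap_params(k = 2, d = 1))
  mid <- matrix(1.55, 1, 1)            # midpoint of rows at 1.5 and 1.6
  ym <- predict(lfit, mid)
  ia <- which(line$X[, 1] == 1.5); ib <- which(line$X[, 1] == 1.6)
  gap <- abs(lfit$Y[ia, 1] - lfit$Y[ib, 1])
  expect_lt(abs(ym[1, 1] - lfit$Y[ia, 1]), gap)
  expect_lt(abs(ym[1, 1] - lfit$Y[ib, 1]), gap)

  # empty input, empty output; dimension mismatch rejected
  expect_equal(nrow(predict(fit, tab$X[0, , drop = FALSE])), 0)
  expect_error(predict(fit, matrix(0, 2, 3)), "columns")
  expect_identical(sisomap_transform(fit, tab$X), predict(fit, tab$X))
})

test_that("transductive refit embeds train and test jointly", {
  tab <- gaussian_fixture(n_per = 15, dim = 6, separation = 5, seed = 9)
  tr <- tab[1:20]; te <- tab[21:30]
  td <- suppressWarnings(sisomap_fit_transductive(tr, te, sisomap_params(k = 5, d = 2)))
  expect_equal(nrow(td$Y_train), 20)
  expect_equal(nrow(td$Y_test), 10)
  expect_true(td$fit$supervised)
})

test_that("parameter validation matches the documented constraints", {
  expect_error(sisomap_params(alpha = 1.2), "alpha")
  expect_error(sisomap_params(beta = 0), "beta")
  expect_error(sisomap_params(k = 0), "k")
  tab <- gaussian_fixture(n_per = 3, dim = 2, separation = 1, seed = 2)
  expect_error(sisomap_fit(tab, sisomap_params(k = 2, d = 6)), "d must be < N")
  expect_error(sisomap_fit(feature_table(tab$X)), "labels")
})
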