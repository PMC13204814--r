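test_that("soft-thresholding matches its definition", {
  expect_equal(softThreshold(c(-2, 1, 0.3), 0), c(-2, 1, 0.3))
  expect_equal(softThreshold(c(0.5), 0.5), 0)
  expect_equal(softThreshold(c(-2, 1, 0.3), 1), c(-1, 0, 0))
  expect_error(softThreshold(1:3, -0.1), "nonnegative")
})

test_that("L1 projection handles boundary cases and rejects bad input", {
  expect_equal(projectL1(c(3, 0, 0), 1), c(1, 0, 0))
  expect_equal(projectL1(c(1, 1), sqrt(2)), rep(1 / sqrt(2), 2),
               tolerance = 1e-10)
  expect_error(projectL1(c(0, 0, 0), 1), "all-zero")
  expect_error(projectL1(c(1, 2), 0.5), "must lie in")
  expect_error(projectL1(c(1, 2), 3), "must lie in")
})

test_that("L1 projection matches a dense grid-search oracle", {
  set.seed(42)
  for (k in 1:60) {
    p <- sample(3:12, 1)
    x <- rnorm(p)
    cc <- runif(1, 1, sqrt(p))
    w <- projectL1(x, cc)
    wg <- gridProjectOracle(x, cc)
    expect_lt(max(abs(w - wg)), 1e-6)
    expect_lte(sum(abs(w)), cc + 1e-8)
    expect_lte(sqrt(sum(w^2)), 1 + 1e-8)
  }
})

test_that("unpenalized two-block fit equals the leading SVD of the cross-product", {
  for (k in 1:10) {
    X <- randBlocks(50, c(6, 4), seed = 100 + k)
    f <- fitSmcca(X, sqrt(c(6, 4)), nDims = 1, tol = 1e-12, maxIter = 20000)
    s <- svd(crossprod(X[[1]], X[[2]]))
    expect_lt(abs(f@objectives[1] - s$d[1]), 1e-6)
    w1 <- weightMatrix(f, 1)[, 1]
    sgn <- sign(sum(w1 * s$u[, 1]))
    expect_lt(max(abs(w1 - sgn * s$u[, 1])), 1e-4)
    expect_lt(max(abs(weightMatrix(f, 2)[, 1] - sgn * s$v[, 1])), 1e-4)
  }
})

test_that("extreme sparsity (c = 1) reduces to the largest cross-product entry", {
  for (k in 1:10) {
    X <- randBlocks(30, c(2, 2), seed = 200 + k)
    f <- suppressWarnings(fitSmcca(X, c(1, 1), nDims = 1))
    sel <- c(which(abs(weightMatrix(f, 1)[, 1]) > 1e-9),
             which(abs(weightMatrix(f, 2)[, 1]) > 1e-9))
    expect_equal(unname(sel), oneHotOracle(crossprod(X[[1]], X[[2]])))
  }
})

test_that("the objective never decreases across coordinate-ascent sweeps", {
  for (k in 1:20) {
    p <- c(7, 3, 5)
    X <- randBlocks(20, p, seed = 300 + k)
    set.seed(k)
    pen <- 1 + runif(3) * (sqrt(p) - 1)
    f <- suppressWarnings(fitSmcca(X, pen, nDims = 2, maxIter = 60))
    for (tr in f@objectiveTrace) {
      expect_true(all(diff(tr) > -1e-9))
    }
  }
})

test_that("orthogonal blocks give a zero objective and a degenerate flag", {
  X1 <- matrix(0, 8, 3)
  X1[1:4, ] <- scale(matrix(rnorm(12), 4)) / 2
  X2 <- matrix(0, 8, 2)
  X2[5:8, ] <- scale(matrix(rnorm(8), 4)) / 2
  colnames(X1) <- paste0("a", 1:3)
  colnames(X2) <- paste0("b", 1:2)
  expect_equal(max(abs(crossprod(X1, X2))), 0)
  f <- suppressWarnings(fitSmcca(list(A = X1, B = X2), c(1.5, 1.2), nDims = 1))
  expect_equal(f@objectives[1], 0)
  expect_true(f@degenerate[1])
})

test_that("every returned solution satisfies the norm constraints", {
  for (k in 1:15) {
    p <- c(6, 4, 5)
    X <- randBlocks(25, p, seed = 400 + k)
    set.seed(k)
    pen <- 1 + runif(3) * (sqrt(p) - 1)
    f <- suppressWarnings(fitSmcca(X, pen, nDims = 2))
    for (i in 1:3) {
      w <- weightMatrix(f, i)
      expect_true(all(abs(w) <= 1 + 1e-8))
      expect_true(all(sqrt(colSums(w^2)) <= 1 + 1e-8))
      expect_true(all(colSums(abs(w)) <= pen[i] + 1e-8))
    }
    expect_true(all(abs(canonicalCorrelations(f)) <= 1 + 1e-8))
  }
})

test_that("support size is non-increasing as the L1 budget shrinks", {
  X <- randBlocks(30, c(10, 4, 6), seed = 7)
  nnz <- vapply(seq(sqrt(10), 1, length.out = 8), function(cb) {
    f <- suppressWarnings(fitSmcca(X, c(cb, 1.5, 1.8), nDims = 1,
                                   extraStarts = 0))
    sum(abs(weightMatrix(f, 1)[, 1]) > 1e-10)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("permuting variable order within a block permutes the weights", {
  X <- randBlocks(25, c(6, 4), seed = 11)
  pen <- c(1.8, 1.4)
  f1 <- suppressWarnings(fitSmcca(X, pen, nDims = 1))
  perm <- c(4, 1, 6, 2, 5, 3)
  Xp <- X
  Xp[[1]] <- X[[1]][, perm]
  f2 <- suppressWarnings(fitSmcca(Xp, pen, nDims = 1))
  expect_equal(weightMatrix(f2, 1)[, 1],
               weightMatrix(f1, 1)[perm, 1], tolerance = 1e-8)
  expect_equal(canonicalCorrelations(f2), canonicalCorrelations(f1),
               tolerance = 1e-8)
})

test_that("deflation annihilates a rank-1 cross-product exactly", {
  set.seed(5)
  u <- projectL1(rnorm(6), sqrt(6))
  v <- projectL1(rnorm(4), 2)
  C <- list("A:B" = 3.7 * tcrossprod(u, v))
  Cd <- deflateCrossProducts(C, list(A = u, B = v))
  expect_lt(max(abs(Cd[["A:B"]])), 1e-10)
  # when w_i' C w_j = 0 the cross-product is untouched
  C2 <- list("A:B" = tcrossprod(c(1, 0, 0, 0), rnorm(4)))
  w <- list(A = c(0, 1, 0, 0), B = projectL1(rnorm(4), 2))
  expect_equal(drop(crossprod(w$A, C2[["A:B"]] %*% w$B)), 0)
  expect_equal(deflateCrossProducts(C2, w)[["A:B"]], C2[["A:B"]])
  expect_error(deflateCrossProducts(C, list(A = u[1:3], B = v)),
               "shape mismatch")
})

test_that("two orthogonal planted components are recovered in order", {
  set.seed(8)
  n <- 400
  f1 <- rnorm(n)
  f2 <- rnorm(n)
  X1 <- cbind(f1 + 0.3 * rnorm(n), f1 + 0.3 * rnorm(n),
              f2 + 0.3 * rnorm(n), f2 + 0.3 * rnorm(n),
              rnorm(n), rnorm(n))
  X2 <- cbind(f1 + 0.3 * rnorm(n), f2 + 0.3 * rnorm(n), rnorm(n))
  colnames(X1) <- paste0("a", 1:6)
  colnames(X2) <- paste0("b", 1:3)
  X <- list(A = scale(X1), B = scale(X2))
  f <- fitSmcca(X, c(1.5, 1.1), nDims = 2, maxIter = 100)
  top2 <- function(d) sort(order(-abs(weightMatrix(f, "A")[, d]))[1:2])
  s1 <- top2(1)
  s2 <- top2(2)
  expect_true(identical(s1, c(1L, 2L)) || identical(s1, c(3L, 4L)))
  expect_true(identical(s2, c(1L, 2L)) || identical(s2, c(3L, 4L)))
  expect_length(intersect(s1, s2), 0)
})

test_that("a single-dimension multi-fit equals fitComponent", {
  X <- randBlocks(20, c(5, 3, 4), seed = 21)
  pen <- c(1.7, 1.2, 1.5)
  f1 <- suppressWarnings(fitSmcca(X, pen, nDims = 1))
  f2 <- suppressWarnings(fitComponent(X, pen))
  expect_identical(f1@weights, f2@weights)
  expect_identical(f1@correlations, f2@correlations)
})

test_that("penalty bounds are enforced", {
  X <- randBlocks(20, c(5, 3), seed = 31)
  expect_error(fitSmcca(X, c(0.5, 1.2)), "outside")
  expect_error(fitSmcca(X, c(1.2, 2)), "outside")
  expect_error(fitSmcca(X, c(1.2)), "one penalty per block")
})

test_that("cumulative shared variance is within [0, 1] and non-decreasing", {
  X <- randBlocks(30, c(6, 4, 5), seed = 41)
  f <- suppressWarnings(fitSmcca(X, c(2, 1.5, 1.8), nDims = 3, maxIter = 60))
  css <- cumulativeSharedVariance(f)
  expect_true(all(css >= 0 & css <= 1))
  expect_true(all(diff(css) >= -1e-12))
})
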