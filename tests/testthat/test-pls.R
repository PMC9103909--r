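test_that("the rank-stratified split follows the 2:1 triplet rule", {
  sp <- rankStratifiedSplit(runif(252), seed = 9)
  expect_length(sp@calibration, 168L)
  expect_length(sp@prediction, 84L)

  y <- c(7, 6, 5, 4, 3, 2)
  sp <- rankStratifiedSplit(y, seed = 2)
  expect_length(sp@prediction, 2L)
  expect_length(intersect(sp@prediction, 1:3), 1L)  # one of {7,6,5}
  expect_length(intersect(sp@prediction, 4:6), 1L)  # one of {4,3,2}

  sp8 <- rankStratifiedSplit(runif(8), seed = 1)
  expect_length(sp8@prediction, 2L)
  expect_length(sp8@calibration, 6L)

  expect_error(rankStratifiedSplit(c(1, 2), seed = 1), "at least 3")
})

test_that("split partition laws hold over random instances", {
  set.seed(77)
  for (case in 1:25) {
    n <- sample(3:100, 1)
    y <- sample(rep(runif(max(1, n %/% 4)), length.out = n))  # heavy ties
    sp <- rankStratifiedSplit(y, seed = case)
    expect_length(intersect(sp@calibration, sp@prediction), 0L)
    expect_setequal(c(sp@calibration, sp@prediction), seq_len(n))
    expect_length(sp@prediction, n %/% 3L)
  }
})

test_that("PLS1 on one variable reduces to simple regression", {
  m <- plsFit(cbind(c(1, 2, 3)), c(2, 4, 6), 1)
  expect_equal(coef(m), 2, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(m@intercept, 0, tolerance = 1e-12)
  expect_equal(predict(m, cbind(4)), 8, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected or truncated", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(plsFit(X, rep(1, 10), 1), "zero variance")
  expect_warning(plsFit(X, rnorm(10), 5), "rank bound")
})

test_that("full-rank PLS equals ordinary least squares", {
  set.seed(5)
  X <- matrix(rnorm(100), 20, 5)
  y <- drop(X %*% c(1, -2, 0.5, 3, -1)) + rnorm(20, 0, 0.2)
  m <- plsFit(X, y, 5)
  ols <- unname(coef(lm(y ~ X)))
  expect_equal(coef(m), ols[-1], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(m@intercept, ols[1], tolerance = 1e-8)
})

test_that("score vectors are mutually orthogonal", {
  set.seed(6)
  X <- matrix(rnorm(40 * 12), 40)
  y <- rnorm(40)
  T <- plsFit(X, y, 6)@scores
  for (i in 1:5) for (j in (i + 1):6)
    expect_lt(abs(crossprod(T[, i], T[, j])),
              1e-8 * sqrt(sum(T[, i]^2) * sum(T[, j]^2)))
})

test_that("prediction is the documented affine map", {
  set.seed(8)
  X <- matrix(rnorm(30 * 6), 30)
  y <- rnorm(30)
  m <- plsFit(X, y, 3)
  expect_equal(predict(m, X), drop(X %*% coef(m)) + m@intercept)
  expect_equal(predict(m, matrix(colMeans(X), 1)), mean(y), tolerance = 1e-10)
  expect_error(predict(m, X[, 1:3]), "variables")
})

test_that("permuting variables and un-permuting coefficients is a no-op", {
  set.seed(9)
  X <- matrix(rnorm(25 * 8), 25)
  y <- rnorm(25)
  m <- plsFit(X, y, 4)
  perm <- sample(8)
  mp <- plsFit(X[, perm], y, 4)
  expect_equal(coef(mp)[order(perm)], coef(m), tolerance = 1e-10)
  expect_equal(predict(mp, X[, perm]), predict(m, X), tolerance = 1e-10)
})

test_that("cross-validation recovers a noiseless linear relation with one LV", {
  x <- seq_len(30)
  cv <- plsCrossValidate(cbind(x), 2 * x + 1, maxComponents = 3, folds = 5,
                         seed = 4)
  expect_equal(cv$nComponents, 1L)
  expect_lt(cv$rmsecv[1], 1e-10)
})

test_that("cross-validation is deterministic under its seed", {
  set.seed(10)
  X <- matrix(rnorm(40 * 6), 40)
  y <- rnorm(40)
  a <- plsCrossValidate(X, y, 4, folds = 5, seed = 3)
  b <- plsCrossValidate(X, y, 4, folds = 5, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a$foldid,
                         plsCrossValidate(X, y, 4, folds = 5, seed = 8)$foldid))
})

test_that("the RMSECV curve matches an explicit fold-by-fold oracle", {
  set.seed(12)
  n <- 30; p <- 10
  scores <- matrix(rnorm(n * 3), n)
  load <- matrix(rnorm(3 * p), 3)
  X <- scores %*% load + matrix(rnorm(n * p, 0, 0.1), n)
  y <- drop(scores %*% c(2, -1, 0.5)) + rnorm(n, 0, 0.1)
  K <- 4L
  cv <- plsCrossValidate(X, y, K, folds = 5, seed = 6)
  sse <- matrix(0, 1, K)
  for (f in 1:5) {
    tr <- cv$foldid != f
    for (k in 1:K) {
      m <- plsFit(X[tr, ], y[tr], k)
      pred <- predict(m, X[!tr, , drop = FALSE])
      sse[k] <- sse[k] + sum((y[!tr] - pred)^2)
    }
  }
  expect_equal(cv$rmsecv, sqrt(sse[1, ] / n), tolerance = 1e-10)
})

test_that("cross-validation validates its fold arguments", {
  X <- matrix(rnorm(20), 10, 2)
  y <- rnorm(10)
  expect_error(plsCrossValidate(X, y, 2, folds = 1), "folds")
  expect_error(plsCrossValidate(X, y, 2, folds = 11), "empty")
})
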