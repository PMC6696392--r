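test_that("autoscaling centres to mean 0, unit sample variance", {
  sc <- fitScaler(cbind(a = c(1, 2, 3)))
  scaled <- scaleData(sc, cbind(a = c(1, 2, 3)))$X
  # sample (n-1) SD convention: sd(1,2,3) = 1
  expect_equal(unname(scaled[, 1]), c(-1, 0, 1))
  # already-standardized column is unchanged
  z <- scale(rnorm(20))[, 1]
  sc2 <- fitScaler(cbind(z))
  expect_equal(unname(scaleData(sc2, cbind(z))$X[, 1]), z, tolerance = 1e-12)
  # constant column: flagged, scaled to exactly zero
  sc3 <- fitScaler(cbind(k = rep(4, 5), x = 1:5))
  expect_true(sc3$constant[1])
  expect_false(sc3$constant[2])
  expect_equal(unname(scaleData(sc3, cbind(rep(4, 5), 1:5))$X[, 1]), rep(0, 5))
  expect_error(fitScaler(cbind(1)), "at least 2")
  # transform then inverse-transform is identity on y
  y <- rnorm(6)
  sc4 <- fitScaler(matrix(rnorm(12), 6), y)
  expect_equal(unscaleY(sc4, scaleData(sc4, matrix(rnorm(12), 6), y)$y), y)
})

test_that("PLS1 reduces to known regression oracles", {
  set.seed(42)
  # A = min(n-1, p) on full-column-rank X equals ordinary least squares
  X <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  m <- fitPLS(X, y, A = 3)
  olsPred <- drop(cbind(1, X) %*% coef(lm(y ~ X)))
  expect_equal(predict(m, X), olsPred, tolerance = 1e-8, ignore_attr = TRUE)
  # p = 1 equals simple least squares
  x1 <- matrix(rnorm(12), ncol = 1)
  y1 <- 1.5 * x1[, 1] + rnorm(12, sd = 0.2)
  m1 <- fitPLS(x1, y1, A = 1)
  expect_equal(unname(predict(m1, x1)), unname(fitted(lm(y1 ~ x1))),
               tolerance = 1e-10)
  # single predictor: standardized coefficient equals Pearson correlation
  expect_equal(unname(stdCoefficients(m1)), cor(x1[, 1], y1))
  # exact linear y, A = p: perfect training fit
  ylin <- drop(X %*% c(1, -2, 0.5))
  mExact <- fitPLS(X, ylin, A = 3)
  expect_equal(rSquared(ylin, predict(mExact, X)), 1, tolerance = 1e-10)
})

test_that("fitPLS rejects out-of-range component counts", {
  X <- matrix(rnorm(20), 10, 2)
  y <- rnorm(10)
  expect_error(fitPLS(X, y, A = 0), "A must be")
  expect_error(fitPLS(X, y, A = 3), "A must be")
  expect_error(fitPLS(X, y[-1], A = 1), "length")
})

test_that("training R2 is non-decreasing in the component count", {
  set.seed(7)
  X <- matrix(rnorm(15 * 6), 15, 6)
  y <- drop(X[, 1] - X[, 4]) + rnorm(15, sd = 0.5)
  r2 <- vapply(1:6, function(A) {
    m <- fitPLS(X, y, A = A)
    rSquared(y, predict(m, X))
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("predictions are invariant to column order of X", {
  set.seed(8)
  X <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- rnorm(12)
  perm <- c(3, 1, 5, 2, 4)
  m1 <- fitPLS(X, y, A = 3)
  m2 <- fitPLS(X[, perm], y, A = 3)
  expect_equal(predict(m1, X), predict(m2, X[, perm]), tolerance = 1e-10)
  expect_equal(stdCoefficients(m1)[perm], stdCoefficients(m2),
               tolerance = 1e-10)
})

test_that("standardized coefficients are invariant to raw column rescaling", {
  set.seed(9)
  X <- matrix(rnorm(20 * 4), 20, 4)
  y <- drop(X %*% c(1, 0.5, 0, -1)) + rnorm(20, sd = 0.3)
  b1 <- stdCoefficients(fitPLS(X, y, A = 2))
  X2 <- X
  X2[, 2] <- X2[, 2] * 1000          # change of units
  X2[, 3] <- X2[, 3] / 250 + 7       # affine change
  b2 <- stdCoefficients(fitPLS(X2, y, A = 2))
  expect_equal(unname(b1), unname(b2), tolerance = 1e-10)
})

test_that("a pure-noise variable gets a near-zero standardized coefficient", {
  set.seed(10)
  n <- 400
  X <- cbind(sig = rnorm(n), noise = rnorm(n))
  y <- X[, "sig"] + rnorm(n, sd = 0.3)
  b <- stdCoefficients(fitPLS(X, y, A = 2))
  se <- 1 / sqrt(n)                   # correlation-scale standard error
  expect_lt(abs(b["noise"]), 3 * se)
  expect_gt(b["sig"], 0.8)
})

test_that("rmse and rSquared match their definitions", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(1, 1)), 1)
  expect_equal(rmse(c(0, 2), c(0, 0)), sqrt(2), tolerance = 1e-5)
  expect_error(rmse(1:3, 1:2), "lengths differ")
  y <- c(0, 1, 2)
  expect_equal(rSquared(y, y), 1)
  expect_equal(rSquared(y, rep(mean(y), 3)), 0)
  expect_equal(rSquared(c(0, 1, 2), c(0, 0, 2)), 0.5)
  expect_error(rSquared(c(1, 1), c(1, 2)), "constant")
})

test_that("component selection maximizes Q2 with ties to the smaller count", {
  set.seed(11)
  # one informative latent direction + noise: A = 1 wins at high signal
  n <- 40
  t <- rnorm(n)
  X <- outer(t, rep(1, 6)) + matrix(rnorm(n * 6, sd = 0.1), n, 6)
  y <- 2 * t + rnorm(n, sd = 0.05)
  folds <- kfoldSplit(n, 5, seed = 2)
  sel <- selectComponents(X, y, folds, Amax = 5)
  # brute-force Q2 curve from independent per-A cross-validation
  brute <- vapply(1:5, function(A) crossValidate(X, y, folds, A)$q2, numeric(1))
  expect_equal(sel$q2, brute, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sel$A, which.max(brute))
  expect_equal(sel$A, 1L)
  # Amax = 1 returns 1
  expect_equal(selectComponents(X, y, folds, Amax = 1)$A, 1L)
  # duplicated column: the Q2 path flattens and the smaller count is kept
  Xdup <- cbind(x = t, x2 = t)
  ydup <- t
  seldup <- selectComponents(Xdup, ydup, folds, Amax = 2)
  expect_equal(seldup$q2[1], seldup$q2[2], tolerance = 1e-12)
  expect_equal(seldup$A, 1L)
})

test_that("PLS models serialize to JSON and back with identical predictions", {
  set.seed(12)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(10)
  m <- fitPLS(X, y, A = 2)
  path <- tempfile(fileext = ".json")
  writePLSModel(m, path)
  m2 <- readPLSModel(path)
  expect_identical(m2@variables, m@variables)
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-15)
})
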