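test_that("weighted bootstrap subsets respect the weight distribution", {
  # degenerate weight: always the single supported variable
  withSeed(1, {
    for (i in 1:20)
      expect_identical(weightedBootstrapSubset(c(0, 1, 0), 5), 2L)
  })
  # zero-weight variables never appear
  withSeed(2, {
    hits <- replicate(2000, 4L %in% weightedBootstrapSubset(c(1, 1, 1, 0), 4))
    expect_false(any(hits))
  })
  expect_error(weightedBootstrapSubset(c(0, 0), 2), "all zero")
  expect_error(weightedBootstrapSubset(c(-1, 1), 2), "non-negative")
})

test_that("uniform-weight unique-draw fraction matches 1-(1-1/p)^p", {
  p <- 50
  frac <- withSeed(3, {
    mean(replicate(3000, length(weightedBootstrapSubset(rep(1, p), p)) / p))
  })
  expect_equal(frac, 1 - (1 - 1 / p)^p, tolerance = 0.01)
})

test_that("bossConfig validates its invariants", {
  expect_error(bossConfig(nSubsets = 5), "nSubsets")
  expect_error(bossConfig(topFraction = 0), "topFraction")
  expect_error(bossConfig(nSubsets = 10, topFraction = 0.05),
               "topFraction \\* nSubsets")
  cfg <- bossConfig(nSubsets = 100)
  expect_s3_class(cfg, "BOSSConfig")
})

test_that("one iteration reweights toward signal and keeps a probability vector", {
  d <- sparseSignalFixture()
  cfg <- bossConfig(nSubsets = 200)
  folds <- kfoldSplit(nrow(d$X), 5, seed = 1)
  p <- ncol(d$X)
  pool <- seq_len(p)
  w <- rep(1 / p, p)
  sigIdx <- match(d$signal, colnames(d$X))
  sigMass <- numeric(3)
  withSeed(5, {
    for (it in 1:3) {
      res <- bossIteration(d$X, d$y, pool, w, cfg, folds)
      expect_true(all(res$weights >= 0))
      expect_equal(sum(res$weights), 1)
      expect_lte(length(res$pool), length(pool))   # soft shrinkage
      sigMass[it] <- sum(res$weights[names(res$weights) %in% d$signal])
      pool <- res$pool
      w <- unname(res$weights)
    }
  })
  # summed weight of the planted variables grows over the first iterations
  expect_equal(sigMass, sort(sigMass))
  expect_gt(sigMass[1], 5 / p)       # already above the uniform share
})

test_that("a pool of one variable is terminal", {
  d <- sparseSignalFixture()
  cfg <- bossConfig(nSubsets = 50)
  folds <- kfoldSplit(nrow(d$X), 5, seed = 2)
  j <- match(d$signal[1], colnames(d$X))
  res <- withSeed(6, bossIteration(d$X, d$y, j, 1, cfg, folds))
  expect_true(res$terminal)
  expect_identical(res$pool, j)
  expect_identical(res$bestSubset, j)
})

test_that("on all-noise data the best submodel RMSECV is near SD(y)", {
  withSeed(7, {
    n <- 40
    X <- matrix(rnorm(n * 30), n, 30,
                dimnames = list(NULL, paste0("V", 1:30)))
    y <- rnorm(n)
    cfg <- bossConfig(nSubsets = 200)
    folds <- kfoldSplit(n, 5, seed = 3)
    res <- bossIteration(X, y, seq_len(30), rep(1 / 30, 30), cfg, folds)
    # null-model oracle: predicting the mean gives RMSECV ~ SD(y)
    expect_lt(abs(res$bestRmsecv - sd(y)) / sd(y), 0.2)
  })
})

test_that("runBOSS shrinks the pool monotonically and is seed-deterministic", {
  d <- sparseSignalFixture()
  cfg <- bossConfig(nSubsets = 300)
  res <- runBOSS(d$X, d$y, cfg, seed = 9)
  expect_s4_class(res, "BOSSResult")
  expect_true(all(diff(res@trace$poolSize) <= 0))
  expect_equal(res@rmsecv, min(res@trace$bestRmsecv))
  # weights are probability vectors at every iteration
  for (w in res@weightsTrace) {
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1)
  }
  res2 <- runBOSS(d$X, d$y, cfg, seed = 9)
  expect_identical(res@selected, res2@selected)
  expect_identical(res@rmsecv, res2@rmsecv)
  expect_identical(res@trace, res2@trace)
  res3 <- runBOSS(d$X, d$y, cfg, seed = 10)
  expect_false(identical(res@trace, res3@trace))
})

test_that("with two candidates BOSS selects the perfect predictor", {
  withSeed(11, {
    n <- 30
    X <- cbind(good = rnorm(n), bad = rnorm(n))
    y <- X[, "good"]
    res <- runBOSS(X, y, bossConfig(nSubsets = 100), seed = 12)
    expect_identical(res@selected, "good")
  })
})

test_that("the winning subset beats the full-variable model's RMSECV", {
  d <- sparseSignalFixture()
  res <- runBOSS(d$X, d$y, bossConfig(nSubsets = 300), seed = 13)
  folds <- res@folds
  full <- crossValidate(d$X, d$y, folds,
                        A = selectComponents(d$X, d$y, folds)$A)
  expect_lt(res@rmsecv, full$rmsecv)
})

test_that("repeatBOSS aggregates per-run statistics with finite SDs", {
  d <- sparseSignalFixture()
  runs <- repeatBOSS(d$X, d$y, bossConfig(nSubsets = 200), nRuns = 3,
                     seed = 14)
  expect_length(runs$results, 3L)
  expect_equal(nrow(runs$stats), 3L)
  expect_true(all(is.finite(runs$summary$mean)))
  expect_true(all(is.finite(runs$summary$sd)))
  # per-run RMSECV consistency between results and stats
  expect_equal(runs$stats$rmsecv,
               vapply(runs$results, function(r) r@rmsecv, numeric(1)))
  # single run: SD reported as NA
  one <- repeatBOSS(d$X, d$y, bossConfig(nSubsets = 200), nRuns = 1,
                    seed = 15)
  expect_true(all(is.na(one$summary$sd)))
  # planted variables are selected more often than typical noise variables
  freq <- selectionFrequency(runs$results, colnames(d$X))
  noise <- setdiff(colnames(d$X), d$signal)
  expect_gt(min(freq[d$signal]), median(freq[noise]))
})
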