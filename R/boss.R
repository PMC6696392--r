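# Bootstrapping soft shrinkage (BOSS) variable selection.
#
# Each iteration draws many bootstrap subsets of the current variable pool
# (weighted bootstrap sampling), scores a PLS submodel per subset by RMSECV
# under a shared fold assignment, extracts the best fraction of submodels
# (model population analysis), reweights variables by their summed absolute
# standardized coefficients in those models, and shrinks the pool to the
# union of variables the best models used. Iteration continues until one
# variable remains; the subset with the smallest RMSECV seen anywhere wins.

#' BOSS configuration
#'
#' @param nSubsets Bootstrap subsets (and submodels) per iteration;
#'   default 1000.
#' @param topFraction Fraction of lowest-RMSECV submodels extracted for
#'   reweighting; default 0.10.
#' @param cvFolds Cross-validation folds for submodel RMSECV; default 5.
#' @param Amax Upper bound on PLS components per submodel (further capped by
#'   subset size and training-fold size); default 10.
#' @param maxIterations Safety cap on shrinkage iterations; default 100.
#' @param stallIterations Terminate once the pool size has not decreased for
#'   this many consecutive iterations (default 5). The winning subset is the
#'   minimum-RMSECV subset over all iterations, so once the pool stops
#'   shrinking further iterations only resample the same candidate space.
#' @param scaleMode Autoscaling mode for cross-validation, \code{"per_fold"}
#'   or \code{"global"}.
#' @return Validated configuration list of class \code{BOSSConfig}.
#' @export
bossConfig <- function(nSubsets = 1000L, topFraction = 0.10, cvFolds = 5L,
                       Amax = 10L, maxIterations = 100L,
                       stallIterations = 5L,
                       scaleMode = c("per_fold", "global")) {
  scaleMode <- match.arg(scaleMode)
  nSubsets <- as.integer(nSubsets)
  if (nSubsets < 10L) stop("nSubsets must be >= 10")
  if (topFraction <= 0 || topFraction > 1)
    stop("topFraction must be in (0, 1]")
  if (topFraction * nSubsets < 1)
    stop("topFraction * nSubsets must be >= 1")
  structure(list(nSubsets = nSubsets, topFraction = topFraction,
                 cvFolds = as.integer(cvFolds), Amax = as.integer(Amax),
                 maxIterations = as.integer(maxIterations),
                 stallIterations = as.integer(stallIterations),
                 scaleMode = scaleMode),
            class = "BOSSConfig")
}

#' Weighted bootstrap draw of a variable subset
#'
#' Draws \code{nDraws} variables with replacement, with probability
#' proportional to \code{weights}, and returns the deduplicated support of
#' the draws (sorted indices). Uses the caller's RNG stream.
#'
#' @param weights Non-negative weight vector over the candidate variables
#'   (not all zero).
#' @param nDraws Number of draws with replacement.
#' @return Sorted integer vector of unique drawn indices.
#' @export
weightedBootstrapSubset <- function(weights, nDraws) {
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) <= 0) stop("weights must not be all zero")
  sort(unique(sample.int(length(weights), nDraws, replace = TRUE,
                         prob = weights)))
}

#' One BOSS shrinkage iteration
#'
#' Generates \code{nSubsets} weighted bootstrap subsets of the current pool
#' (draw count = pool size), cross-validates a PLS submodel per subset with
#' automatic component selection, extracts the \code{topFraction} of
#' submodels with the lowest RMSECV (ties broken by smaller subset, then
#' draw order), and reweights every variable by its summed absolute
#' standardized coefficient across the extracted models, normalized to sum
#' one. The next pool is the union of variables used by the extracted
#' models. Uses the caller's RNG stream.
#'
#' @param X Full n x p design matrix (raw scale).
#' @param y Activity vector.
#' @param pool Integer indices of the current candidate variables.
#' @param weights Probability vector over \code{pool}.
#' @param config A \code{\link{bossConfig}}.
#' @param folds Shared fold labels (all submodels of a run use the same
#'   folds so their RMSECVs are comparable).
#' @return List: \code{pool}, \code{weights} (over the new pool),
#'   \code{bestSubset} (indices), \code{bestRmsecv}, \code{bestA},
#'   \code{medianRmsecv}, \code{terminal} (TRUE when called with one
#'   variable).
#' @export
bossIteration <- function(X, y, pool, weights, config, folds) {
  if (length(pool) == 1L) {
    cv <- crossValidate(X[, pool, drop = FALSE], y, folds, A = 1L,
                        scaleMode = config$scaleMode)
    return(list(pool = pool, weights = stats::setNames(1, colnames(X)[pool]),
                bestSubset = pool, bestRmsecv = cv$rmsecv, bestA = cv$A,
                medianRmsecv = cv$rmsecv, terminal = TRUE))
  }
  nDraws <- length(pool)
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) <= 0) stop("weights must not be all zero")
  # one batched draw: distributionally identical to nSubsets independent
  # weightedBootstrapSubset() calls, deduplication happens in the kernel
  draws <- matrix(pool[sample.int(nDraws, nDraws * config$nSubsets,
                                  replace = TRUE, prob = weights)],
                  nrow = nDraws)
  scored <- cpp_boss_score_subsets(X, as.numeric(y), as.integer(folds),
                                   draws, config$Amax,
                                   config$scaleMode == "per_fold")
  subsets <- scored$subsets
  rmsecvs <- scored$rmsecv
  sizes <- scored$size
  As <- scored$ncomp
  nTop <- max(1L, as.integer(floor(config$topFraction * config$nSubsets)))
  ord <- order(rmsecvs, sizes, seq_along(rmsecvs))
  top <- ord[seq_len(nTop)]

  wNew <- numeric(ncol(X))
  for (s in top) {
    sub <- subsets[[s]]
    B <- cpp_pls_coef_path(X[, sub, drop = FALSE], as.numeric(y),
                           As[s], TRUE)
    wNew[sub] <- wNew[sub] + abs(B[, As[s]])
  }
  newPool <- which(wNew > 0)
  if (length(newPool) == 0L) {          # degenerate: keep the best subset
    newPool <- subsets[[top[1L]]]
    wNew[newPool] <- 1
  }
  w <- wNew[newPool] / sum(wNew[newPool])
  names(w) <- colnames(X)[newPool]
  list(pool = newPool, weights = w,
       bestSubset = subsets[[top[1L]]], bestRmsecv = rmsecvs[top[1L]],
       bestA = As[top[1L]], medianRmsecv = stats::median(rmsecvs),
       terminal = FALSE)
}

#' Run the BOSS variable-selection algorithm
#'
#' Starts from uniform weights over all p variables (plain bootstrap
#' sampling in the first iteration), iterates \code{\link{bossIteration}}
#' until the candidate pool shrinks to a single variable (or the iteration
#' cap), and returns the subset with the smallest RMSECV observed anywhere
#' during the shrinkage. One fold assignment is drawn per run and shared by
#' every submodel. Deterministic for a seed.
#'
#' @param X n x p design matrix with variable-ID colnames.
#' @param y Activity vector.
#' @param config A \code{\link{bossConfig}}.
#' @param seed Integer seed for the run.
#' @param verbose Print one line per iteration.
#' @return A \linkS4class{BOSSResult}.
#' @export
runBOSS <- function(X, y, config = bossConfig(), seed, verbose = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (p < 2L) stop("BOSS needs at least 2 candidate variables")
  if (n < config$cvFolds) stop("fewer samples than CV folds")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  seeds <- deriveSeeds(seed, 2L)
  folds <- kfoldSplit(n, config$cvFolds, seed = seeds[1L])

  pool <- seq_len(p)
  weights <- rep(1 / p, p)
  names(weights) <- colnames(X)
  weightsTrace <- list(weights)
  trace <- data.frame(iteration = integer(0), poolSize = integer(0),
                      bestRmsecv = numeric(0), medianRmsecv = numeric(0),
                      weightEntropy = numeric(0))
  best <- list(rmsecv = Inf, subset = NULL, A = NA_integer_)
  converged <- FALSE
  stalled <- 0L
  # near-ties in RMSECV (noiseless data drive it to machine epsilon) go to
  # the smaller subset, mirroring the within-iteration tie-break
  rmsecvTol <- 1e-8 * sd(y)
  better <- function(rmsecv, subset) {
    rmsecv < best$rmsecv - rmsecvTol ||
      (rmsecv < best$rmsecv + rmsecvTol &&
         length(subset) < length(best$subset))
  }

  withSeed(seeds[2L], {
    for (it in seq_len(config$maxIterations)) {
      res <- bossIteration(X, y, pool, weights, config, folds)
      ent <- -sum(res$weights[res$weights > 0] * log(res$weights[res$weights > 0]))
      trace[nrow(trace) + 1L, ] <- list(it, length(pool), res$bestRmsecv,
                                        res$medianRmsecv, ent)
      if (verbose)
        message(sprintf(
          "BOSS iter %2d: pool %3d -> %3d, best RMSECV %.4f (median %.4f)",
          it, length(pool), length(res$pool), res$bestRmsecv,
          res$medianRmsecv))
      if (better(res$bestRmsecv, res$bestSubset))
        best <- list(rmsecv = res$bestRmsecv, subset = res$bestSubset,
                     A = res$bestA)
      weightsTrace[[length(weightsTrace) + 1L]] <- res$weights
      stalled <- if (length(res$pool) < length(pool)) 0L else stalled + 1L
      pool <- res$pool
      weights <- unname(res$weights)
      if (stalled >= config$stallIterations) {
        # the pool no longer shrinks; the candidate space is fixed and the
        # minimum-RMSECV subset has been recorded
        converged <- TRUE
        break
      }
      if (res$terminal || length(pool) == 1L) {
        if (!res$terminal) {            # evaluate the final single variable
          res1 <- bossIteration(X, y, pool, weights, config, folds)
          trace[nrow(trace) + 1L, ] <- list(it + 1L, 1L, res1$bestRmsecv,
                                            res1$medianRmsecv, 0)
          if (better(res1$bestRmsecv, res1$bestSubset))
            best <- list(rmsecv = res1$bestRmsecv, subset = res1$bestSubset,
                         A = res1$bestA)
        }
        converged <- TRUE
        break
      }
    }
  })
  if (!converged)
    warning(sprintf("BOSS stopped at the %d-iteration cap with %d variables in the pool",
                    config$maxIterations, length(pool)))
  new("BOSSResult", selected = colnames(X)[best$subset],
      rmsecv = best$rmsecv, ncomp = as.integer(best$A), trace = trace,
      weightsTrace = weightsTrace, folds = as.integer(folds),
      seed = as.integer(seed), converged = converged)
}

#' Repeated BOSS runs with summary statistics
#'
#' Runs BOSS \code{nRuns} times from independent derived seeds (fold
#' assignments and bootstrap streams are re-randomized per run, so run-to-run
#' variation reflects the randomness of the algorithm), refits the final PLS
#' model on each run's selected subset, and summarizes R2, Q2, RMSE, RMSECV,
#' component count and selected-variable count as mean and SD.
#'
#' @param X n x p design matrix with variable-ID colnames.
#' @param y Activity vector.
#' @param config A \code{\link{bossConfig}}.
#' @param nRuns Number of repeated runs (the reference analysis uses 100).
#' @param seed Master seed from which per-run seeds are derived.
#' @param verbose Print one line per finished run.
#' @return List with \code{results} (list of \linkS4class{BOSSResult}),
#'   \code{models} (per-run refitted \linkS4class{PLSModel}), \code{stats}
#'   (per-run data.frame: nSelected, A, r2, q2, rmsecv, rmse), and
#'   \code{summary} (mean/sd per statistic; SD is NA for a single run).
#' @export
repeatBOSS <- function(X, y, config = bossConfig(), nRuns = 100L, seed,
                       verbose = FALSE) {
  stopifnot(nRuns >= 1L)
  X <- as.matrix(X)
  seeds <- deriveSeeds(seed, nRuns)
  results <- vector("list", nRuns)
  models <- vector("list", nRuns)
  stats <- data.frame(run = seq_len(nRuns), seed = seeds,
                      nSelected = NA_integer_, A = NA_integer_,
                      r2 = NA_real_, q2 = NA_real_,
                      rmsecv = NA_real_, rmse = NA_real_)
  sst <- sum((y - mean(y))^2)
  for (r in seq_len(nRuns)) {
    res <- runBOSS(X, y, config, seed = seeds[r])
    sel <- res@selected
    fit <- fitPLS(X[, sel, drop = FALSE], y, A = res@ncomp)
    yhat <- predict(fit, X[, sel, drop = FALSE])
    results[[r]] <- res
    models[[r]] <- fit
    stats$nSelected[r] <- length(sel)
    stats$A[r] <- res@ncomp
    stats$r2[r] <- rSquared(y, yhat)
    stats$q2[r] <- 1 - length(y) * res@rmsecv^2 / sst
    stats$rmsecv[r] <- res@rmsecv
    stats$rmse[r] <- rmse(y, yhat)
    if (verbose)
      message(sprintf("run %3d/%d: %d variables, RMSECV %.4f",
                      r, nRuns, length(sel), res@rmsecv))
  }
  cols <- c("nSelected", "A", "r2", "q2", "rmsecv", "rmse")
  summary <- data.frame(
    statistic = cols,
    mean = vapply(stats[cols], mean, numeric(1)),
    sd = if (nRuns > 1L) vapply(stats[cols], sd, numeric(1)) else NA_real_,
    row.names = NULL)
  list(results = results, models = models, stats = stats, summary = summary)
}
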