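# Variable importance from repeated BOSS runs: selection frequency combined
# with the standardized regression coefficients of the best (lowest-RMSECV)
# model.

#' Selection frequency over repeated BOSS runs
#'
#' @param results List of \linkS4class{BOSSResult} from
#'   \code{\link{repeatBOSS}}.
#' @param allVariables Character vector of all candidate variable IDs;
#'   variables never selected get frequency 0.
#' @return Named numeric vector: fraction of runs whose winning subset
#'   contains each variable.
#' @export
selectionFrequency <- function(results, allVariables) {
  stopifnot(length(results) >= 1L)
  counts <- stats::setNames(numeric(length(allVariables)), allVariables)
  for (res in results) {
    sel <- if (is(res, "BOSSResult")) res@selected else as.character(res)
    unknown <- setdiff(sel, allVariables)
    if (length(unknown))
      stop(sprintf("selected variable '%s' not in allVariables", unknown[1L]))
    counts[sel] <- counts[sel] + 1
  }
  counts / length(results)
}

#' Variables above a selection-frequency threshold
#'
#' @param frequencies Named frequency vector from
#'   \code{\link{selectionFrequency}}.
#' @param threshold Frequency cutoff in [0, 1]; strictly exceeded (the
#'   reference analysis reports variables selected in more than 60\% of 100
#'   runs, so the default is 0.60).
#' @return Character vector of variable IDs with frequency > threshold,
#'   sorted by descending frequency, ties by variable ID.
#' @export
frequentVariables <- function(frequencies, threshold = 0.60) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  keep <- frequencies > threshold
  ids <- names(frequencies)[keep]
  f <- frequencies[keep]
  ids[order(-f, ids)]
}

#' Importance report from repeated BOSS runs
#'
#' Picks the run with the smallest RMSECV (ties: first), refits a PLS model
#' on its selected variables on the full dataset (component count from the
#' winning submodel), and combines the standardized regression coefficients
#' with the selection frequencies of all runs. A positive coefficient means
#' the variable increases bitterness activity (lowers the taste threshold).
#'
#' @param results List of \linkS4class{BOSSResult}.
#' @param X Full design matrix the runs were computed on.
#' @param y Activity vector.
#' @param threshold Frequency cutoff for \code{frequent} (default 0.60).
#' @return List of class \code{ImportanceReport}: \code{frequencies} (all
#'   variables), \code{frequent} (IDs above threshold), \code{threshold},
#'   \code{bestRun} (index), \code{bestRmsecv}, \code{bestModel}
#'   (\linkS4class{PLSModel}), \code{coefficients} (named standardized
#'   coefficients of the best model's variables), \code{nRuns}.
#' @export
bestModelReport <- function(results, X, y, threshold = 0.60) {
  stopifnot(length(results) >= 1L)
  X <- as.matrix(X)
  freqs <- selectionFrequency(results, colnames(X))
  rmsecvs <- vapply(results, function(r) r@rmsecv, numeric(1))
  bestIdx <- which.min(rmsecvs)
  best <- results[[bestIdx]]
  fit <- fitPLS(X[, best@selected, drop = FALSE], y, A = best@ncomp)
  structure(list(frequencies = freqs,
                 frequent = frequentVariables(freqs, threshold),
                 threshold = threshold,
                 bestRun = bestIdx,
                 bestRmsecv = best@rmsecv,
                 bestModel = fit,
                 coefficients = stdCoefficients(fit),
                 nRuns = length(results)),
            class = "ImportanceReport")
}

#' @export
print.ImportanceReport <- function(x, ...) {
  cat(sprintf(
    "ImportanceReport over %d BOSS run(s); best run %d (RMSECV %.4f)\n",
    x$nRuns, x$bestRun, x$bestRmsecv))
  cat(sprintf("%d variable(s) with selection frequency > %d%%:\n",
              length(x$frequent), round(100 * x$threshold)))
  for (v in x$frequent) {
    b <- if (v %in% names(x$coefficients)) sprintf("% .4f", x$coefficients[v])
         else "   --  "
    cat(sprintf("  %-16s freq %4.0f%%  coef %s\n", v,
                100 * x$frequencies[v], b))
  }
  invisible(x)
}

#' Importance report as a table
#'
#' @param x An \code{ImportanceReport}.
#' @param all Include variables never selected (default FALSE).
#' @return data.frame with columns \code{variable}, \code{frequency},
#'   \code{coefficient} (NA for variables outside the best model), sorted by
#'   descending frequency then |coefficient|.
#' @export
importanceTable <- function(x, all = FALSE) {
  stopifnot(inherits(x, "ImportanceReport"))
  f <- x$frequencies
  if (!all) f <- f[f > 0]
  b <- x$coefficients[names(f)]
  names(b) <- names(f)
  df <- data.frame(variable = names(f), frequency = unname(f),
                   coefficient = unname(b), stringsAsFactors = FALSE)
  df <- df[order(-df$frequency, -abs(ifelse(is.na(df$coefficient), 0,
                                            df$coefficient)),
                 df$variable), ]
  rownames(df) <- NULL
  df
}

#' Write / read an importance report
#'
#' JSON serialization with 17 significant digits, so numeric values
#' round-trip bit-exactly.
#'
#' @param x An \code{ImportanceReport}.
#' @param path Output path.
#' @return \code{path} invisibly; \code{readImportanceReport} returns the
#'   report (without the refitted model object).
#' @export
writeImportanceReport <- function(x, path) {
  stopifnot(inherits(x, "ImportanceReport"))
  obj <- list(n_runs = x$nRuns, threshold = x$threshold,
              best_run = x$bestRun, best_rmsecv = x$bestRmsecv,
              frequencies = as.list(x$frequencies),
              frequent = x$frequent,
              coefficients = as.list(x$coefficients))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname writeImportanceReport
#' @export
readImportanceReport <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(frequencies = unlist(obj$frequencies),
                 frequent = as.character(obj$frequent),
                 threshold = obj$threshold,
                 bestRun = obj$best_run,
                 bestRmsecv = obj$best_rmsecv,
                 bestModel = NULL,
                 coefficients = unlist(obj$coefficients),
                 nRuns = obj$n_runs),
            class = "ImportanceReport")
}

#' Bar chart of variable importance
#'
#' Two-panel display in the style of the repeated-run analysis: selection
#' frequencies of the frequent variables, and the standardized regression
#' coefficients of the best model.
#'
#' @param x An \code{ImportanceReport}.
#' @param ... Passed to \code{barplot}.
#' @return Invisibly, the plotted table.
#' @export
plotImportance <- function(x, ...) {
  stopifnot(inherits(x, "ImportanceReport"))
  old <- graphics::par(mfrow = c(2L, 1L), mar = c(7, 4, 2, 1))
  on.exit(graphics::par(old))
  f <- x$frequencies[x$frequent]
  if (length(f))
    graphics::barplot(100 * f, las = 2, ylab = "selection frequency (%)",
                      main = sprintf("frequency > %d%% over %d runs",
                                     round(100 * x$threshold), x$nRuns), ...)
  b <- sort(x$coefficients)
  graphics::barplot(b, las = 2, ylab = "standardized coefficient",
                    main = "best model (lowest RMSECV)", ...)
  invisible(list(frequencies = f, coefficients = b))
}
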