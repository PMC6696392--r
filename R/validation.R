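# K-fold cross-validation producing RMSECV and Q2.

#' Random K-fold assignment
#'
#' Uniform unstratified split: a random permutation of samples is divided
#' into K folds whose sizes differ by at most one. Deterministic for a seed.
#'
#' @param n Number of samples.
#' @param K Number of folds (default 5), K <= n.
#' @param seed Integer seed.
#' @return Integer vector of fold labels in 1..K.
#' @examples
#' table(kfoldSplit(48, 5, seed = 1))  # sizes 10,10,10,9,9
#' @export
kfoldSplit <- function(n, K = 5L, seed) {
  n <- as.integer(n); K <- as.integer(K)
  if (K > n) stop(sprintf("K = %d folds but only n = %d samples", K, n))
  if (K < 2L) stop("K must be >= 2")
  withSeed(seed, sample(rep_len(seq_len(K), n)))
}

#' Cross-validate a PLS model
#'
#' For each fold: autoscaling is fit on the training portion only (default;
#' \code{scaleMode = "global"} reproduces the variant where scaling
#' parameters come from the full dataset), a PLS model with A components is
#' fit, and the held-out samples are predicted on the raw activity scale.
#' Held-out predictions are pooled over folds, then
#' RMSECV = sqrt(mean((y - yhat)^2)) and Q2 = 1 - SSres/SStot with SStot
#' about the observed mean of y — so a model predicting the mean gets
#' exactly Q2 = 0.
#'
#' @param X n x p numeric matrix.
#' @param y Response (activity) vector.
#' @param folds Integer fold labels from \code{\link{kfoldSplit}}.
#' @param A Number of PLS components; clamped to what the smallest training
#'   fold supports.
#' @param scaleMode \code{"per_fold"} (default) or \code{"global"}.
#' @return List with \code{rmsecv}, \code{q2}, \code{predictions} (held-out,
#'   raw scale, in sample order), \code{A}.
#' @export
crossValidate <- function(X, y, folds, A,
                          scaleMode = c("per_fold", "global")) {
  scaleMode <- match.arg(scaleMode)
  X <- as.matrix(X)
  folds <- as.integer(folds)
  if (length(folds) != nrow(X)) stop("fold labels length must equal nrow(X)")
  A <- .clampAmax(A, X, folds)
  preds <- cpp_cv_prediction_path(X, as.numeric(y), folds, A,
                                  scaleMode == "per_fold")[, A]
  list(rmsecv = rmse(y, preds), q2 = rSquared(y, preds),
       predictions = preds, A = A)
}

#' Write a cross-validation report
#'
#' @param cv Result of \code{\link{crossValidate}}.
#' @param path Output JSON path.
#' @param seed Fold seed to record (optional).
#' @return \code{path}, invisibly.
#' @export
writeCVReport <- function(cv, path, seed = NULL) {
  obj <- list(rmsecv = cv$rmsecv, q2 = cv$q2, A = cv$A,
              fold_seed = seed, predictions = unname(cv$predictions))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
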