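# PLS1 regression engine: autoscaling, NIPALS fit, component selection by
# cross-validated Q2, fit statistics and standardized coefficients.
#
# Modelling convention throughout: X columns and y are autoscaled (centred,
# unit sample variance) before fitting, so the regression vector on the
# scaled scale IS the vector of standardized coefficients used for variable
# importance. Raw-scale predictions are reconstructed through the scaler.

#' Fit an autoscaler
#'
#' Column means and sample (n-1) standard deviations for X and y. Columns
#' with zero variance are flagged and given sd 1, so their scaled values are
#' exactly 0 and they receive a zero regression coefficient; bootstrap
#' subsets of nearly-categorical descriptor columns can be constant, so this
#' is a routine case, not an error.
#'
#' @param X n x p numeric matrix, n >= 2.
#' @param y Optional response vector.
#' @return List with \code{xMeans}, \code{xSds}, \code{constant} (logical
#'   zero-variance flags), and when y is given \code{yMean}, \code{ySd}.
#' @export
fitScaler <- function(X, y = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("autoscaling needs at least 2 samples")
  mu <- colMeans(X)
  sds <- apply(X, 2L, sd)
  constant <- sds < 1e-12
  sds[constant] <- 1
  sc <- list(xMeans = mu, xSds = sds, constant = constant)
  if (!is.null(y)) {
    sc$yMean <- mean(y)
    sc$ySd <- sd(y)
    if (sc$ySd < 1e-12) sc$ySd <- 1
  }
  sc
}

#' Apply / invert an autoscaler
#'
#' @param scaler A scaler from \code{\link{fitScaler}}.
#' @param X Matrix to scale (columns matching the fitted X).
#' @param y Optional response vector to scale.
#' @return \code{scaleData}: list with scaled \code{X} (and \code{y});
#'   \code{unscaleY}: raw-scale response.
#' @export
scaleData <- function(scaler, X, y = NULL) {
  Xs <- sweep(sweep(as.matrix(X), 2L, scaler$xMeans, "-"),
              2L, scaler$xSds, "/")
  out <- list(X = Xs)
  if (!is.null(y)) out$y <- (y - scaler$yMean) / scaler$ySd
  out
}

#' @rdname scaleData
#' @param ys Scaled response values.
#' @export
unscaleY <- function(scaler, ys) scaler$yMean + scaler$ySd * ys

#' Fit a PLS1 regression model
#'
#' Single-response NIPALS partial least squares. With one response the
#' algorithm is closed-form per component (weight vector proportional to
#' X'y), hence fully deterministic. Data are autoscaled internally; the
#' stored coefficient path is on the autoscaled scale for every component
#' count 1..A, so \code{\link{stdCoefficients}} is a direct lookup.
#'
#' @param X n x p numeric matrix (colnames become variable IDs).
#' @param y Response vector, length n.
#' @param A Number of latent components, 1 <= A <= min(n-1, p). If the
#'   response is exhausted earlier (rank deficiency), the effective number of
#'   informative components is smaller and later coefficient columns repeat
#'   the last informative one.
#' @return A \linkS4class{PLSModel}.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40), 10, 4)
#' y <- X[, 1] - 2 * X[, 3] + rnorm(10, sd = 0.1)
#' m <- fitPLS(X, y, A = 2)
#' rSquared(y, predict(m, X))
#' @export
fitPLS <- function(X, y, A) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  A <- as.integer(A)
  if (A < 1L || A > min(n - 1L, p))
    stop(sprintf("A must be in 1..min(n-1, p) = 1..%d", min(n - 1L, p)))
  vars <- colnames(X)
  if (is.null(vars)) vars <- paste0("V", seq_len(p))

  scaler <- fitScaler(X, y)
  sc <- scaleData(scaler, X, y)
  Xs <- sc$X; ys <- sc$y

  W <- P <- matrix(0, p, A)
  q <- numeric(A)
  B <- matrix(0, p, A, dimnames = list(vars, NULL))
  aEff <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xs, ys))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- drop(Xs %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pl <- drop(crossprod(Xs, t)) / tt
    ql <- sum(ys * t) / tt
    Xs <- Xs - tcrossprod(t, pl)
    ys <- ys - ql * t
    W[, a] <- w; P[, a] <- pl; q[a] <- ql
    aEff <- a
    PtW <- crossprod(P[, seq_len(a), drop = FALSE],
                     W[, seq_len(a), drop = FALSE])
    B[, a] <- W[, seq_len(a), drop = FALSE] %*%
      backsolve(PtW, q[seq_len(a)])
  }
  if (aEff > 0L && aEff < A)
    for (a in seq((aEff + 1L), A)) B[, a] <- B[, aEff]

  new("PLSModel", ncomp = A, weights = W, loadings = P, yloadings = q,
      coefPath = B, scaler = scaler, variables = vars)
}

#' Predict from a PLSModel
#'
#' @param object A \linkS4class{PLSModel}.
#' @param newdata n x p matrix on the raw (unscaled) variable scale, columns
#'   in the model's variable order.
#' @param ncomp Component count to predict with (defaults to the fitted A).
#' @param ... Ignored.
#' @return Raw-scale predicted activities.
#' @export
setMethod("predict", "PLSModel", function(object, newdata,
                                          ncomp = object@ncomp, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object@variables))
    stop("newdata column count does not match the model")
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > ncol(object@coefPath))
    stop("ncomp out of fitted range")
  Xs <- scaleData(object@scaler, newdata)$X
  unscaleY(object@scaler, drop(Xs %*% object@coefPath[, ncomp]))
})

#' Standardized regression coefficients
#'
#' Coefficients of the fitted model expressed on autoscaled X and y. Because
#' the unit scale of each variable is divided out, their absolute values are
#' comparable across descriptor sets and quantify variable importance: the
#' larger |coefficient|, the more important the variable; the sign gives the
#' direction of the effect on bitterness activity.
#'
#' @param model A \linkS4class{PLSModel}.
#' @param ncomp Component count (defaults to the fitted A).
#' @return Named numeric p-vector.
#' @export
stdCoefficients <- function(model, ncomp = model@ncomp) {
  stopifnot(is(model, "PLSModel"))
  b <- model@coefPath[, as.integer(ncomp)]
  names(b) <- model@variables
  b
}

#' Root mean square error
#'
#' @param y Observed values.
#' @param yhat Predicted values, same length.
#' @return sqrt(mean((y - yhat)^2)).
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat lengths differ")
  if (length(y) < 1L) stop("empty input")
  sqrt(mean((y - yhat)^2))
}

#' Coefficient of determination
#'
#' 1 - SSres/SStot with SStot about the observed mean of \code{y}. Applied to
#' training predictions this is R2; applied to held-out cross-validation
#' predictions it is Q2.
#'
#' @param y Observed values (must not be constant).
#' @param yhat Predicted values.
#' @return Numeric in (-Inf, 1].
#' @export
rSquared <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat lengths differ")
  sst <- sum((y - mean(y))^2)
  if (sst < 1e-24) stop("y is constant; R2 undefined")
  1 - sum((y - yhat)^2) / sst
}

#' Select the number of PLS components by cross-validated Q2
#'
#' Computes held-out predictions for every component count 1..Amax under the
#' given fold assignment and returns the count maximizing Q2; ties go to the
#' smaller count (parsimony).
#'
#' @param X n x p matrix.
#' @param y Response vector.
#' @param folds Integer fold labels 1..K (see \code{\link{kfoldSplit}}).
#' @param Amax Largest component count to consider; default
#'   \code{min(10, n - 1, p)} capped at what the smallest training fold
#'   supports.
#' @param scaleMode \code{"per_fold"} (autoscaling refit inside each training
#'   fold; default) or \code{"global"} (parameters from the full data).
#' @return List with \code{A} (selected count), \code{q2} (Q2 at each
#'   candidate count), \code{predictions} (n x Amax held-out prediction
#'   matrix, raw scale).
#' @export
selectComponents <- function(X, y, folds, Amax = NULL,
                             scaleMode = c("per_fold", "global")) {
  scaleMode <- match.arg(scaleMode)
  X <- as.matrix(X)
  Amax <- .clampAmax(Amax, X, folds)
  preds <- cpp_cv_prediction_path(X, as.numeric(y), as.integer(folds),
                                  Amax, scaleMode == "per_fold")
  q2 <- apply(preds, 2L, function(yh) rSquared(y, yh))
  list(A = which.max(q2), q2 = q2, predictions = preds)
}

#' Serialize a PLSModel to JSON
#'
#' Stores the component count, variable IDs, standardized and coefficient-path
#' values and the scaler, enough to reconstruct predictions.
#'
#' @param model A \linkS4class{PLSModel}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writePLSModel <- function(model, path) {
  stopifnot(is(model, "PLSModel"))
  obj <- list(ncomp = model@ncomp,
              variables = model@variables,
              coefPath = apply(model@coefPath, 2L, identity, simplify = FALSE),
              scaler = model@scaler)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname writePLSModel
#' @export
readPLSModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  # array-of-arrays simplifies to a component x variable matrix (or to a
  # list when component counts differ); normalize to p x A
  B <- if (is.matrix(obj$coefPath)) t(obj$coefPath)
       else do.call(cbind, obj$coefPath)
  rownames(B) <- obj$variables
  scaler <- obj$scaler
  scaler$constant <- as.logical(scaler$constant)
  A <- as.integer(obj$ncomp)
  new("PLSModel", ncomp = A,
      weights = matrix(NA_real_, nrow(B), 0L),
      loadings = matrix(NA_real_, nrow(B), 0L),
      yloadings = numeric(0),
      coefPath = B, scaler = scaler, variables = obj$variables)
}

# Largest A supported by data and fold structure.
.clampAmax <- function(Amax, X, folds) {
  n <- nrow(X); p <- ncol(X)
  minTrain <- n - max(tabulate(as.integer(folds)))
  cap <- max(1L, min(n - 1L, p, minTrain - 1L))
  if (is.null(Amax)) Amax <- min(10L, cap)
  as.integer(max(1L, min(Amax, cap)))
}
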