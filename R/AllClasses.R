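#' @import methods
#' @importFrom stats predict rnorm sd var cor median coef lm setNames quantile
#' @importFrom utils read.table write.table head modifyList
#' @useDynLib peptideBOSS, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' The 20 coded amino acids
#'
#' One-letter codes of the 20 proteinogenic amino acids covered by every
#' descriptor scale in the registry. Ambiguity/rare codes (B, J, O, U, X, Z)
#' are rejected throughout because no published scale assigns them values.
#'
#' @format Character vector of length 20, alphabetical by one-letter code.
#' @export
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' DescriptorSet: one amino-acid descriptor scale
#'
#' A named table assigning each of the 20 coded amino acids a fixed-length
#' numeric vector of physicochemical parameters (e.g. the 3 z-scales, the 8
#' VHSE components, the 12 HESH components). The parameter number is the
#' 1-based column position, which is how variables are later named
#' (\code{N1-3z-1} is parameter 1 of set \code{3z} at the N-terminal residue).
#'
#' @slot name Short identifier, e.g. \code{"3z"}, \code{"VHSE"}.
#' @slot values 20 x k numeric matrix; rownames are the amino-acid one-letter
#'   codes, colnames \code{p1..pk}.
#' @slot provenance Free-text citation for the scale's source.
#'
#' @aliases DescriptorSet-class
#' @exportClass DescriptorSet
setClass("DescriptorSet",
  representation(name = "character", values = "matrix",
                 provenance = "character"))

setValidity("DescriptorSet", function(object) {
  v <- object@values
  if (length(object@name) != 1L || !nzchar(object@name))
    return("'name' must be a single non-empty string")
  if (!is.numeric(v))
    return("'values' must be numeric")
  if (nrow(v) != 20L)
    return(sprintf("expected 20 amino-acid rows, found %d", nrow(v)))
  if (ncol(v) < 1L)
    return("descriptor set must have at least one parameter column")
  rn <- rownames(v)
  if (is.null(rn) || !setequal(rn, AMINO_ACIDS)) {
    missing <- setdiff(AMINO_ACIDS, rn)
    extra <- setdiff(rn, AMINO_ACIDS)
    msg <- character(0)
    if (length(missing))
      msg <- c(msg, paste0("missing residue(s): ",
                           paste(missing, collapse = ", ")))
    if (length(extra))
      msg <- c(msg, paste0("invalid residue(s): ",
                           paste(extra, collapse = ", ")))
    return(paste(msg, collapse = "; "))
  }
  if (anyDuplicated(rn))
    return(paste0("duplicate residue: ", rn[duplicated(rn)][1L]))
  if (anyNA(v)) {
    idx <- which(is.na(v), arr.ind = TRUE)[1L, ]
    return(sprintf("missing value at residue '%s', parameter %d",
                   rownames(v)[idx[1L]], idx[2L]))
  }
  TRUE
})

#' ScaleRegistry: an ordered collection of descriptor sets
#'
#' Holds the active descriptor sets in a fixed order; encoding concatenates
#' them position-wise, so registry order determines column order of the
#' design matrix. With all 14 canonical sets active the total dimension is
#' 87 parameters per residue position.
#'
#' @slot sets List of \linkS4class{DescriptorSet}, names matching set names.
#'
#' @aliases ScaleRegistry-class
#' @exportClass ScaleRegistry
setClass("ScaleRegistry", representation(sets = "list"))

setValidity("ScaleRegistry", function(object) {
  if (length(object@sets) == 0L)
    return("registry must contain at least one descriptor set")
  if (!all(vapply(object@sets, is, logical(1), "DescriptorSet")))
    return("all elements of 'sets' must be DescriptorSet objects")
  nm <- vapply(object@sets, function(s) s@name, character(1),
               USE.NAMES = FALSE)
  if (anyDuplicated(nm))
    return(paste0("duplicate set name: ", nm[duplicated(nm)][1L]))
  if (!identical(names(object@sets), nm))
    return("list names must equal the set names")
  TRUE
})

#' PLSModel: a fitted PLS1 regression model
#'
#' Partial least squares regression with a single response, fitted on
#' autoscaled data. Coefficients are stored on the autoscaled scale for every
#' component count 1..A (column \code{a} of \code{coefPath}); the standardized
#' regression coefficients of the model are the column at the chosen A.
#' Predictions on the raw scale are reconstructed through the stored scaler.
#'
#' @slot ncomp Number of latent components A actually used.
#' @slot weights p x A X-weight matrix (NIPALS W).
#' @slot loadings p x A X-loading matrix (P).
#' @slot yloadings Length-A y-loading vector (q).
#' @slot coefPath p x A matrix; column a holds the autoscaled-scale
#'   regression vector of the a-component model.
#' @slot scaler List with xMeans, xSds, yMean, ySd, constant (zero-variance
#'   column flags).
#' @slot variables Character vector of variable IDs (column names of X).
#'
#' @aliases PLSModel-class
#' @exportClass PLSModel
setClass("PLSModel",
  representation(ncomp = "integer", weights = "matrix", loadings = "matrix",
                 yloadings = "numeric", coefPath = "matrix", scaler = "list",
                 variables = "character"))

setValidity("PLSModel", function(object) {
  A <- object@ncomp
  if (A < 1L) return("ncomp must be >= 1")
  if (ncol(object@coefPath) < A) return("coefPath has fewer columns than ncomp")
  if (nrow(object@coefPath) != length(object@variables))
    return("coefPath rows must match number of variables")
  TRUE
})

#' BOSSResult: outcome of one bootstrapping-soft-shrinkage run
#'
#' @slot selected Character vector of selected variable IDs (the subset with
#'   the smallest RMSECV over all iterations).
#' @slot rmsecv RMSECV of the winning subset.
#' @slot ncomp Components used by the winning submodel.
#' @slot trace data.frame with one row per iteration: pool size, minimum and
#'   median RMSECV among the bootstrap submodels, number of unique variables
#'   in the extracted best models, and weight entropy.
#' @slot weightsTrace List of per-iteration named weight vectors (probability
#'   vectors over the current pool).
#' @slot folds Integer fold labels shared by all submodels of the run.
#' @slot seed Seed the run was started from.
#' @slot converged FALSE when the iteration cap stopped the shrinkage before
#'   the pool reached one variable.
#'
#' @aliases BOSSResult-class
#' @exportClass BOSSResult
setClass("BOSSResult",
  representation(selected = "character", rmsecv = "numeric",
                 ncomp = "integer", trace = "data.frame",
                 weightsTrace = "list", folds = "integer", seed = "integer",
                 converged = "logical"))

setValidity("BOSSResult", function(object) {
  if (length(object@selected) == 0L)
    return("selected variable set must be non-empty")
  if (object@rmsecv < 0) return("rmsecv must be non-negative")
  TRUE
})

setMethod("show", "DescriptorSet", function(object) {
  cat(sprintf("DescriptorSet '%s': %d parameters for 20 amino acids\n",
              object@name, ncol(object@values)))
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "ScaleRegistry", function(object) {
  dims <- vapply(object@sets, function(s) ncol(s@values), integer(1))
  cat(sprintf("ScaleRegistry with %d descriptor set(s), total dimension %d\n",
              length(object@sets), sum(dims)))
  cat(" ", paste(sprintf("%s(%d)", names(dims), dims), collapse = " "), "\n")
})

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d latent component(s), %d variable(s)\n",
              object@ncomp, length(object@variables)))
  b <- object@coefPath[, object@ncomp]
  top <- order(abs(b), decreasing = TRUE)[seq_len(min(5L, length(b)))]
  cat("  largest |standardized coefficient|:\n")
  for (j in top)
    cat(sprintf("    %s  % .4f\n", object@variables[j], b[j]))
})

setMethod("show", "BOSSResult", function(object) {
  cat(sprintf(
    "BOSSResult: %d variable(s) selected, RMSECV %.4f (A = %d, %d iterations)\n",
    length(object@selected), object@rmsecv, object@ncomp, nrow(object@trace)))
  cat("  ", paste(object@selected, collapse = ", "), "\n")
})
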