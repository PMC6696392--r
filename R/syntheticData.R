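# Synthetic bitter-peptide datasets with known sparse signal.
#
# The generator emulates the structure the analysis assumes: random peptide
# sequences of one length, descriptor encoding through a registry, and an
# activity that is a sparse linear function of a few encoded (standardized)
# variables plus Gaussian noise, back-transformed to taste thresholds. The
# planted truth is recorded so selection methods can be scored for recovery.

#' Random peptide sequences
#'
#' Uniform draws over the 20 coded amino acids; duplicates are allowed (real
#' bitterness datasets contain near-duplicates such as GGV/GVV).
#' Deterministic for a seed.
#'
#' @param n Number of peptides.
#' @param length Peptide length.
#' @param seed Integer seed.
#' @return Character vector of n sequences.
#' @export
generateSequences <- function(n, length, seed) {
  stopifnot(n >= 1L, length >= 1L)
  withSeed(seed, {
    vapply(seq_len(n), function(i)
      paste(sample(AMINO_ACIDS, length, replace = TRUE), collapse = ""),
      character(1))
  })
}

#' Simulation specification for a synthetic dataset
#'
#' @param nPeptides Number of peptides (the bitterness datasets have 48, 52
#'   and 23 for lengths 2, 3 and 4).
#' @param peptideLength Residues per peptide (2-4 in the reference datasets;
#'   any length >= 1 is accepted).
#' @param registry \linkS4class{ScaleRegistry} used for encoding (real or
#'   \code{\link{syntheticScales}}).
#' @param signalVariables Variable IDs carrying true signal (must exist in
#'   the encoded space for this registry and length).
#' @param effectSizes Effect size per signal variable, on the standardized
#'   column scale.
#' @param noiseSd Gaussian noise SD added to the activity.
#' @param thresholdRange Plausible molar range the back-transformed
#'   thresholds are clipped to; default 1e-5 to 1 M (the source thresholds
#'   are mM-scale).
#' @param seed Integer seed.
#' @return List of class \code{SimulationSpec}.
#' @export
simulationSpec <- function(nPeptides, peptideLength, registry,
                           signalVariables, effectSizes, noiseSd,
                           thresholdRange = c(1e-5, 1), seed) {
  stopifnot(is(registry, "ScaleRegistry"),
            length(signalVariables) == length(effectSizes),
            noiseSd >= 0, nPeptides >= 2L)
  ids <- variableIds(peptideLength, registry)
  missing <- setdiff(signalVariables, ids)
  if (length(missing))
    stop(sprintf("signal variable '%s' does not exist in the encoded space",
                 missing[1L]))
  structure(list(nPeptides = as.integer(nPeptides),
                 peptideLength = as.integer(peptideLength),
                 registry = registry,
                 signalVariables = as.character(signalVariables),
                 effectSizes = as.numeric(effectSizes),
                 noiseSd = noiseSd,
                 thresholdRange = thresholdRange,
                 seed = as.integer(seed)),
            class = "SimulationSpec")
}

#' Generate a synthetic peptide dataset
#'
#' Sequences are drawn uniformly, encoded through the registry, and columns
#' standardized; the activity is
#' \code{y = Xs[, signal] \%*\% effects + N(0, noiseSd)}. Effects act on
#' standardized columns so effect sizes are comparable across descriptor
#' sets of different scales, mirroring the pipeline's autoscaling.
#' Thresholds are \code{10^(-y)} clipped to the plausible molar range (the
#' peptide table's activity column is recomputed from the clipped threshold,
#' so it can differ from \code{y} for extreme draws). Bit-reproducible from
#' the simulation spec's seed.
#'
#' @param spec A \code{\link{simulationSpec}}.
#' @return List of class \code{SyntheticDataset}: \code{peptides}
#'   (data.frame sequence/threshold_M/activity), \code{X} (raw encoded
#'   design matrix), \code{y} (activity vector as generated, before
#'   clipping), \code{truth} (the simulation spec, plus the signal column
#'   indices).
#' @examples
#' reg <- syntheticScales(c(3, 2), seed = 1)
#' spec <- simulationSpec(30, 2, reg, signalVariables = c("N1-S1-1"),
#'                        effectSizes = 1, noiseSd = 0.1, seed = 42)
#' d <- generateDataset(spec)
#' dim(d$X)  # 30 x 10
#' @export
generateDataset <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  seeds <- deriveSeeds(spec$seed, 2L)
  seqs <- generateSequences(spec$nPeptides, spec$peptideLength, seeds[1L])
  enc <- encodeDataset(data.frame(sequence = seqs, stringsAsFactors = FALSE),
                       spec$registry)
  X <- enc$X
  sigIdx <- match(spec$signalVariables, colnames(X))
  Xs <- scaleData(fitScaler(X), X)$X
  withSeed(seeds[2L], {
    signal <- if (length(sigIdx))
      drop(Xs[, sigIdx, drop = FALSE] %*% spec$effectSizes)
    else rep(0, nrow(X))
    y <- signal + rnorm(nrow(X), sd = spec$noiseSd)
  })
  thr <- pmin(pmax(thresholdFromActivity(y), spec$thresholdRange[1L]),
              spec$thresholdRange[2L])
  peptides <- data.frame(sequence = seqs, threshold_M = thr,
                         activity = activityFromThreshold(thr),
                         stringsAsFactors = FALSE)
  structure(list(peptides = peptides, X = X, y = unname(y),
                 truth = c(spec, list(signalIndex = sigIdx))),
            class = "SyntheticDataset")
}

#' Write a synthetic dataset
#'
#' Emits the standard peptide table plus a \code{truth.json} sidecar with
#' the planted signal (variable IDs, effect sizes, noise SD, seed).
#'
#' @param dataset A \code{SyntheticDataset}.
#' @param dir Output directory (created if needed).
#' @return Directory path, invisibly.
#' @export
writeSyntheticDataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "SyntheticDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writePeptideTable(dataset$peptides, file.path(dir, "peptides.csv"))
  tr <- dataset$truth
  jsonlite::write_json(
    list(n_peptides = tr$nPeptides, peptide_length = tr$peptideLength,
         signal_variables = tr$signalVariables,
         effect_sizes = tr$effectSizes, noise_sd = tr$noiseSd,
         threshold_range = tr$thresholdRange, seed = tr$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = I(17))
  invisible(dir)
}
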