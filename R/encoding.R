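# Position-wise descriptor encoding of peptide sequences.
#
# Each residue position contributes one block of columns per active
# descriptor set; with the canonical 14-set registry (87 parameters per
# position) a dipeptide maps to 174 variables, a tripeptide to 261, a
# tetrapeptide to 348. Variable IDs follow the
# "N{position}-{set}-{parameter}" convention (N1 = N-terminus), e.g.
# N1-3z-1 is the first 3z-scale parameter of the N-terminal residue.

#' Bitterness activity from a taste threshold
#'
#' Bitterness activity is defined as log10(1/T) where T is the bitter-taste
#' threshold concentration in molar units: the lower the threshold, the more
#' bitter the peptide and the higher the activity.
#'
#' @param thresholdM Positive threshold concentration(s), molar.
#' @return Numeric activity value(s).
#' @examples
#' activityFromThreshold(0.019)  # dipeptide AF at 19 mM -> 1.7212
#' @export
activityFromThreshold <- function(thresholdM) {
  if (any(!is.finite(thresholdM)) || any(thresholdM <= 0))
    stop("threshold concentrations must be positive and finite")
  -log10(thresholdM)
}

#' @describeIn activityFromThreshold Inverse transform: threshold (M) from
#'   activity.
#' @param activity Numeric activity value(s).
#' @export
thresholdFromActivity <- function(activity) 10^(-activity)

#' Canonical variable IDs for a peptide length and registry
#'
#' Enumerates the encoded design-matrix columns in position-major order:
#' position 1..L, within a position the registry's set order, within a set
#' the 1-based parameter order.
#'
#' @param length Peptide length (number of residues).
#' @param registry A \linkS4class{ScaleRegistry}.
#' @return Character vector of \code{N{pos}-{set}-{param}} IDs, one per
#'   design-matrix column.
#' @export
variableIds <- function(length, registry) {
  stopifnot(is(registry, "ScaleRegistry"), length >= 1L)
  unlist(lapply(seq_len(length), function(pos) {
    unlist(lapply(registry@sets, function(s)
      sprintf("N%d-%s-%d", pos, s@name, seq_len(descriptorDim(s)))),
      use.names = FALSE)
  }), use.names = FALSE)
}

#' Parse variable IDs into their components
#'
#' @param ids Character vector of \code{N{pos}-{set}-{param}} IDs.
#' @return data.frame with columns \code{position}, \code{set},
#'   \code{parameter}.
#' @export
parseVariableIds <- function(ids) {
  m <- regmatches(ids, regexec("^N([0-9]+)-(.+)-([0-9]+)$", ids))
  bad <- lengths(m) != 4L
  if (any(bad))
    stop(sprintf("malformed variable ID '%s'", ids[bad][1L]))
  data.frame(position = as.integer(vapply(m, `[`, "", 2L)),
             set = vapply(m, `[`, "", 3L),
             parameter = as.integer(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' Encode one peptide sequence
#'
#' @param sequence Peptide string of one-letter amino-acid codes (any length
#'   >= 1; the bitterness datasets use lengths 2-4).
#' @param registry A \linkS4class{ScaleRegistry}.
#' @return Named numeric vector of length
#'   \code{nchar(sequence) * totalDimension(registry)}, names being the
#'   variable IDs.
#' @examples
#' reg <- syntheticScales(c(3, 2), seed = 1)
#' length(encodePeptide("AF", reg))  # 2 * 5 = 10
#' @export
encodePeptide <- function(sequence, registry) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            is(registry, "ScaleRegistry"))
  res <- strsplit(toupper(sequence), "")[[1L]]
  if (length(res) < 1L) stop("empty sequence")
  bad <- which(!(res %in% AMINO_ACIDS))
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d of '%s'",
                 res[bad[1L]], bad[1L], sequence))
  v <- unlist(lapply(seq_along(res), function(pos) {
    unlist(lapply(registry@sets, function(s)
      descriptorValues(s)[res[pos], ]), use.names = FALSE)
  }), use.names = FALSE)
  names(v) <- variableIds(length(res), registry)
  v
}

#' Encode a peptide dataset into a design matrix
#'
#' All sequences must have the same length: bitterness models are built per
#' peptide length, so mixed-length input is an error rather than padded.
#'
#' @param peptides data.frame with at least a \code{sequence} column;
#'   an \code{activity} column (or \code{threshold_M}, from which activity is
#'   computed) is carried into the result when present.
#' @param registry A \linkS4class{ScaleRegistry}.
#' @return List with \code{X} (n x p numeric matrix, colnames = variable IDs,
#'   rownames = sequences made unique) and \code{y} (activity vector, or NULL
#'   when no activity/threshold column exists).
#' @examples
#' reg <- syntheticScales(c(3, 2), seed = 1)
#' d <- data.frame(sequence = c("AF", "GL"), threshold_M = c(0.019, 0.021))
#' dim(encodeDataset(d, reg)$X)  # 2 x 10
#' @export
encodeDataset <- function(peptides, registry) {
  stopifnot(is.data.frame(peptides), nrow(peptides) >= 1L,
            "sequence" %in% names(peptides))
  seqs <- as.character(peptides$sequence)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop(sprintf(
      "mixed peptide lengths (%s): models are length-specific, encode each length separately",
      paste(sort(unique(lens)), collapse = ", ")))
  X <- t(vapply(seqs, encodePeptide, numeric(lens[1L] * totalDimension(registry)),
                registry = registry))
  rownames(X) <- make.unique(seqs)
  y <- NULL
  if ("activity" %in% names(peptides)) {
    y <- as.numeric(peptides$activity)
  } else if ("threshold_M" %in% names(peptides)) {
    y <- activityFromThreshold(as.numeric(peptides$threshold_M))
  }
  if (!is.null(y)) names(y) <- rownames(X)
  list(X = X, y = y)
}

#' Read a peptide table
#'
#' Expected delimited-text format: header \code{sequence,threshold,units}
#' with units \code{M} or \code{mM} (thresholds are normalised to molar), or
#' \code{sequence,threshold_M}, or a pre-computed \code{activity} column.
#'
#' @param path File path (comma- or tab-separated, auto-detected).
#' @return data.frame with columns \code{sequence}, \code{threshold_M},
#'   \code{activity}.
#' @export
readPeptideTable <- function(path) {
  sep <- .sniffSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!"sequence" %in% names(df))
    stop(sprintf("'%s': missing 'sequence' column", path))
  df$sequence <- toupper(trimws(df$sequence))
  if ("threshold" %in% names(df)) {
    units <- if ("units" %in% names(df)) tolower(trimws(df$units)) else "m"
    bad <- setdiff(unique(units), c("m", "mm"))
    if (length(bad))
      stop(sprintf("'%s': unknown units '%s' (use 'M' or 'mM')", path, bad[1L]))
    df$threshold_M <- as.numeric(df$threshold) * ifelse(units == "mm", 1e-3, 1)
  }
  if (!"threshold_M" %in% names(df) && !"activity" %in% names(df))
    stop(sprintf("'%s': need a 'threshold' (+units), 'threshold_M' or 'activity' column",
                 path))
  if (!"activity" %in% names(df))
    df$activity <- activityFromThreshold(df$threshold_M)
  if (!"threshold_M" %in% names(df))
    df$threshold_M <- thresholdFromActivity(df$activity)
  df[, c("sequence", "threshold_M", "activity")]
}

#' Write a peptide table
#'
#' Emits \code{sequence,threshold,units,activity} with thresholds in molar
#' units at full precision, readable back by \code{\link{readPeptideTable}}.
#'
#' @param peptides data.frame with \code{sequence} and \code{threshold_M}
#'   (activity recomputed if absent).
#' @param path Output path; \code{.tsv} selects tab separation.
#' @return \code{path}, invisibly.
#' @export
writePeptideTable <- function(peptides, path) {
  stopifnot(all(c("sequence", "threshold_M") %in% names(peptides)))
  act <- if ("activity" %in% names(peptides)) peptides$activity
         else activityFromThreshold(peptides$threshold_M)
  out <- data.frame(sequence = peptides$sequence,
                    threshold = sprintf("%.17g", peptides$threshold_M),
                    units = "M",
                    activity = sprintf("%.17g", act),
                    stringsAsFactors = FALSE)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
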