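# Registry of amino-acid descriptor scales.
#
# The canonical integrated-descriptor registry holds 14 published scales with
# dimensions 3, 5, 10, 3, 2, 8, 6, 9, 5, 8, 5, 3, 8, 12 (87 parameters per
# residue in total). Their numeric values are not shipped: they live in the
# cited literature and are loaded from user-supplied delimited tables.
# syntheticScales() provides value-complete stand-in registries for testing.

.CANONICAL_DIMS <- c("3z" = 3L, "5z" = 5L, "DPPS" = 10L, "MS-WHIM" = 3L,
                     "ISA-ECI" = 2L, "VHSE" = 8L, "FASGAI" = 6L, "VSW" = 9L,
                     "T" = 5L, "ST" = 8L, "E" = 5L, "V" = 3L, "G" = 8L,
                     "HESH" = 12L)

# Alternate labels seen in the literature for the same scale.
.SET_ALIASES <- c("MS-WHIM-extended" = "MS-WHIM",
                  "3z-scale" = "3z", "5z-scale" = "5z",
                  "T-scale" = "T", "ST-scale" = "ST",
                  "E-scale" = "E", "G-scale" = "G", "V-scale" = "V")

#' Canonical descriptor-set metadata
#'
#' Names and dimensions of the 14 amino-acid descriptor sets making up the
#' integrated-descriptor space (87 parameters per residue position): the 3
#' and 5 z-scales, DPPS, MS-WHIM (also labelled MS-WHIM-extended), ISA-ECI,
#' VHSE, FASGAI, VSW, the T, ST, E, V and G scales, and HESH.
#'
#' @return data.frame with columns \code{name} and \code{dimension}, in
#'   canonical registry order.
#' @examples
#' sum(canonicalDescriptorSets()$dimension)  # 87
#' @export
canonicalDescriptorSets <- function() {
  data.frame(name = names(.CANONICAL_DIMS),
             dimension = unname(.CANONICAL_DIMS),
             stringsAsFactors = FALSE)
}

#' Resolve a descriptor-set name through known aliases
#'
#' @param name Set label as found in a file or manifest.
#' @return Canonical name if \code{name} is a known alias, otherwise
#'   \code{name} unchanged.
#' @export
resolveSetName <- function(name) {
  if (name %in% names(.SET_ALIASES)) unname(.SET_ALIASES[[name]]) else name
}

#' Construct a DescriptorSet
#'
#' @param name Short set identifier (aliases such as \code{"MS-WHIM-extended"}
#'   are resolved to their canonical name).
#' @param values 20 x k numeric matrix with amino-acid one-letter codes as
#'   rownames. Rows are stored in the canonical residue order.
#' @param provenance Citation string for the scale's source.
#' @return A validated \linkS4class{DescriptorSet}.
#' @export
DescriptorSet <- function(name, values, provenance = "") {
  name <- resolveSetName(name)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    colnames(values) <- paste0("p", seq_len(ncol(values)))
  obj <- new("DescriptorSet", name = name, values = values,
             provenance = provenance)
  # canonical residue order so identical sets compare identical
  obj@values <- obj@values[AMINO_ACIDS, , drop = FALSE]
  if (name %in% names(.CANONICAL_DIMS) &&
      ncol(values) != .CANONICAL_DIMS[[name]])
    stop(sprintf(
      "descriptor set '%s' must have %d parameters, found %d",
      name, .CANONICAL_DIMS[[name]], ncol(values)))
  obj
}

#' @describeIn DescriptorSet Number of parameters (columns) of a set.
#' @param x A \code{DescriptorSet}.
#' @export
descriptorDim <- function(x) {
  stopifnot(is(x, "DescriptorSet"))
  ncol(x@values)
}

#' Descriptor values of a set
#'
#' @param x A \linkS4class{DescriptorSet}.
#' @return The 20 x k numeric value matrix (residues in rows).
#' @export
descriptorValues <- function(x) {
  stopifnot(is(x, "DescriptorSet"))
  x@values
}

#' Read a descriptor scale table from delimited text
#'
#' Expected format: a header row, a \code{residue} column with the 20 coded
#' one-letter amino acids, and k numeric parameter columns. Comma- and
#' tab-separated files are auto-detected. Parameter numbering follows column
#' order (1-based), which is also the numbering used in variable IDs.
#'
#' @param path File path.
#' @param name Set identifier; defaults to the file name without extension.
#' @param expectedDimension If given, the file must have exactly this many
#'   parameter columns.
#' @param provenance Optional citation string.
#' @return A validated \linkS4class{DescriptorSet}.
#' @export
loadDescriptorSet <- function(path, name = NULL, expectedDimension = NULL,
                              provenance = "") {
  if (is.null(name))
    name <- tools::file_path_sans_ext(basename(path))
  sep <- .sniffSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  rescol <- which(tolower(names(df)) == "residue")
  if (length(rescol) != 1L)
    stop(sprintf("'%s': expected exactly one 'residue' column", path))
  res <- toupper(trimws(as.character(df[[rescol]])))
  dup <- res[duplicated(res)]
  if (length(dup))
    stop(sprintf("'%s': duplicate residue '%s'", path, dup[1L]))
  bad <- setdiff(res, AMINO_ACIDS)
  if (length(bad))
    stop(sprintf("'%s': invalid residue '%s' (only the 20 coded amino acids are allowed)",
                 path, bad[1L]))
  missing <- setdiff(AMINO_ACIDS, res)
  if (length(missing))
    stop(sprintf("'%s': missing residue(s): %s", path,
                 paste(missing, collapse = ", ")))
  vals <- df[, -rescol, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(col)) {
      i <- which(is.na(col))[1L]
      stop(sprintf("'%s': non-numeric value '%s' at residue '%s', column '%s'",
                   path, as.character(vals[[j]][i]), res[i], names(vals)[j]))
    }
    vals[[j]] <- col
  }
  m <- as.matrix(vals)
  rownames(m) <- res
  if (!is.null(expectedDimension) && ncol(m) != expectedDimension)
    stop(sprintf("'%s': expected %d parameter columns, found %d",
                 path, expectedDimension, ncol(m)))
  DescriptorSet(name, m, provenance)
}

#' Write a descriptor scale table
#'
#' Inverse of \code{\link{loadDescriptorSet}}: emits a delimited text table
#' with columns \code{residue, p1..pk}. Values are written with 17 significant
#' digits so that a load/write/load cycle is bit-exact.
#'
#' @param set A \linkS4class{DescriptorSet}.
#' @param path Output path; \code{.tsv} extension selects tab separation,
#'   anything else comma.
#' @return \code{path}, invisibly.
#' @export
writeDescriptorSet <- function(set, path) {
  stopifnot(is(set, "DescriptorSet"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  v <- descriptorValues(set)
  df <- data.frame(residue = rownames(v),
                   apply(v, 2L, function(col) sprintf("%.17g", col)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("residue", paste0("p", seq_len(ncol(v))))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a ScaleRegistry
#'
#' @param ... \linkS4class{DescriptorSet} objects, or a single list of them.
#' @return A validated \linkS4class{ScaleRegistry}; set order is preserved and
#'   determines design-matrix column order.
#' @examples
#' reg <- syntheticScales(dims = c(3, 2), seed = 1)
#' totalDimension(reg)  # 5
#' @export
ScaleRegistry <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !is(sets[[1L]], "DescriptorSet"))
    sets <- sets[[1L]]
  names(sets) <- vapply(sets, function(s) s@name, character(1))
  new("ScaleRegistry", sets = sets)
}

#' Total descriptor dimension of a registry
#'
#' Sum of the parameter counts of all active sets; with the 14 canonical sets
#' this is 87, giving design-matrix widths 174/261/348 for peptide lengths
#' 2/3/4.
#'
#' @param registry A \linkS4class{ScaleRegistry}.
#' @return Integer total dimension.
#' @export
totalDimension <- function(registry) {
  stopifnot(is(registry, "ScaleRegistry"))
  sum(vapply(registry@sets, descriptorDim, integer(1)))
}

#' @describeIn ScaleRegistry Names of the active sets, in order.
#' @param registry A \code{ScaleRegistry}.
#' @export
registrySetNames <- function(registry) {
  stopifnot(is(registry, "ScaleRegistry"))
  names(registry@sets)
}

#' Extract a descriptor set from a registry
#'
#' @param registry A \linkS4class{ScaleRegistry}.
#' @param name Set name (aliases resolved) or integer position.
#' @return The \linkS4class{DescriptorSet}.
#' @export
getDescriptorSet <- function(registry, name) {
  stopifnot(is(registry, "ScaleRegistry"))
  if (is.character(name)) name <- resolveSetName(name)
  set <- registry@sets[[name]]
  if (is.null(set))
    stop(sprintf("no descriptor set '%s' in registry", as.character(name)))
  set
}

#' Generate a synthetic scale registry
#'
#' Builds descriptor sets with independent standard-normal parameter values
#' for all 20 residues. These stand-ins have the shape and scaling behaviour
#' of published scales (they are synthetic, carrying no physicochemical
#' meaning) and make the full pipeline runnable without transcribing
#' literature tables. Deterministic for a seed.
#'
#' @param dims Integer vector of set dimensions, e.g.
#'   \code{canonicalDescriptorSets()$dimension} for the full 87-parameter
#'   integrated space.
#' @param seed Integer seed.
#' @param names Optional set names; defaults to \code{S1..Sn}, or the
#'   canonical names when \code{dims} matches the canonical dimensions
#'   exactly.
#' @return A \linkS4class{ScaleRegistry}.
#' @examples
#' reg <- syntheticScales(canonicalDescriptorSets()$dimension, seed = 7)
#' totalDimension(reg)  # 87
#' @export
syntheticScales <- function(dims, seed, names = NULL) {
  stopifnot(length(dims) >= 1L, all(dims >= 1L))
  dims <- as.integer(dims)
  if (is.null(names)) {
    names <- if (identical(dims, unname(.CANONICAL_DIMS)))
      base::names(.CANONICAL_DIMS)
    else paste0("S", seq_along(dims))
  }
  stopifnot(length(names) == length(dims))
  withSeed(seed, {
    sets <- lapply(seq_along(dims), function(i) {
      m <- matrix(rnorm(20L * dims[i]), nrow = 20L,
                  dimnames = list(AMINO_ACIDS, paste0("p", seq_len(dims[i]))))
      DescriptorSet(names[i], m, provenance = "synthetic standard-normal scale")
    })
    ScaleRegistry(sets)
  })
}

#' Read a registry manifest
#'
#' A manifest is a JSON array of objects with fields \code{name},
#' \code{path} (relative paths resolved against the manifest's directory),
#' optional \code{dimension} (validated when present) and \code{provenance}.
#'
#' @param path Manifest file path.
#' @return A \linkS4class{ScaleRegistry}.
#' @export
readRegistryManifest <- function(path) {
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- dirname(normalizePath(path))
  sets <- lapply(entries, function(e) {
    p <- e$path
    if (!file.exists(p)) p <- file.path(base, e$path)
    loadDescriptorSet(p, name = e$name,
                      expectedDimension = e$dimension,
                      provenance = if (is.null(e$provenance)) "" else e$provenance)
  })
  ScaleRegistry(sets)
}

#' Write a registry to scale tables plus a manifest
#'
#' @param registry A \linkS4class{ScaleRegistry}.
#' @param dir Output directory (created if needed); one \code{<name>.csv} per
#'   set plus \code{manifest.json}.
#' @return Path of the manifest, invisibly.
#' @export
writeRegistryManifest <- function(registry, dir) {
  stopifnot(is(registry, "ScaleRegistry"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(registry@sets, function(s) {
    fn <- paste0(gsub("[^A-Za-z0-9._-]", "_", s@name), ".csv")
    writeDescriptorSet(s, file.path(dir, fn))
    list(name = s@name, path = fn, dimension = descriptorDim(s),
         provenance = s@provenance)
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(unname(entries), manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

.sniffSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}
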