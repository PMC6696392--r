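# Shared fixtures, all generated in code.

# Full 87-parameter synthetic registry (canonical set names and dimensions,
# standard-normal values).
canonicalSyntheticRegistry <- function(seed = 7L) {
  syntheticScales(canonicalDescriptorSets()$dimension, seed = seed)
}

# Small registry for cheap tests: dims 3 + 2, names S1/S2.
smallRegistry <- function(seed = 1L) {
  syntheticScales(c(3L, 2L), seed = seed)
}

# Dipeptide dataset with 5 planted signal variables among 174 encoded ones:
# the sparse-signal study conditions (n = 60, unit effects, noise SD 0.2).
sparseSignalFixture <- function(seed = 11L, n = 60L, noiseSd = 0.2) {
  reg <- canonicalSyntheticRegistry()
  sig <- c("N1-3z-1", "N1-VHSE-2", "N2-DPPS-1", "N2-HESH-2", "N2-T-3")
  spec <- simulationSpec(n, 2L, reg, signalVariables = sig,
                         effectSizes = rep(1, 5), noiseSd = noiseSd,
                         seed = seed)
  d <- generateDataset(spec)
  d$signal <- sig
  d
}

# A valid 20 x k descriptor table written to a temp file.
writeScaleFixture <- function(k = 3L, name = "3z", path = tempfile(fileext = ".csv"),
                              seed = 1L) {
  set.seed(seed)
  df <- data.frame(residue = AMINO_ACIDS,
                   matrix(round(rnorm(20 * k), 4), 20,
                          dimnames = list(NULL, paste0("p", seq_len(k)))))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
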