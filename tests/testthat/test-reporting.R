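# End-to-end pipeline on a small synthetic study: full-variable row, BOSS
# row, importance artifacts, reproducibility from the manifest seed.

makeStudy <- function(dir, nRuns = 2L) {
  reg <- syntheticScales(c(3L, 2L, 4L), seed = 60)
  ids <- variableIds(2, reg)
  spec <- simulationSpec(40, 2, reg,
                         signalVariables = ids[c(1, 8, 15)],
                         effectSizes = c(1, -1, 0.8), noiseSd = 0.2,
                         seed = 61)
  d <- generateDataset(spec)
  writeSyntheticDataset(d, dir)
  writeRegistryManifest(reg, file.path(dir, "registry"))
  cfgPath <- file.path(dir, "config.json")
  jsonlite::write_json(
    list(peptide_table = file.path(dir, "peptides.csv"),
         registry_manifest = file.path(dir, "registry", "manifest.json"),
         output_dir = file.path(dir, "out"),
         n_runs = nRuns, n_subsets = 100L, seed = 62L),
    cfgPath, auto_unbox = TRUE)
  cfgPath
}

test_that("fitStats reports schema-complete full-variable rows", {
  d <- sparseSignalFixture()
  fs <- fitStats(d$X, d$y, seed = 70)
  expect_named(fs$row, c("nVariables", "boss", "A", "r2", "q2", "rmsecv",
                         "rmse"))
  expect_equal(fs$row$nVariables, 174L)
  expect_equal(fs$row$boss, "No")
  expect_true(fs$row$r2 <= 1 && fs$row$q2 <= 1)
  expect_error(fitStats(d$X[1:3, ], d$y[1:3], seed = 1), "fewer samples")
  # noiseless linear signal: R2 = 1
  withSeed(71, {
    X <- matrix(rnorm(200), 20, 10)
    y <- drop(X %*% c(1, -1, rep(0, 8)))
    expect_equal(fitStats(X, y, seed = 72)$row$r2, 1, tolerance = 1e-8)
  })
  # pure noise: Q2 <= 0 on average is checked in test-validation; here the
  # row is just schema-complete
})

test_that("statsTable renders plain and mean±SD rows at 3 decimals", {
  d <- sparseSignalFixture()
  fs <- fitStats(d$X, d$y, seed = 73)
  bs <- bossStats(d$X, d$y, bossConfig(nSubsets = 100), nRuns = 2, seed = 74)
  tab <- statsTable(list(fs, bs), names = c("dipeptides", "dipeptides"))
  expect_equal(tab$BOSS, c("No", "Yes"))
  expect_match(tab$Q2[1], "^-?\\d+\\.\\d{3}$")
  expect_match(tab$Q2[2], "^-?\\d+\\.\\d{3} ± \\d+\\.\\d{3}$")
  # the BOSS row must come from the same matrix and improve cross-validation
  expect_gt(bs$row$q2, fs$row$q2)
})

test_that("runPipeline writes all artifacts and is seed-reproducible", {
  dir <- tempfile()
  dir.create(dir)
  cfgPath <- makeStudy(dir)
  out <- runPipeline(cfgPath, verbose = FALSE)
  files <- c("encoded.csv", "stats.csv", "stats.txt", "importance.json",
             "importance.csv", "best_model.json", "cv_report.json",
             "manifest.json")
  for (f in files)
    expect_true(file.exists(file.path(dir, "out", f)), label = f)
  # encoded matrix has the variable-ID header and n x p layout
  enc <- read.csv(file.path(dir, "out", "encoded.csv"), check.names = FALSE)
  expect_equal(dim(enc), c(40L, 1L + 18L))
  expect_equal(names(enc)[2], "N1-S1-1")
  # manifest ties the run together
  man <- jsonlite::read_json(file.path(dir, "out", "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$n_variables, 18L)
  expect_length(man$run_seeds, 2L)
  # re-running with the same config reproduces the statistics exactly
  stats1 <- read.csv(file.path(dir, "out", "stats.csv"), check.names = FALSE)
  man1 <- man
  out2 <- runPipeline(cfgPath, verbose = FALSE)
  stats2 <- read.csv(file.path(dir, "out", "stats.csv"), check.names = FALSE)
  man2 <- jsonlite::read_json(file.path(dir, "out", "manifest.json"),
                              simplifyVector = TRUE)
  expect_identical(stats1, stats2)
  expect_identical(man1$design_matrix_hash, man2$design_matrix_hash)
  # the no-BOSS and with-BOSS rows used the same input matrix
  expect_identical(out$fit$row$nVariables, out$boss$row$nVariables)
})

test_that("run configs resolve relative paths and fill defaults", {
  dir <- tempfile()
  dir.create(dir)
  cfgPath <- makeStudy(dir)
  cfg <- readRunConfig(cfgPath)
  expect_equal(cfg$cv_folds, 5L)
  expect_equal(cfg$top_fraction, 0.10)
  expect_equal(cfg$n_subsets, 100L)
  # missing file errors at load
  jsonlite::write_json(list(peptide_table = "nope.csv",
                            registry_manifest = "also-nope.json",
                            output_dir = "x"),
                       file.path(dir, "bad.json"), auto_unbox = TRUE)
  expect_error(readRunConfig(file.path(dir, "bad.json")), "does not exist")
})
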