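# Pipeline driver and statistics reporting: full-variable and BOSS-selected
# model summaries in the layout of a QSAR statistics table (A, R2, Q2,
# RMSECV, RMSE, with mean +/- SD for repeated runs), plus a config-driven
# end-to-end entry point.

#' Full-variable model statistics (no variable selection)
#'
#' Fits a PLS model on all encoded variables with automatic component
#' selection by cross-validated Q2 and reports the fit and CV statistics.
#'
#' @param X n x p design matrix.
#' @param y Activity vector.
#' @param cvFolds CV folds (default 5).
#' @param Amax Component-count cap (default min(10, n-1, p)).
#' @param seed Seed for the fold assignment.
#' @param scaleMode \code{"per_fold"} or \code{"global"} autoscaling in CV.
#' @return List with \code{row} (one-row data.frame: nVariables, A, r2, q2,
#'   rmsecv, rmse), \code{model} (\linkS4class{PLSModel}), \code{cv},
#'   \code{folds}.
#' @export
fitStats <- function(X, y, cvFolds = 5L, Amax = NULL, seed,
                     scaleMode = c("per_fold", "global")) {
  scaleMode <- match.arg(scaleMode)
  X <- as.matrix(X)
  if (nrow(X) < cvFolds) stop("fewer samples than CV folds")
  folds <- kfoldSplit(nrow(X), cvFolds, seed = seed)
  sel <- selectComponents(X, y, folds, Amax, scaleMode)
  cv <- crossValidate(X, y, folds, sel$A, scaleMode)
  model <- fitPLS(X, y, A = sel$A)
  yhat <- predict(model, X)
  row <- data.frame(nVariables = ncol(X), boss = "No", A = sel$A,
                    r2 = rSquared(y, yhat), q2 = cv$q2,
                    rmsecv = cv$rmsecv, rmse = rmse(y, yhat))
  list(row = row, model = model, cv = cv, folds = folds)
}

#' BOSS-selected model statistics over repeated runs
#'
#' Runs \code{\link{repeatBOSS}} and reduces the per-run statistics to a
#' mean +/- SD table row, alongside the importance report.
#'
#' @param X n x p design matrix.
#' @param y Activity vector.
#' @param config A \code{\link{bossConfig}}.
#' @param nRuns Repeated runs (reference analysis: 100).
#' @param seed Master seed.
#' @param threshold Selection-frequency cutoff for the importance report.
#' @return List with \code{row} (one-row data.frame of means), \code{sd}
#'   (matching SDs, NA when nRuns = 1), \code{runs} (the
#'   \code{\link{repeatBOSS}} output), \code{importance}
#'   (\code{ImportanceReport}).
#' @export
bossStats <- function(X, y, config = bossConfig(), nRuns = 100L, seed,
                      threshold = 0.60) {
  runs <- repeatBOSS(X, y, config, nRuns = nRuns, seed = seed)
  s <- runs$summary
  g <- function(stat, col) s[[col]][s$statistic == stat]
  row <- data.frame(nVariables = ncol(X), boss = "Yes", A = g("A", "mean"),
                    r2 = g("r2", "mean"), q2 = g("q2", "mean"),
                    rmsecv = g("rmsecv", "mean"), rmse = g("rmse", "mean"),
                    nSelected = g("nSelected", "mean"))
  sdRow <- data.frame(A = g("A", "sd"), r2 = g("r2", "sd"),
                      q2 = g("q2", "sd"), rmsecv = g("rmsecv", "sd"),
                      rmse = g("rmse", "sd"),
                      nSelected = g("nSelected", "sd"))
  imp <- bestModelReport(runs$results, X, y, threshold = threshold)
  list(row = row, sd = sdRow, runs = runs, importance = imp)
}

#' Format model statistics as a display table
#'
#' Renders rows from \code{\link{fitStats}} / \code{\link{bossStats}} with
#' three decimals and \code{mean +/- SD} formatting for repeated-run rows.
#'
#' @param rows List of results from \code{fitStats} and/or \code{bossStats}.
#' @param names Optional dataset names, one per row.
#' @return data.frame of formatted character columns (BOSS, Variables, Name,
#'   A, R2, Q2, RMSECV, RMSE).
#' @export
statsTable <- function(rows, names = NULL) {
  fmt <- function(m, s) {
    if (is.null(s) || is.na(s)) sprintf("%.3f", m)
    else sprintf("%.3f ± %.3f", m, s)
  }
  out <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]$row
    s <- rows[[i]]$sd
    data.frame(BOSS = r$boss, Variables = r$nVariables,
               Name = if (is.null(names)) "" else names[i],
               A = fmt(r$A, s$A), R2 = fmt(r$r2, s$r2),
               Q2 = fmt(r$q2, s$q2), RMSECV = fmt(r$rmsecv, s$rmsecv),
               RMSE = fmt(r$rmse, s$rmse), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read a run configuration
#'
#' YAML or JSON (by extension) with fields: \code{peptide_table},
#' \code{registry_manifest}, \code{output_dir}, and optional analysis
#' parameters \code{cv_folds} (5), \code{n_runs} (100), \code{n_subsets}
#' (1000), \code{top_fraction} (0.10), \code{a_max} (10),
#' \code{importance_threshold} (0.60), \code{scale_mode} ("per_fold"),
#' \code{seed}.
#'
#' @param path Config file path.
#' @return List of class \code{RunConfig} with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(cv_folds = 5L, n_runs = 100L, n_subsets = 1000L,
                   top_fraction = 0.10, a_max = 10L,
                   importance_threshold = 0.60, scale_mode = "per_fold",
                   seed = 1L)
  cfg <- utils::modifyList(defaults, cfg)
  for (f in c("peptide_table", "registry_manifest")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      cand <- file.path(dirname(normalizePath(path)), cfg[[f]])
      if (file.exists(cand)) cfg[[f]] <- cand
      else stop(sprintf("config path '%s' does not exist", cfg[[f]]))
    }
  }
  structure(cfg, class = "RunConfig")
}

#' Run the full QSAR pipeline
#'
#' Reads the peptide table and registry, encodes the design matrix, fits the
#' full-variable model, runs repeated BOSS selection, and writes all
#' artifacts to the output directory: \code{encoded.csv} (design matrix with
#' variable-ID header), \code{stats.csv} / \code{stats.txt} (the
#' with/without-BOSS statistics table), \code{importance.json} and
#' \code{importance.csv}, \code{best_model.json}, \code{cv_report.json},
#' and \code{manifest.json} recording seeds, parameters and a content hash
#' of the design matrix, sufficient to reproduce the run.
#'
#' @param config A \code{RunConfig} (see \code{\link{readRunConfig}}), or a
#'   path to one.
#' @param verbose Progress messages.
#' @return Invisibly, a list with the stats rows, importance report and
#'   output paths.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  outDir <- config$output_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  peptides <- readPeptideTable(config$peptide_table)
  registry <- readRegistryManifest(config$registry_manifest)
  enc <- encodeDataset(peptides, registry)
  X <- enc$X; y <- enc$y
  say("encoded %d peptides x %d variables", nrow(X), ncol(X))

  utils::write.table(
    data.frame(sequence = rownames(X), X, check.names = FALSE),
    file.path(outDir, "encoded.csv"), sep = ",", quote = FALSE,
    row.names = FALSE)

  seeds <- deriveSeeds(config$seed, 2L)
  xHash <- .contentHash(X)

  fit <- fitStats(X, y, cvFolds = config$cv_folds, Amax = config$a_max,
                  seed = seeds[1L], scaleMode = config$scale_mode)
  say("full-variable model: A = %d, Q2 = %.3f", fit$row$A, fit$row$q2)

  cfg <- bossConfig(nSubsets = config$n_subsets,
                    topFraction = config$top_fraction,
                    cvFolds = config$cv_folds, Amax = config$a_max,
                    scaleMode = config$scale_mode)
  bs <- bossStats(X, y, cfg, nRuns = config$n_runs, seed = seeds[2L],
                  threshold = config$importance_threshold)
  say("BOSS (%d runs): mean Q2 = %.3f, mean %.1f variables selected",
      config$n_runs, bs$row$q2, bs$row$nSelected)

  tab <- statsTable(list(fit, bs))
  utils::write.table(tab, file.path(outDir, "stats.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  writeLines(c(utils::capture.output(print(tab, right = FALSE))),
             file.path(outDir, "stats.txt"))
  writeImportanceReport(bs$importance, file.path(outDir, "importance.json"))
  utils::write.table(importanceTable(bs$importance),
                     file.path(outDir, "importance.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  writePLSModel(bs$importance$bestModel, file.path(outDir, "best_model.json"))
  writeCVReport(fit$cv, file.path(outDir, "cv_report.json"), seed = seeds[1L])
  jsonlite::write_json(
    list(seed = config$seed, stage_seeds = seeds,
         design_matrix_hash = xHash,
         n_peptides = nrow(X), n_variables = ncol(X),
         parameters = config[setdiff(names(config),
                                     c("peptide_table", "registry_manifest",
                                       "output_dir"))],
         run_seeds = bs$runs$stats$seed),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = I(17))

  say("artifacts written to %s", outDir)
  invisible(list(fit = fit, boss = bs, table = tab, outputDir = outDir))
}

# Stable content hash of a numeric matrix (sum-based, no external deps).
.contentHash <- function(X) {
  v <- as.numeric(X)
  sprintf("%s-%d-%d", format(sum(v * seq_along(v)) + sum(v^2), digits = 17),
          nrow(X), ncol(X))
}
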