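## End-to-end orchestration: design matrix construction and the staged
## pipeline (simulate -> preprocess -> tune -> fit -> stability select ->
## downstream statistics -> validation) driven by a single config.

#' Build a block/outcome coupling design matrix
#'
#' Symmetric matrix over the omics blocks plus the outcome: a weak
#' coupling (default 0.1) between every pair of omics blocks and full
#' coupling (default 1.0) between each block and the outcome, zero
#' diagonal.
#' @param blockNames character vector of block names.
#' @param omicsOmicsWeight coupling between omics blocks (default 0.1).
#' @param omicsOutcomeWeight coupling between each block and the outcome
#'   (default 1).
#' @return (B+1) x (B+1) matrix with dimnames `c(blockNames, "outcome")`.
#' @examples
#' makeDesign(c("gene", "protein", "peptide"))
#' @export
makeDesign <- function(blockNames, omicsOmicsWeight = 0.1,
                       omicsOutcomeWeight = 1.0) {
  if (omicsOmicsWeight < 0 || omicsOutcomeWeight < 0)
    stop("makeDesign: weights must be nonnegative")
  nm <- c(blockNames, "outcome")
  C <- matrix(omicsOmicsWeight, length(nm), length(nm),
              dimnames = list(nm, nm))
  C[, "outcome"] <- omicsOutcomeWeight
  C["outcome", ] <- omicsOutcomeWeight
  diag(C) <- 0
  C
}

#' Default pipeline configuration
#'
#' Desk-scale defaults for [runPipeline()]: a small simulated cohort, the
#' standard design weights, a reduced tuning grid and repeat counts. Any
#' element can be overridden via `...`. Supply `gmt` (path) to enable the
#' enrichment stage.
#' @param ... overrides for the default elements.
#' @return config list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    simulation = list(
      nPerClass = c(16L, 26L),
      blockSpecs = data.frame(name = c("gene", "protein", "peptide"),
                              nFeatures = c(300L, 120L, 180L),
                              missingFrac = c(0, 0.26, 0.39)),
      nInformative = 10L, effectSize = 2, latentDim = 2L,
      blockNoiseSd = 2, overlapFraction = 0.5),
    preprocess = list(maxMissingFrac = 0.5, knnK = 7L,
                      topNVariance = 10000L),
    design = list(omicsOmicsWeight = 0.1, omicsOutcomeWeight = 1.0),
    tuning = list(candidates = c(5L, 10L, 25L), maxNcomp = 2L,
                  nFolds = 5L, nRepeats = 5L),
    stability = list(nCopies = 100L, coverageFrac = 0.8),
    validation = list(classifier = "logistic", nFolds = 5L,
                      nRepeats = 20L),
    gmt = NULL,
    seed = 1L)
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(cfg[[nm]]) && is.list(ov[[nm]]))
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    else cfg[[nm]] <- ov[[nm]]
  }
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys override [pipelineConfig()] defaults.
#' @return config list.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation$blockSpecs))
    raw$simulation$blockSpecs <-
      as.data.frame(lapply(raw$simulation$blockSpecs, unlist))
  do.call(pipelineConfig, raw)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- simulate, preprocess, tune, fit,
#' stability-select, signature finalization, differential expression,
#' component-trait correlation, optional gene-set overrepresentation, and
#' validation on an independently simulated cohort -- persisting every
#' intermediate artifact under `outdir` and recording a manifest (config
#' echo, per-stage seeds, output paths). Re-running with an identical
#' config reproduces byte-identical outputs: the global seed spawns each
#' stage's seed deterministically from the stage name, so adding a stage
#' never perturbs earlier stages' randomness.
#'
#' @param config list from [pipelineConfig()] or [readPipelineConfig()].
#' @param outdir output directory.
#' @return the manifest (invisibly also written as
#'   `manifest.json`), including the chosen parameters, signature size and
#'   validation performance.
#' @export
runPipeline <- function(config, outdir) {
  if (is.character(config))
    config <- readPipelineConfig(config)
  if (!is.null(config$gmt) && !file.exists(config$gmt))
    stop("runPipeline: GMT file not found: ", config$gmt)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(simulate = deriveSeed(config$seed, "simulate"),
                tune = deriveSeed(config$seed, "tune"),
                stability = deriveSeed(config$seed, "stability"),
                validate = deriveSeed(config$seed, "validate"))
  manifest <- list(config = config, seeds = seeds, stages = list())
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    manifest$stages[[name]] <<- list(seconds =
      round(proc.time()[["elapsed"]] - t0, 2))
    res
  }

  ## 1. simulate
  simCfg <- do.call(simulationConfig,
                    c(config$simulation, list(seed = seeds$simulate)))
  sim <- stage("simulate", simulateMultiOmics(simCfg))
  writeSimulatedDataset(sim, file.path(outdir, "simulated"))

  ## 2. preprocess
  prep <- stage("preprocess", do.call(preprocessDataset,
    c(list(data = sim$data), config$preprocess)))
  data <- prep$data
  jsonlite::write_json(prep$report,
                       file.path(outdir, "preprocess_report.json"),
                       auto_unbox = TRUE, digits = NA)

  ## 3. design + tune
  design <- do.call(makeDesign,
                    c(list(blockNames = names(blocks(data))),
                      config$design))
  tuned <- stage("tune", tuneKeepX(
    data, candidates = config$tuning$candidates,
    maxNcomp = config$tuning$maxNcomp, design = design,
    nFolds = config$tuning$nFolds, nRepeats = config$tuning$nRepeats,
    seed = seeds$tune))
  utils::write.table(tuned$surface, file.path(outdir, "cv_surface.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(ncomp = tuned$ncomp, keepX = tuned$keepX),
                       file.path(outdir, "optimal_parameters.json"),
                       auto_unbox = TRUE, digits = NA)

  ## 4. fit on full data
  fit <- stage("fit", fitBlockSplsda(data, design = design,
                                     ncomp = tuned$ncomp,
                                     keepX = tuned$keepX))
  writeModelJson(fit, file.path(outdir, "model.json"))

  ## 5. stability selection + signature
  imp <- stage("stability", stabilitySelect(
    data, ncomp = tuned$ncomp, keepX = tuned$keepX, design = design,
    nCopies = config$stability$nCopies,
    coverageFrac = config$stability$coverageFrac,
    seed = seeds$stability))
  utils::write.table(imp, file.path(outdir, "feature_importance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  idMap <- sim$truth$symbolMap[, c("feature_id", "symbol")]
  sig <- stage("signature", finalizeSignature(imp, tuned$keepX, idMap,
                                              name = "MULTI"))
  writeSignatureTsv(sig, file.path(outdir, "signature.tsv"))

  ## 6. downstream statistics
  de <- stage("diffexp", differentialExpression(
    blocks(data)[[1L]], phenotype(data), patientIds(data)))
  utils::write.table(de, file.path(outdir, "differential_expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- traitTable(data)
  if (ncol(tr)) {
    ctc <- stage("traits", componentTraitCorrelation(fit, tr))
    utils::write.table(ctc, file.path(outdir, "component_traits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(config$gmt)) {
    sets <- readGmt(config$gmt)
    enr <- stage("enrich", gsoa(sig$symbol, sets,
                                universe = unique(idMap$symbol)))
    utils::write.table(enr, file.path(outdir, "gsoa.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  ## 7. validation on an independently simulated cohort
  valCfg <- do.call(simulationConfig,
                    c(config$simulation, list(seed = seeds$validate)))
  valSim <- stage("simulate_validation", simulateMultiOmics(valCfg))
  valBlock <- blocks(valSim$data)[[1L]]
  valMap <- valSim$truth$symbolMap[
    valSim$truth$symbolMap$block == blockName(valBlock),
    c("feature_id", "symbol")]
  val <- stage("validate", {
    sub <- subsetToSignature(valBlock, sig$symbol, valMap)
    perf <- evaluateSignature(sub$block, phenotype(valSim$data),
                              classifier = config$validation$classifier,
                              nFolds = config$validation$nFolds,
                              nRepeats = config$validation$nRepeats,
                              seed = seeds$validate)
    perf$coverage <- sub$coverage
    perf
  })
  valOut <- data.frame(metric = c("accuracy", "auc"),
                       mean = c(val$accuracyMean, val$aucMean),
                       sd = c(val$accuracySd, val$aucSd))
  utils::write.table(valOut, file.path(outdir, "validation_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest$results <- list(
    ncomp = tuned$ncomp, keepX = tuned$keepX,
    signatureSize = nrow(sig),
    validationAucMean = val$aucMean,
    validationAccuracyMean = val$accuracyMean,
    signatureCoverage = val$coverage)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
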