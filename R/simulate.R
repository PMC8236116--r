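#' Simulation configuration for synthetic multiomics data
#'
#' Bundles the parameters of the synthetic generator. Defaults emulate the
#' shape of a paired carotid-plaque cohort: two phenotype classes of 16
#' (non-hemorrhaged, `nonIPH`) and 26 (hemorrhaged, `IPH`) samples, three
#' omics blocks with block-wise missing-completely-at-random values in the
#' protein (26%) and peptide (39%) layers, a shared class-discriminative
#' latent factor inducing cross-block covariance, and continuous "plaque
#' trait" covariates correlated with that factor.
#'
#' @param nPerClass integer(2), samples in the negative and positive class.
#' @param blockSpecs data.frame with columns `name`, `nFeatures`,
#'   `missingFrac` (fraction in `[0,1)` of entries set missing).
#' @param nInformative number of planted class-discriminative features per
#'   block.
#' @param effectSize planted between-class mean shift in within-class SD
#'   units (standardized difference of each informative feature).
#' @param latentDim number of shared latent factors; factor 1 carries the
#'   class signal, further factors add class-neutral correlated structure.
#' @param blockNoiseSd residual (feature-specific) noise SD.
#' @param traitSpecs data.frame with columns `name`, `cor`: target Pearson
#'   correlation of each trait with latent factor 1 (`|cor| <= 1`).
#' @param overlapFraction fraction of each block's informative features that
#'   share a gene symbol across blocks.
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return a list of class `SimulationConfig`.
#' @examples
#' cfg <- simulationConfig(blockSpecs = data.frame(
#'   name = c("gene", "protein"), nFeatures = c(100, 50),
#'   missingFrac = c(0, 0.3)), seed = 1)
#' @export
simulationConfig <- function(nPerClass = c(16L, 26L),
                             blockSpecs = data.frame(
                               name = c("gene", "protein", "peptide"),
                               nFeatures = c(10000L, 943L, 2637L),
                               missingFrac = c(0, 0.2645, 0.3894)),
                             nInformative = 10L,
                             effectSize = 2,
                             latentDim = 2L,
                             blockNoiseSd = 2,
                             traitSpecs = data.frame(
                               name = c("plaque_size", "fibroblast_content",
                                        "arg1_macrophage"),
                               cor = c(0.74, 0.64, -0.62)),
                             overlapFraction = 0.5,
                             seed = 1L) {
  stopifnot(length(nPerClass) == 2L, all(nPerClass >= 2L))
  blockSpecs <- as.data.frame(blockSpecs)
  stopifnot(all(c("name", "nFeatures", "missingFrac") %in% names(blockSpecs)))
  if (any(blockSpecs$missingFrac >= 1) || any(blockSpecs$missingFrac < 0))
    stop("missingFrac must lie in [0, 1)")
  if (any(nInformative > blockSpecs$nFeatures))
    stop("nInformative exceeds nFeatures for at least one block")
  if (effectSize < 0)
    stop("effectSize must be >= 0")
  traitSpecs <- as.data.frame(traitSpecs)
  if (nrow(traitSpecs) && any(abs(traitSpecs$cor) > 1))
    stop("trait correlation specs must lie in [-1, 1]")
  structure(list(nPerClass = as.integer(nPerClass), blockSpecs = blockSpecs,
                 nInformative = as.integer(nInformative),
                 effectSize = effectSize, latentDim = as.integer(latentDim),
                 blockNoiseSd = blockNoiseSd, traitSpecs = traitSpecs,
                 overlapFraction = overlapFraction, seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Generate a synthetic multiomics dataset with planted class structure
#'
#' The planted signal enters through a low-rank latent model: every sample
#' carries a latent score on factor 1 whose class means are separated, and
#' every informative feature loads (with a positive coefficient tied to the
#' effect size) on that factor plus feature-specific Gaussian noise. Cross-block covariance among informative
#' features is therefore genuinely present -- the structure a design-coupled
#' multiblock model exploits -- rather than independent per-feature mean
#' shifts. The class separation of the latent factor is calibrated so each
#' informative feature's standardized group difference equals `effectSize`.
#' Non-informative features are pure noise. Missing entries are placed
#' completely at random per block at the requested fraction (exact count),
#' after the signal is planted, so an informative feature can by chance
#' exceed a downstream missingness filter; the ground truth reports which
#' informative features survive a 50% filter.
#'
#' @param config a [simulationConfig()] object.
#' @return list with elements `data` (a [MultiOmicsDataset-class]) and
#'   `truth` (list: `informativeIds` per block, `latentScores` matrix,
#'   `traitValues`, `symbolMap` data.frame `feature_id`/`block`/`symbol`,
#'   `survivingInformative` per block, `effectiveDelta`).
#' @examples
#' sim <- simulateMultiOmics(simulationConfig(
#'   blockSpecs = data.frame(name = c("gene", "protein"),
#'     nFeatures = c(60, 40), missingFrac = c(0, 0.3)),
#'   nPerClass = c(8, 10), seed = 7))
#' sim$data
#' @export
simulateMultiOmics <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(config$seed, {
    nA <- config$nPerClass[1L]; nB <- config$nPerClass[2L]
    n <- nA + nB
    y <- factor(rep(c("nonIPH", "IPH"), c(nA, nB)),
                levels = c("nonIPH", "IPH"))
    sids <- sprintf("S%03d", seq_len(n))
    ## paired design: patients contribute one sample per class where possible
    pid <- c(sprintf("P%03d", seq_len(nA)),
             sprintf("P%03d", seq_len(nB)))

    ## latent factor 1: class-separated. Informative features load on it
    ## with coefficient s = effectSize/2, and the class separation of the
    ## factor is delta_z = 2*sqrt(effectSize^2/4 + sigma^2), so that each
    ## informative feature's standardized group difference
    ## (s*delta_z / sqrt(s^2 + sigma^2)) equals effectSize exactly for any
    ## noise level, and a zero effect size plants nothing (informative
    ## features are then exchangeable with noise features).
    sigma <- config$blockNoiseSd
    sLoad <- config$effectSize / 2
    deltaZ <- 2 * sqrt(config$effectSize^2 / 4 + sigma^2)
    z <- matrix(rnorm(n * config$latentDim), n, config$latentDim)
    z[, 1L] <- z[, 1L] + ifelse(y == "IPH", deltaZ / 2, -deltaZ / 2)
    rownames(z) <- sids
    colnames(z) <- paste0("LF", seq_len(config$latentDim))

    nShared <- roundHalfUp(config$overlapFraction * config$nInformative)
    sharedSymbols <- sprintf("SYMSHARED%03d", seq_len(nShared))

    blockList <- list()
    informativeIds <- list()
    surviving <- list()
    symbolMap <- NULL
    for (i in seq_len(nrow(config$blockSpecs))) {
      bname <- as.character(config$blockSpecs$name[i])
      p <- config$blockSpecs$nFeatures[i]
      mf <- config$blockSpecs$missingFrac[i]
      fids <- sprintf("%s_f%05d", toupper(bname), seq_len(p))
      X <- matrix(rnorm(p * n, sd = sigma), p, n,
                  dimnames = list(fids, sids))
      ninf <- config$nInformative
      infIdx <- seq_len(ninf)           # planted features are the first rows
      if (sLoad > 0)
        X[infIdx, ] <- X[infIdx, , drop = FALSE] +
          sLoad * matrix(rep(z[, 1L], each = ninf), ninf, n)
      ## extra class-neutral latent factors load on a slice of noise features
      if (config$latentDim > 1L && p > ninf) {
        for (l in 2:config$latentDim) {
          lo <- ninf + 1L; hi <- min(p, ninf + ninf)
          if (lo <= hi)
            X[lo:hi, ] <- X[lo:hi, , drop = FALSE] +
              0.7 * matrix(rep(z[, l], each = hi - lo + 1L),
                           hi - lo + 1L, n)
        }
      }
      ## MCAR missingness at the exact requested per-block fraction
      if (mf > 0) {
        nMiss <- round(mf * length(X))
        X[sample.int(length(X), nMiss)] <- NA
      }
      ## symbols: first nShared informative features map to shared symbols
      sym <- sprintf("SYM_%s_%05d", toupper(bname), seq_len(p))
      if (nShared > 0)
        sym[seq_len(min(nShared, ninf))] <-
          sharedSymbols[seq_len(min(nShared, ninf))]
      symbolMap <- rbind(symbolMap,
        data.frame(feature_id = fids, block = bname, symbol = sym,
                   stringsAsFactors = FALSE))
      blockList[[bname]] <- omicsBlock(bname, X)
      informativeIds[[bname]] <- fids[infIdx]
      surviving[[bname]] <-
        fids[infIdx][rowMeans(is.na(X[infIdx, , drop = FALSE])) < 0.5]
    }

    ## traits: affine in standardized latent factor 1 plus calibrated noise
    zstd <- as.numeric(scale(z[, 1L]))
    traits <- data.frame(row.names = sids)
    if (nrow(config$traitSpecs)) {
      for (j in seq_len(nrow(config$traitSpecs))) {
        rho <- config$traitSpecs$cor[j]
        traits[[as.character(config$traitSpecs$name[j])]] <-
          rho * zstd + sqrt(1 - rho^2) * rnorm(n)
      }
    }

    data <- multiOmicsDataset(blockList, y, pid, traits)
    truth <- list(informativeIds = informativeIds, latentScores = z,
                  traitValues = traits, symbolMap = symbolMap,
                  survivingInformative = surviving,
                  effectiveDelta = deltaZ)
    list(data = data, truth = truth)
  })
}

#' Generate additional trait covariates from simulated latent scores
#'
#' Each trait is drawn as `rho * z1 + sqrt(1 - rho^2) * noise` where `z1` is
#' the standardized latent factor 1, so its population correlation with the
#' factor equals the spec. At study-scale n the sample correlation scatters
#' around the target (Fisher-z width).
#'
#' @param truth the `truth` element of [simulateMultiOmics()] output.
#' @param traitSpecs data.frame with columns `name`, `cor`.
#' @param seed integer seed.
#' @return data.frame of traits, one row per sample.
#' @export
generateTraitTable <- function(truth, traitSpecs, seed) {
  traitSpecs <- as.data.frame(traitSpecs)
  if (any(abs(traitSpecs$cor) > 1))
    stop("trait correlation specs must lie in [-1, 1]")
  z <- truth$latentScores[, 1L]
  zstd <- as.numeric(scale(z))
  withSeed(seed, {
    out <- data.frame(row.names = rownames(truth$latentScores))
    for (j in seq_len(nrow(traitSpecs))) {
      rho <- traitSpecs$cor[j]
      out[[as.character(traitSpecs$name[j])]] <-
        rho * zstd + sqrt(1 - rho^2) * rnorm(length(zstd))
    }
    out
  })
}

#' Write a simulated dataset to plain-text files
#'
#' Blocks are written as TSV (features as rows, first column `feature_id`),
#' plus sample metadata (`sample_id`, `group`, `patient_id`), traits, the
#' feature-to-symbol map, and the ground truth as JSON.
#'
#' @param sim output of [simulateMultiOmics()].
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of written paths.
#' @export
writeSimulatedDataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (b in blocks(sim$data)) {
    p <- file.path(dir, paste0("block_", blockName(b), ".tsv"))
    writeBlockTsv(b, p)
    paths[paste0("block_", blockName(b))] <- p
  }
  meta <- data.frame(sample_id = sampleIds(sim$data),
                     group = as.character(phenotype(sim$data)),
                     patient_id = patientIds(sim$data))
  mp <- file.path(dir, "metadata.tsv")
  utils::write.table(meta, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["metadata"] <- mp
  tr <- traitTable(sim$data)
  if (ncol(tr)) {
    tp <- file.path(dir, "traits.tsv")
    utils::write.table(cbind(sample_id = rownames(tr), tr), tp, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths["traits"] <- tp
  }
  sp <- file.path(dir, "symbol_map.tsv")
  utils::write.table(sim$truth$symbolMap, sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["symbol_map"] <- sp
  gp <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(informativeIds = sim$truth$informativeIds,
                            survivingInformative = sim$truth$survivingInformative,
                            effectiveDelta = sim$truth$effectiveDelta),
                       gp, auto_unbox = TRUE, digits = NA)
  paths["ground_truth"] <- gp
  invisible(paths)
}
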