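## Stability-based feature selection: stratified resampling with
## replacement, loading-weight aggregation across copies, and
## cross-omics identifier unification into a gene-symbol signature.

#' Stratified resample with replacement
#'
#' Draws, per class, `round(coverageFrac * n_class)` sample indices with
#' replacement (round-half-up), so each data copy covers the requested
#' fraction of the data with the original phenotype distribution.
#'
#' @param y labels (both classes present).
#' @param coverageFrac fraction of each class to draw (default 0.8).
#' @param seed integer seed.
#' @return integer index multiset (concatenated per class).
#' @examples
#' table(rep(c("a","b"), c(16, 26))[stratifiedResample(
#'   rep(c("a","b"), c(16, 26)), 0.8, 1)])  # 13 a, 21 b
#' @export
stratifiedResample <- function(y, coverageFrac = 0.8, seed = 1L) {
  y <- as.factor(y)
  if (coverageFrac <= 0 || coverageFrac > 1)
    stop("coverageFrac must lie in (0, 1]")
  if (any(table(y) == 0L))
    stop("stratifiedResample: empty class")
  withSeed(seed, {
    unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      nDraw <- roundHalfUp(coverageFrac * length(idx))
      idx[sample.int(length(idx), nDraw, replace = TRUE)]
    }))
  })
}

#' Stability selection by resampled model refits
#'
#' Fits the model (with fixed, pre-tuned parameters) on `nCopies`
#' stratified resampled copies of the dataset and aggregates, per (block,
#' component, feature), the sum of absolute loading weights across copies
#' together with the fraction of copies in which the feature received a
#' nonzero loading. Copies that fail to fit are skipped and counted; more
#' than 10% failures is an error.
#'
#' @param data a complete [MultiOmicsDataset-class].
#' @param ncomp,keepX,design model parameters (typically from
#'   [tuneKeepX()]).
#' @param nCopies number of resampled copies (default 200; scale up for
#'   production runs).
#' @param coverageFrac per-class coverage of each copy (default 0.8).
#' @param seed base seed; copy `i` uses `seed + i`.
#' @return data.frame (`FeatureImportanceTable`) with columns `block`,
#'   `comp`, `feature_id`, `importance` (sum of |loading| over copies),
#'   `frequency` (selection fraction), sorted by importance within
#'   (block, comp); attribute `nFailed` counts skipped copies.
#' @export
stabilitySelect <- function(data, ncomp, keepX, design = NULL,
                            nCopies = 200L, coverageFrac = 0.8,
                            seed = 1L) {
  bn <- names(blocks(data))
  if (is.null(design))
    design <- makeDesign(bn)
  imp <- lapply(blocks(data), function(b)
    matrix(0, nrow(blockValues(b)), ncomp,
           dimnames = list(featureIds(b), NULL)))
  freq <- imp
  nFailed <- 0L
  for (i in seq_len(nCopies)) {
    idx <- stratifiedResample(phenotype(data), coverageFrac, seed + i)
    fit <- tryCatch(
      fitBlockSplsda(subsetSamples(data, idx), design = design,
                     ncomp = ncomp, keepX = keepX),
      error = function(e) NULL)
    if (is.null(fit)) { nFailed <- nFailed + 1L; next }
    for (b in bn) {
      L <- modelLoadings(fit)[[b]]
      imp[[b]] <- imp[[b]] + abs(L)
      freq[[b]] <- freq[[b]] + (L != 0)
    }
  }
  if (nFailed > 0.1 * nCopies)
    stop(sprintf("stabilitySelect: %d of %d copies failed to fit",
                 nFailed, nCopies))
  nOk <- nCopies - nFailed
  rows <- list()
  for (b in bn) {
    for (h in seq_len(ncomp)) {
      rows[[length(rows) + 1L]] <- data.frame(
        block = b, comp = h, feature_id = rownames(imp[[b]]),
        importance = imp[[b]][, h], frequency = freq[[b]][, h] / nOk,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$block, out$comp, -out$importance, out$feature_id), ]
  rownames(out) <- NULL
  attr(out, "nFailed") <- nFailed
  attr(out, "nCopies") <- nCopies
  out
}

#' Collapse a feature-importance table into a gene-symbol signature
#'
#' Takes the top `keepX` features per (block, component) by aggregate
#' importance, maps each feature id to its gene symbol, and deduplicates
#' symbols keeping the maximum importance (a symbol's component is the one
#' where it reached that maximum). The result is ordered by descending
#' overall importance.
#'
#' @param table a `FeatureImportanceTable` from [stabilitySelect()].
#' @param keepX named list (per block) of per-component budgets, as used at
#'   fit time.
#' @param idMap data.frame with columns `feature_id` and `symbol` covering
#'   every selected feature.
#' @param name optional signature tag (e.g. `"MULTI 1"`).
#' @return data.frame (`Signature`) with columns `symbol`, `importance`,
#'   `blocks` (comma-joined provenance), `comp`; attribute `name`.
#' @examples
#' tab <- data.frame(block = "g", comp = 1, feature_id = c("a", "b"),
#'                   importance = c(2, 1), frequency = 1)
#' finalizeSignature(tab, list(g = 2),
#'                   data.frame(feature_id = c("a", "b"),
#'                              symbol = c("S1", "S2")))
#' @export
finalizeSignature <- function(table, keepX, idMap, name = "signature") {
  sel <- list()
  for (b in unique(table$block)) {
    for (h in unique(table$comp[table$block == b])) {
      sub <- table[table$block == b & table$comp == h, ]
      sub <- sub[order(-sub$importance, sub$feature_id), ]
      kb <- keepX[[b]]
      k <- if (length(kb) >= h) kb[h] else kb[length(kb)]
      sel[[length(sel) + 1L]] <- utils::head(sub, k)
    }
  }
  sel <- do.call(rbind, sel)
  m <- match(sel$feature_id, idMap$feature_id)
  if (anyNA(m))
    stop("finalizeSignature: unmapped feature id(s): ",
         paste(utils::head(sel$feature_id[is.na(m)], 5), collapse = ", "))
  sel$symbol <- idMap$symbol[m]
  ## deduplicate symbols keeping the maximum importance; record provenance
  sel <- sel[order(-sel$importance, sel$symbol), ]
  first <- !duplicated(sel$symbol)
  prov <- vapply(split(sel$block, sel$symbol), function(x)
    paste(sort(unique(x)), collapse = ","), character(1))
  out <- sel[first, c("symbol", "importance", "comp")]
  out$blocks <- prov[out$symbol]
  out <- out[order(-out$importance, out$symbol),
             c("symbol", "importance", "blocks", "comp")]
  rownames(out) <- NULL
  attr(out, "name") <- name
  out
}

#' Write a signature as TSV and as a plain symbol list
#' @param signature output of [finalizeSignature()].
#' @param path TSV path; a `.symbols.txt` sibling file is written too.
#' @export
writeSignatureTsv <- function(signature, path) {
  utils::write.table(signature, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(signature$symbol, sub("\\.tsv$", ".symbols.txt", path))
  invisible(path)
}
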