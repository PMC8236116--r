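## Preprocessing: normalization stand-ins, missingness filtering,
## k-NN imputation, top-variance feature filtering.

#' Filter features by missingness
#'
#' Discards every feature whose fraction of missing samples is greater than
#' or equal to `maxMissingFrac` (a feature missing in exactly half the
#' samples is discarded at the default 0.5). Feature order is preserved.
#'
#' @param block an [OmicsBlock-class].
#' @param maxMissingFrac threshold in `[0,1]`; default 0.5.
#' @return list with `block` (filtered [OmicsBlock-class]) and `discarded`
#'   (character vector of removed feature ids).
#' @examples
#' m <- matrix(c(1, NA, 3, NA, 2, 4, 1, 2), 2, 4,
#'   dimnames = list(c("a", "b"), paste0("s", 1:4)))
#' filterMissing(omicsBlock("x", m))$discarded   # "a" (2 of 4 missing)
#' @export
filterMissing <- function(block, maxMissingFrac = 0.5) {
  stopifnot(is(block, "OmicsBlock"))
  frac <- rowMeans(missingMask(block))
  keep <- frac < maxMissingFrac
  if (!any(keep))
    stop("filterMissing: no feature passes the missingness threshold")
  v <- blockValues(block)[keep, , drop = FALSE]
  list(block = omicsBlock(blockName(block), v),
       discarded = featureIds(block)[!keep])
}

#' k-nearest-neighbour imputation of missing entries
#'
#' Sample-wise, unsupervised imputation: for a sample with a missing
#' feature, the distance to every other sample is the Euclidean distance
#' over mutually observed features divided by the square root of their
#' count (so distances are comparable across different overlap sizes). The
#' missing value is the unweighted mean of the feature's observed values
#' among the `k` nearest neighbours; neighbours in which the feature is
#' also missing contribute nothing. If the feature is observed in none of
#' the `k` neighbours, the feature's overall observed mean is used and a
#' warning is emitted. Phenotype labels are never consulted. Observed
#' entries are left untouched; the result has no missing values.
#'
#' @param block an [OmicsBlock-class]; every feature should already pass
#'   the missingness filter.
#' @param k neighbour count (default 7); must be below the sample count.
#' @return imputed [OmicsBlock-class].
#' @export
knnImpute <- function(block, k = 7L) {
  stopifnot(is(block, "OmicsBlock"))
  v <- blockValues(block)
  n <- ncol(v)
  if (k < 1L || k >= n)
    stop("knnImpute: k must satisfy 1 <= k < number of samples")
  miss <- is.na(v)
  if (!any(miss))
    return(block)
  out <- v
  obsMean <- rowMeans(v, na.rm = TRUE)
  needs <- which(colSums(miss) > 0L)
  for (s in needs) {
    d <- rep(Inf, n)
    for (t in seq_len(n)) {
      if (t == s) next
      both <- !miss[, s] & !miss[, t]
      m <- sum(both)
      if (m == 0L) next
      d[t] <- sqrt(sum((v[both, s] - v[both, t])^2) / m)
    }
    ## k nearest neighbours; distance ties broken by sample index (stable)
    nb <- order(d, seq_len(n))[seq_len(k)]
    for (f in which(miss[, s])) {
      vals <- v[f, nb]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0L) {
        warning(sprintf(
          "knnImpute: feature '%s' unobserved in all %d neighbours of sample '%s'; falling back to its overall mean",
          rownames(v)[f], k, colnames(v)[s]))
        out[f, s] <- obsMean[f]
      } else {
        out[f, s] <- mean(vals)
      }
    }
  }
  omicsBlock(blockName(block), out)
}

#' Normalize an omics block
#'
#' Two documented stand-ins for platform-specific normalizations that
#' require raw platform data:
#' * `"log_median"`: log2 transform followed by per-sample median centering
#'   (median over the sample's observed values). A variance-stabilizing
#'   surrogate for array intensities.
#' * `"reference_geomean"`: per-sample division by the geometric mean of
#'   the complete-case features (features observed in every sample), then
#'   log2 -- reference-feature scaling in the spirit of housekeeping-gene
#'   normalization for abundance ratios.
#'
#' Missing entries stay missing. Raw values must be strictly positive.
#'
#' @param block an [OmicsBlock-class] of raw (unlogged) values.
#' @param mode `"log_median"` or `"reference_geomean"`.
#' @return normalized [OmicsBlock-class] (log2 scale).
#' @export
normalizeBlock <- function(block, mode = c("log_median", "reference_geomean")) {
  mode <- match.arg(mode)
  v <- blockValues(block)
  if (any(v <= 0, na.rm = TRUE))
    stop("normalizeBlock: raw values must be strictly positive")
  if (mode == "log_median") {
    lv <- log2(v)
    med <- apply(lv, 2L, stats::median, na.rm = TRUE)
    out <- sweep(lv, 2L, med, "-")
  } else {
    complete <- rowSums(is.na(v)) == 0L
    if (!any(complete))
      stop("normalizeBlock: no complete-case features for reference_geomean")
    gm <- exp(colMeans(log(v[complete, , drop = FALSE])))
    out <- log2(sweep(v, 2L, gm, "/"))
  }
  omicsBlock(blockName(block), out)
}

#' Retain the most variable features
#'
#' Keeps the `n` features with the largest sample variance; ties are broken
#' by feature id in lexicographic order. Requires an imputed (complete)
#' block. Selected features keep their original row order.
#'
#' @param block an [OmicsBlock-class] without missing values.
#' @param n number of features to retain (default 10000).
#' @return filtered [OmicsBlock-class].
#' @export
topVarianceFilter <- function(block, n = 10000L) {
  stopifnot(is(block, "OmicsBlock"))
  if (n <= 0)
    stop("topVarianceFilter: n must be positive")
  v <- blockValues(block)
  if (anyNA(v))
    stop("topVarianceFilter: block must be imputed first")
  if (n >= nrow(v))
    return(block)
  m <- rowMeans(v)
  vars <- rowSums((v - m)^2) / (ncol(v) - 1L)
  ord <- order(-vars, rownames(v))
  keepIds <- rownames(v)[ord[seq_len(n)]]
  keep <- rownames(v) %in% keepIds
  omicsBlock(blockName(block), v[keep, , drop = FALSE])
}

#' Preprocess every block of a dataset
#'
#' Applies the per-layer pipeline: blocks listed in `imputeBlocks` go
#' through missingness filtering then k-NN imputation; blocks listed in
#' `varianceFilterBlocks` (already complete, e.g. arrays) go through the
#' top-variance filter. Input blocks are assumed already normalized (or
#' normalize them first with [normalizeBlock()]).
#'
#' @param data a [MultiOmicsDataset-class].
#' @param maxMissingFrac missingness threshold (default 0.5).
#' @param knnK imputation neighbour count (default 7).
#' @param topNVariance feature budget for variance filtering (default
#'   10000).
#' @param imputeBlocks names of blocks to filter+impute; default: all
#'   blocks containing missing values.
#' @param varianceFilterBlocks names of blocks to variance-filter; default:
#'   all complete blocks.
#' @return list with `data` (preprocessed [MultiOmicsDataset-class]) and
#'   `report` (per-block counts of retained/discarded features).
#' @export
preprocessDataset <- function(data, maxMissingFrac = 0.5, knnK = 7L,
                              topNVariance = 10000L,
                              imputeBlocks = NULL,
                              varianceFilterBlocks = NULL) {
  bl <- blocks(data)
  hasNA <- vapply(bl, function(b) anyNA(blockValues(b)), logical(1))
  if (is.null(imputeBlocks)) imputeBlocks <- names(bl)[hasNA]
  if (is.null(varianceFilterBlocks))
    varianceFilterBlocks <- setdiff(names(bl), imputeBlocks)
  report <- list()
  out <- list()
  for (nm in names(bl)) {
    b <- bl[[nm]]
    if (nm %in% imputeBlocks) {
      fm <- filterMissing(b, maxMissingFrac)
      b <- knnImpute(fm$block, knnK)
      report[[nm]] <- list(retained = length(featureIds(b)),
                           discarded = length(fm$discarded),
                           discardedIds = fm$discarded)
    } else if (nm %in% varianceFilterBlocks) {
      before <- length(featureIds(b))
      b <- topVarianceFilter(b, topNVariance)
      report[[nm]] <- list(retained = length(featureIds(b)),
                           discarded = before - length(featureIds(b)),
                           discardedIds = character())
    } else {
      report[[nm]] <- list(retained = length(featureIds(b)), discarded = 0L,
                           discardedIds = character())
    }
    out[[nm]] <- b
  }
  list(data = multiOmicsDataset(out, phenotype(data), patientIds(data),
                                traitTable(data)),
       report = report)
}
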