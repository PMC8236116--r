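## Model selection: tuning grids, BER, AUC, stratified repeated
## cross-validation, and greedy keepX/ncomp tuning.

#' Enumerate a piecewise feature-count grid
#'
#' Expands a list of `(from, to, by)` ranges into the sorted distinct
#' integers they imply (boundary values deduplicated).
#'
#' @param pieces list of numeric triples `c(from, to, by)`.
#' @return sorted distinct integer vector.
#' @examples
#' length(enumerateGrid(list(c(10, 50, 5), c(50, 100, 10))))  # 14
#' @export
enumerateGrid <- function(pieces) {
  if (length(pieces) == 0L)
    stop("enumerateGrid: empty grid specification")
  vals <- unlist(lapply(pieces, function(p) {
    stopifnot(length(p) == 3L, p[3L] > 0, p[2L] >= p[1L])
    seq(p[1L], p[2L], by = p[3L])
  }))
  sort(unique(as.integer(vals)))
}

#' The integrative-model keepX grid (10 to 100)
#'
#' 10 to 50 in steps of five then 50 to 100 in steps of ten: 14 distinct
#' candidate feature counts per component per omics block.
#' @return integer vector of 14 candidates.
#' @export
integrativeGrid <- function() {
  enumerateGrid(list(c(10, 50, 5), c(50, 100, 10)))
}

#' The single-omics keepX grid (3 to 300)
#'
#' 3-30 by 3, 30-60 by 6, 60-150 by 15, 150-300 by 30; 26 distinct
#' candidates after boundary deduplication.
#' @return integer vector of 26 candidates.
#' @export
singleOmicsGrid <- function() {
  enumerateGrid(list(c(3, 30, 3), c(30, 60, 6), c(60, 150, 15),
                     c(150, 300, 30)))
}

#' Balanced error rate
#'
#' Mean over classes of the within-class misclassification rate; robust to
#' class imbalance.
#' @param yTrue true labels (both classes must be present).
#' @param yPred predicted labels on the same levels.
#' @return BER in `[0,1]`.
#' @examples
#' balancedErrorRate(rep(c("a","b"), c(16, 26)),
#'                   rep(c("b","b"), c(16, 26)))  # 0.5
#' @export
balancedErrorRate <- function(yTrue, yPred) {
  yTrue <- as.factor(yTrue)
  lev <- levels(yTrue)
  if (any(tabulate(yTrue, nbins = length(lev)) == 0L))
    stop("balancedErrorRate: a class is absent from yTrue")
  yPred <- factor(as.character(yPred), levels = lev)
  errs <- vapply(lev, function(cl)
    mean(yPred[yTrue == cl] != cl), numeric(1))
  mean(errs)
}

#' Rank-statistic AUC
#'
#' Exact pairwise AUC: `P(score_pos > score_neg) + 0.5 P(tie)`, equivalent
#' to the Mann-Whitney statistic. Invariant to strictly monotone transforms
#' of the scores.
#' @param yTrue true labels; the second factor level is the positive class.
#' @param scores continuous score, higher = more positive.
#' @return AUC in `[0,1]`.
#' @examples
#' aucScore(factor(rep(c("n","p"), each = 2), levels = c("n","p")),
#'          c(0.5, 0.1, 0.9, 0.4))  # 0.75
#' @export
aucScore <- function(yTrue, scores) {
  yTrue <- as.factor(yTrue)
  if (nlevels(yTrue) != 2L || any(tabulate(yTrue, 2L) == 0L))
    stop("aucScore: both classes must be present")
  pos <- scores[yTrue == levels(yTrue)[2L]]
  neg <- scores[yTrue == levels(yTrue)[1L]]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Stratified fold assignment
#'
#' Shuffles each class and deals it round-robin into `k` folds, so per-class
#' fold sizes differ by at most one.
#' @param y labels.
#' @param k fold count.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratifiedFolds <- function(y, k, seed) {
  y <- as.factor(y)
  if (any(table(y) < k))
    stop("stratifiedFolds: a class has fewer members than folds")
  withSeed(seed, {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Stratified repeated cross-validation of a (multi)block sPLS-DA model
#'
#' Per repeat, samples are split into stratified folds (repeat `r` uses the
#' derived seed `seed + r`); per fold the model is fitted on the training
#' portion only -- feature scaling is re-estimated inside the fold -- and
#' the held-out samples are scored. BER, accuracy, and AUC (from the
#' aggregated positive-class score) are computed per fold and averaged over
#' folds and repeats.
#'
#' @param data a complete [MultiOmicsDataset-class].
#' @param ncomp,keepX,design model parameters passed to
#'   [fitBlockSplsda()].
#' @param nFolds fold count (default 5).
#' @param nRepeats repeat count.
#' @param seed base seed.
#' @return list with `berMean`, `berSd`, `accuracyMean`, `accuracySd`,
#'   `aucMean`, `aucSd`, the per-fold tables `folds`, and `nFolds`,
#'   `nRepeats`, `seed`.
#' @export
cvBlockSplsda <- function(data, ncomp, keepX = NULL, design = NULL,
                          nFolds = 5L, nRepeats = 10L, seed = 1L) {
  y <- phenotype(data)
  if (is.null(design))
    design <- makeDesign(names(blocks(data)))
  rows <- list()
  for (r in seq_len(nRepeats)) {
    fold <- stratifiedFolds(y, nFolds, seed + r)
    for (f in seq_len(nFolds)) {
      test <- which(fold == f)
      train <- which(fold != f)
      fit <- fitBlockSplsda(subsetSamples(data, train), design = design,
                            ncomp = ncomp, keepX = keepX)
      pr <- predict(fit, subsetSamples(data, test))
      yt <- y[test]
      rows[[length(rows) + 1L]] <- data.frame(
        repeatIdx = r, fold = f,
        ber = balancedErrorRate(yt, pr$label),
        accuracy = mean(pr$label == yt),
        auc = if (nlevels(droplevels(yt)) == 2L) aucScore(yt, pr$score)
              else NA_real_)
    }
  }
  folds <- do.call(rbind, rows)
  list(berMean = mean(folds$ber), berSd = stats::sd(folds$ber),
       accuracyMean = mean(folds$accuracy),
       accuracySd = stats::sd(folds$accuracy),
       aucMean = mean(folds$auc, na.rm = TRUE),
       aucSd = stats::sd(folds$auc, na.rm = TRUE),
       folds = folds, nFolds = nFolds, nRepeats = nRepeats, seed = seed)
}

#' Tune keepX and the component count by cross-validated BER
#'
#' Greedy per-component search: for component `h`, earlier components'
#' budgets are fixed and each candidate is scanned (for the integrative
#' model one shared candidate value is applied to every block, keeping the
#' scan linear in the grid size); the candidate minimizing mean CV BER is
#' chosen, with ties broken towards the smaller budget. The component count
#' minimizing the running BER is returned (ties towards fewer components).
#'
#' @param data a complete [MultiOmicsDataset-class].
#' @param candidates integer vector of keepX candidates (e.g.
#'   [integrativeGrid()] or [singleOmicsGrid()]).
#' @param maxNcomp largest component count to consider (default 2; the
#'   search is sequential so earlier components are unaffected by later
#'   ones).
#' @param design optional design matrix.
#' @param nFolds,nRepeats,seed cross-validation control.
#' @return list with `ncomp`, `keepX` (named list per block), `berByComp`,
#'   and `surface` (data.frame of the full CV surface: component,
#'   candidate, mean/sd BER, mean accuracy, mean AUC).
#' @export
tuneKeepX <- function(data, candidates, maxNcomp = 2L, design = NULL,
                      nFolds = 5L, nRepeats = 10L, seed = 1L) {
  if (length(candidates) == 0L)
    stop("tuneKeepX: empty candidate grid")
  bn <- names(blocks(data))
  pMin <- min(vapply(blocks(data), function(b) nrow(blockValues(b)),
                     numeric(1)))
  candidates <- sort(unique(pmin(as.integer(candidates), pMin)))
  chosen <- c()
  surface <- list()
  berByComp <- numeric(maxNcomp)
  for (h in seq_len(maxNcomp)) {
    best <- NULL
    for (cand in candidates) {
      kx <- stats::setNames(rep(list(c(chosen, cand)), length(bn)), bn)
      cv <- cvBlockSplsda(data, ncomp = h, keepX = kx, design = design,
                          nFolds = nFolds, nRepeats = nRepeats,
                          seed = seed)
      surface[[length(surface) + 1L]] <- data.frame(
        comp = h, keepX = cand, berMean = cv$berMean, berSd = cv$berSd,
        accuracyMean = cv$accuracyMean, aucMean = cv$aucMean)
      if (is.null(best) || cv$berMean < best$ber - 1e-12)
        best <- list(cand = cand, ber = cv$berMean)
    }
    chosen <- c(chosen, best$cand)
    berByComp[h] <- best$ber
  }
  ncompOpt <- which.min(berByComp)  # ties -> smaller ncomp
  list(ncomp = ncompOpt,
       keepX = stats::setNames(rep(list(chosen[seq_len(ncompOpt)]),
                                   length(bn)), bn),
       berByComp = berByComp, surface = do.call(rbind, surface))
}
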