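## Signature validation on an independent cohort: subsetting by symbol,
## stratified repeated CV with three classifiers, and signature
## comparison.

#' Subset a cohort block to a signature's symbols
#'
#' Retains cohort features whose gene symbol appears in the signature;
#' duplicate symbols keep all matching features. Reports the fraction of
#' signature symbols covered by the cohort.
#' @param block cohort [OmicsBlock-class] (features x samples).
#' @param signatureSymbols character vector of signature symbols.
#' @param symbolMap optional data.frame `feature_id`/`symbol`; by default
#'   the cohort's feature ids are themselves symbols.
#' @return list with `block` (subset) and `coverage` (covered / signature
#'   size).
#' @export
subsetToSignature <- function(block, signatureSymbols, symbolMap = NULL) {
  if (length(signatureSymbols) == 0L)
    stop("subsetToSignature: empty signature")
  v <- blockValues(block)
  sym <- if (is.null(symbolMap)) rownames(v)
         else symbolMap$symbol[match(rownames(v), symbolMap$feature_id)]
  keep <- !is.na(sym) & sym %in% signatureSymbols
  if (!any(keep))
    stop("subsetToSignature: signature has zero overlap with the cohort")
  covered <- length(intersect(unique(sym[keep]), signatureSymbols))
  list(block = omicsBlock(blockName(block), v[keep, , drop = FALSE]),
       coverage = covered / length(unique(signatureSymbols)))
}

## fit one classifier on standardized training data, return a scoring
## closure: score(Xnew) -> positive-class continuous score
.fitClassifier <- function(classifier, Xtr, ytr) {
  lev <- levels(ytr)
  switch(classifier,
    logistic = {
      ## L2-penalized logistic (ridge, small fixed lambda): well-posed at
      ## p >> n, mirroring penalized solvers in common ML toolkits
      fit <- glmnet::glmnet(Xtr, ytr, family = "binomial", alpha = 0,
                            lambda = 1 / nrow(Xtr), standardize = FALSE)
      function(Xnew)
        drop(stats::predict(fit, Xnew, type = "link"))
    },
    svm_rbf = {
      fit <- e1071::svm(Xtr, ytr, kernel = "radial",
                        gamma = 1 / ncol(Xtr), scale = FALSE)
      function(Xnew) {
        dv <- drop(attr(stats::predict(fit, Xnew, decision.values = TRUE),
                        "decision.values"))
        ## decision value is oriented towards the first training level seen;
        ## orient towards the positive (second) class
        if (grepl(paste0("^", lev[2L], "/"), colnames(
              attr(stats::predict(fit, Xtr[1, , drop = FALSE],
                                  decision.values = TRUE),
                   "decision.values"))[1L]))
          dv else -dv
      }
    },
    decision_tree = {
      df <- data.frame(.y = ytr, Xtr, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class")
      function(Xnew)
        stats::predict(fit, data.frame(Xnew, check.names = FALSE),
                       type = "prob")[, lev[2L]]
    },
    stop("unknown classifier: ", classifier))
}

#' Evaluate a signature's predictive power on a cohort
#'
#' Stratified `nFolds`-fold cross-validation with `nRepeats` repeats: per
#' fold, features are standardized on the training fold only, the chosen
#' classifier is fitted, and held-out samples are scored; accuracy (at a
#' score threshold equivalent to the classifier's label rule) and AUC are
#' computed per fold and summarized as mean and SD over all folds x
#' repeats. Degenerate folds where the classifier fails are skipped with a
#' warning.
#'
#' @param block cohort [OmicsBlock-class], already subset to the signature
#'   (see [subsetToSignature()]).
#' @param y binary labels; second level = positive class.
#' @param classifier `"logistic"` (ridge-penalized), `"svm_rbf"`
#'   (`gamma = 1/n_features`), or `"decision_tree"` (defaults).
#' @param nFolds folds (default 5).
#' @param nRepeats repeats (default 50).
#' @param seed base seed; repeat `r` uses `seed + r`.
#' @return list (`PerformanceSummary`) with `accuracyMean`, `accuracySd`,
#'   `aucMean`, `aucSd`, `nFolds`, `nRepeats`, `perRepeatAuc`, `folds`.
#' @export
evaluateSignature <- function(block, y,
                              classifier = c("logistic", "svm_rbf",
                                             "decision_tree"),
                              nFolds = 5L, nRepeats = 50L, seed = 1L) {
  classifier <- match.arg(classifier)
  y <- as.factor(y)
  stopifnot(nlevels(y) == 2L)
  X <- t(blockValues(block))   # samples x features
  rows <- list()
  for (r in seq_len(nRepeats)) {
    fold <- stratifiedFolds(y, nFolds, seed + r)
    for (f in seq_len(nFolds)) {
      te <- fold == f; tr <- !te
      ctr <- colMeans(X[tr, , drop = FALSE])
      sc <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
      sc[sc == 0] <- 1
      Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2L, ctr, "-"), 2L, sc, "/")
      Xte <- sweep(sweep(X[te, , drop = FALSE], 2L, ctr, "-"), 2L, sc, "/")
      res <- tryCatch({
        scoreFn <- .fitClassifier(classifier, Xtr, y[tr])
        s <- scoreFn(Xte)
        thr <- if (classifier == "decision_tree") 0.5 else 0
        pred <- factor(levels(y)[(s > thr) + 1L], levels = levels(y))
        yt <- y[te]
        data.frame(repeatIdx = r, fold = f,
                   accuracy = mean(pred == yt),
                   auc = if (nlevels(droplevels(yt)) == 2L)
                           aucScore(yt, s) else NA_real_)
      }, error = function(e) {
        warning(sprintf("fold %d of repeat %d skipped: %s", f, r,
                        conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  folds <- do.call(rbind, rows)
  perRepeat <- tapply(folds$auc, folds$repeatIdx,
                      function(a) mean(a, na.rm = TRUE))
  list(accuracyMean = mean(folds$accuracy),
       accuracySd = stats::sd(folds$accuracy),
       aucMean = mean(folds$auc, na.rm = TRUE),
       aucSd = stats::sd(folds$auc, na.rm = TRUE),
       nFolds = nFolds, nRepeats = nRepeats,
       perRepeatAuc = as.numeric(perRepeat), folds = folds,
       classifier = classifier)
}

#' Compare several signatures (and the full-data baseline) on a cohort
#'
#' Evaluates each signature with each classifier under identical seeds
#' (shared fold assignments), adds a `FULL` baseline using every cohort
#' feature, and reports mean +/- SD accuracy and AUC per configuration.
#' Per-repeat AUC vectors are kept so configurations can be compared with
#' [signatureTTest()].
#'
#' @param block cohort [OmicsBlock-class]; rownames must be mappable to
#'   symbols via `symbolMap` (or be symbols).
#' @param y binary labels.
#' @param signatures named list of symbol vectors.
#' @param classifiers classifier names (see [evaluateSignature()]).
#' @param symbolMap optional feature-to-symbol map.
#' @param includeFull add the all-features baseline (default TRUE).
#' @param nFolds,nRepeats,seed CV control.
#' @return data.frame with one row per (signature, classifier); attribute
#'   `aucRuns` holds per-configuration per-repeat AUCs.
#' @export
compareSignatures <- function(block, y, signatures,
                              classifiers = "logistic",
                              symbolMap = NULL, includeFull = TRUE,
                              nFolds = 5L, nRepeats = 20L, seed = 1L) {
  if (length(signatures) < 1L)
    stop("compareSignatures: supply at least one signature")
  cfgBlocks <- lapply(signatures, function(s)
    subsetToSignature(block, s, symbolMap)$block)
  if (includeFull)
    cfgBlocks <- c(cfgBlocks, list(FULL = block))
  rows <- list(); runs <- list()
  for (nm in names(cfgBlocks)) {
    for (cl in classifiers) {
      res <- evaluateSignature(cfgBlocks[[nm]], y, classifier = cl,
                               nFolds = nFolds, nRepeats = nRepeats,
                               seed = seed)
      key <- paste(nm, cl, sep = ":")
      runs[[key]] <- res$perRepeatAuc
      rows[[key]] <- data.frame(
        signature = nm, classifier = cl, nFeatures = length(
          featureIds(cfgBlocks[[nm]])),
        accuracyMean = res$accuracyMean, accuracySd = res$accuracySd,
        aucMean = res$aucMean, aucSd = res$aucSd,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "aucRuns") <- runs
  out
}

#' t test between two configurations' per-repeat AUCs
#'
#' Two-sided Student's t test on the per-repeat AUC vectors of two
#' configurations from [compareSignatures()]. Identical vectors (e.g. the
#' same signature compared with itself under the same seeds) return p = 1.
#' @param comparison output of [compareSignatures()].
#' @param config1,config2 configuration keys (`"<signature>:<classifier>"`).
#' @return list with `p`, `meanDiff`.
#' @export
signatureTTest <- function(comparison, config1, config2) {
  runs <- attr(comparison, "aucRuns")
  a <- runs[[config1]]; b <- runs[[config2]]
  if (is.null(a) || is.null(b))
    stop("unknown configuration key; available: ",
         paste(names(runs), collapse = ", "))
  if (isTRUE(all.equal(a, b)) || (stats::sd(a) == 0 && stats::sd(b) == 0))
    return(list(p = 1, meanDiff = mean(a) - mean(b)))
  tt <- stats::t.test(a, b)
  list(p = tt$p.value, meanDiff = mean(a) - mean(b))
}
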