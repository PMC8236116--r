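## Sparse PLS-DA core: soft-thresholded loading selection, single-block
## and design-coupled multiblock fits, and prediction.

#' Soft-thresholded sparse unit vector
#'
#' LASSO-style selection of a loading direction: the threshold is the
#' `(keep+1)`-th largest absolute entry (zero when `keep` covers the whole
#' vector); entries are shrunk towards zero by that threshold
#' (`sign(v) * max(|v| - lambda, 0)`) and the result is scaled to unit
#' Euclidean norm. When the absolute values are distinct the result has
#' exactly `keep` nonzeros; boundary ties (entries equal to the threshold)
#' are shrunk to zero, with entry order deciding which values enter the
#' top-`keep` set.
#'
#' @param v numeric vector, not all zero.
#' @param keep number of entries to retain (`>= 1`).
#' @return unit-norm numeric vector of the same length.
#' @examples
#' softSelect(c(3, -2, 1), 2)   # (2, -1, 0) / sqrt(5)
#' @export
softSelect <- function(v, keep) {
  if (keep < 1)
    stop("softSelect: keep must be >= 1")
  av <- abs(v)
  if (all(av == 0))
    stop("softSelect: input vector is all zero")
  lambda <- if (keep >= length(v)) 0 else sort(av, decreasing = TRUE)[keep + 1L]
  out <- sign(v) * pmax(av - lambda, 0)
  nrm <- sqrt(sum(out^2))
  if (nrm == 0) {
    ## complete tie at the threshold: fall back to the top-keep entries by
    ## (magnitude, index), unshrunk, to keep the operation total
    idx <- order(-av, seq_along(v))[seq_len(min(keep, length(v)))]
    out <- numeric(length(v))
    out[idx] <- v[idx]
    nrm <- sqrt(sum(out^2))
  }
  out / nrm
}

## centered one-column-per-class indicator matrix
.outcomeIndicator <- function(y) {
  y <- as.factor(y)
  if (nlevels(y) != 2L)
    stop("binary phenotype required (exactly 2 levels)")
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  scale(Y, center = TRUE, scale = FALSE)
}

## per-feature center/unit-variance scale of an n x p matrix;
## constant features get scale 1 (and become all-zero columns)
.scaleTrain <- function(X) {
  ctr <- colMeans(X)
  sc <- apply(X, 2L, stats::sd)
  sc[sc == 0] <- 1
  list(x = sweep(sweep(X, 2L, ctr, "-"), 2L, sc, "/"), center = ctr,
       scale = sc)
}

## normalize keepX input to a named list of length-ncomp integer vectors
.normKeepX <- function(keepX, blockNames, pPerBlock, ncomp) {
  if (is.null(keepX))
    keepX <- as.list(pPerBlock)
  if (!is.list(keepX))
    keepX <- stats::setNames(rep(list(keepX), length(blockNames)), blockNames)
  out <- list()
  for (b in blockNames) {
    k <- keepX[[b]]
    if (is.null(k)) k <- pPerBlock[[b]]
    if (length(k) == 1L) k <- rep(k, ncomp)
    if (length(k) != ncomp)
      stop("keepX for block '", b, "' must have length 1 or ncomp")
    out[[b]] <- pmin(as.integer(k), pPerBlock[[b]])
  }
  out
}

## core NIPALS-style cyclic fit shared by fitSplsda and fitBlockSplsda.
## Xs: named list of scaled n x p matrices; design includes the outcome
## as last row/column.
.blockSplsdaCore <- function(Xs, Yc, design, ncomp, keepX, tol, maxIter) {
  bn <- names(Xs)
  n <- nrow(Yc)
  loadings <- lapply(Xs, function(X)
    matrix(0, ncol(X), ncomp, dimnames = list(colnames(X), NULL)))
  projection <- loadings
  scores <- lapply(Xs, function(X) matrix(0, n, ncomp,
                                          dimnames = list(rownames(X), NULL)))
  outW <- matrix(0, 2L, ncomp, dimnames = list(colnames(Yc), NULL))
  Xd <- Xs
  for (h in seq_len(ncomp)) {
    a <- lapply(bn, function(b) {
      M <- crossprod(Xd[[b]], Yc)
      svd(M, nu = 1L, nv = 0L)$u[, 1L]
    })
    names(a) <- bn
    tt <- lapply(bn, function(b) drop(Xd[[b]] %*% a[[b]]))
    names(tt) <- bn
    by <- numeric(2L)
    for (b in bn) by <- by + design["outcome", b] * drop(crossprod(Yc, tt[[b]]))
    by <- by / sqrt(sum(by^2))
    u <- drop(Yc %*% by)
    converged <- FALSE
    ## iterate the natural cyclic map; the sign convention is applied once
    ## after convergence (flipping a, t and p jointly), because forcing an
    ## orientation inside the loop perturbs the coupled fixed point
    for (it in seq_len(maxIter)) {
      maxDelta <- 0
      for (b in bn) {
        dir <- design[b, "outcome"] * drop(crossprod(Xd[[b]], u))
        for (j in setdiff(bn, b)) {
          w <- design[b, j]
          if (w > 0) dir <- dir + w * drop(crossprod(Xd[[b]], tt[[j]]))
        }
        aNew <- softSelect(dir, keepX[[b]][h])
        maxDelta <- max(maxDelta, max(abs(aNew - a[[b]])))
        a[[b]] <- aNew
        tt[[b]] <- drop(Xd[[b]] %*% aNew)
      }
      by <- numeric(2L)
      for (b in bn) by <- by + design["outcome", b] * drop(crossprod(Yc, tt[[b]]))
      by <- by / sqrt(sum(by^2))
      u <- drop(Yc %*% by)
      if (maxDelta < tol) { converged <- TRUE; break }
    }
    ## sparse updates can land in a near-stationary limit cycle where one
    ## or two boundary features flip support with a sub-tolerance loading
    ## change; accept those as converged, error on genuine divergence
    if (!converged && maxDelta < sqrt(tol))
      converged <- TRUE
    if (!converged) {
      e <- simpleError(sprintf(
        "sparse PLS-DA did not converge within %d iterations at component %d (last max loading change %.3g)",
        maxIter, h, maxDelta))
      e$lastIterate <- list(loadings = a, scores = tt, component = h)
      stop(e)
    }
    for (b in bn) {
      ## deterministic orientation: largest-|loading| entry positive;
      ## a, t (and hence p) flip together so the model is unchanged
      if (a[[b]][which.max(abs(a[[b]]))] < 0) {
        a[[b]] <- -a[[b]]
        tt[[b]] <- -tt[[b]]
      }
      loadings[[b]][, h] <- a[[b]]
      scores[[b]][, h] <- tt[[b]]
      ss <- sum(tt[[b]]^2)
      p <- if (ss > 0) drop(crossprod(Xd[[b]], tt[[b]])) / ss
           else numeric(ncol(Xd[[b]]))
      projection[[b]][, h] <- p
      Xd[[b]] <- Xd[[b]] - tcrossprod(tt[[b]], p)
    }
    outW[, h] <- by
  }
  list(loadings = loadings, scores = scores, projection = projection,
       outcomeWeights = outW)
}

#' Fit a single-block sparse PLS-DA model
#'
#' Supervised projection of one omics block onto `ncomp` latent components
#' with LASSO-style sparse loadings. The phenotype is expanded to a
#' centered indicator matrix; per component the loading is the
#' soft-thresholded covariance direction between the (deflated) block and
#' the outcome score, iterated to convergence, after which the block is
#' deflated by regression on its own score. Features are centered and
#' unit-variance scaled internally; the scaling is stored for prediction.
#'
#' @param x an [OmicsBlock-class] or a feature x sample numeric matrix.
#' @param y binary phenotype (two-level factor; second level = positive
#'   class).
#' @param ncomp number of components.
#' @param keepX per-component nonzero-loading budget: a single value
#'   (recycled) or vector of length `ncomp`; default all features.
#' @param tol convergence tolerance on the maximum loading change.
#' @param maxIter maximum iterations per component.
#' @return a [BlockSplsdaModel-class] with a single block.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(200), 10, 20,
#'   dimnames = list(paste0("f", 1:10), paste0("s", 1:20)))
#' m[1, ] <- m[1, ] + rep(c(0, 3), each = 10)
#' fit <- fitSplsda(m, rep(c("a", "b"), each = 10), ncomp = 1, keepX = 1)
#' selectedFeatures(fit)
#' @export
fitSplsda <- function(x, y, ncomp = 1L, keepX = NULL, tol = 1e-6,
                      maxIter = 100L) {
  if (is(x, "OmicsBlock")) {
    nm <- blockName(x); v <- blockValues(x)
  } else {
    nm <- "X"; v <- as.matrix(x)
    if (is.null(rownames(v))) rownames(v) <- paste0("f", seq_len(nrow(v)))
    if (is.null(colnames(v))) colnames(v) <- paste0("s", seq_len(ncol(v)))
  }
  ds <- multiOmicsDataset(stats::setNames(list(omicsBlock(nm, v)), nm), y)
  design <- makeDesign(nm)
  fitBlockSplsda(ds, design = design, ncomp = ncomp,
                 keepX = stats::setNames(list(keepX %||% nrow(v)), nm),
                 tol = tol, maxIter = maxIter)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a design-coupled multiblock sparse PLS-DA model
#'
#' Integrative classification across several aligned omics blocks. Per
#' component, block loadings are updated cyclically: the update direction
#' for block *b* is the design-weighted sum of its covariances with the
#' other blocks' scores and with the outcome score, passed through
#' [softSelect()] at that block's keepX budget; outcome-side weights are
#' refreshed from the block scores after each sweep, and the cycle repeats
#' until the largest loading change falls below `tol`. Each block is then
#' deflated by regression on its own score; the outcome indicator is not
#' deflated (with a binary phenotype the centered indicator has rank one,
#' so deflating it would annihilate the outcome after the first
#' component).
#'
#' @param data a [MultiOmicsDataset-class] without missing values.
#' @param design coupling design matrix over blocks plus `"outcome"` (see
#'   [makeDesign()]); symmetric, zero diagonal, entries in `[0,1]`, outcome
#'   row strictly positive.
#' @param ncomp number of components.
#' @param keepX named list (per block) of per-component budgets; single
#'   values are recycled across components; default all features.
#' @param tol,maxIter convergence control: iteration stops when the
#'   largest loading change falls below `tol`; if `maxIter` is reached
#'   with the change still below `sqrt(tol)` (a boundary-feature limit
#'   cycle) the fit is accepted, otherwise an error is raised.
#' @return a [BlockSplsdaModel-class].
#' @seealso [fitSplsda()], [predict,BlockSplsdaModel-method]
#' @export
fitBlockSplsda <- function(data, design = NULL, ncomp = 1L, keepX = NULL,
                           tol = 1e-6, maxIter = 100L) {
  stopifnot(is(data, "MultiOmicsDataset"))
  bl <- blocks(data)
  bn <- names(bl)
  if (is.null(design))
    design <- makeDesign(bn)
  .checkDesign(design, bn)
  y <- phenotype(data)
  for (b in bl)
    if (anyNA(blockValues(b)))
      stop("fitBlockSplsda: block '", blockName(b),
           "' contains missing values; impute first")
  Yc <- .outcomeIndicator(y)
  scaled <- lapply(bl, function(b) .scaleTrain(t(blockValues(b))))
  Xs <- lapply(scaled, `[[`, "x")
  pPerBlock <- lapply(Xs, ncol)
  keepX <- .normKeepX(keepX, bn, pPerBlock, ncomp)
  core <- .blockSplsdaCore(Xs, Yc, design, as.integer(ncomp), keepX, tol,
                           maxIter)
  new("BlockSplsdaModel", blockNames = bn, loadings = core$loadings,
      scores = core$scores, projection = core$projection,
      outcomeWeights = core$outcomeWeights,
      centers = lapply(scaled, `[[`, "center"),
      scales = lapply(scaled, `[[`, "scale"),
      keepX = keepX, ncomp = as.integer(ncomp),
      design = design, classLevels = levels(y), yTrain = y)
}

.checkDesign <- function(design, blockNames) {
  need <- c(blockNames, "outcome")
  if (!all(need %in% rownames(design)) || !all(need %in% colnames(design)))
    stop("design must cover all blocks plus 'outcome'")
  if (any(design < 0) || any(design > 1))
    stop("design entries must lie in [0, 1]")
  if (!isTRUE(all.equal(design, t(design))))
    stop("design must be symmetric")
  if (any(diag(design) != 0))
    stop("design diagonal must be zero")
  if (any(design["outcome", blockNames] <= 0))
    stop("every block must be connected to the outcome")
  invisible(TRUE)
}

#' Predict class membership for new samples
#'
#' Projects new samples into each block's latent space using the stored
#' feature scaling and sequential deflation, regresses the training
#' indicator matrix on the training scores to obtain per-block predicted
#' indicator values, assigns per-block labels by the maximum predicted
#' indicator ("max.dist"), and averages the per-block indicator values with
#' the design's block-outcome weights into the aggregated score used for
#' the final label and for AUC.
#'
#' @param object a [BlockSplsdaModel-class].
#' @param newdata a [MultiOmicsDataset-class] or named list of
#'   [OmicsBlock-class]/matrices (features x samples) carrying all features
#'   the model was fitted on.
#' @param ... unused.
#' @return list with `blockScores` (latent coordinates per block),
#'   `blockIndicator`, `blockLabels`, `aggregated` (samples x classes),
#'   `label` (factor), and `score` (aggregated positive-class indicator
#'   value, for AUC).
#' @export
setMethod("predict", "BlockSplsdaModel", function(object, newdata, ...) {
  if (is(newdata, "MultiOmicsDataset"))
    newdata <- blocks(newdata)
  if (is.null(names(newdata)))
    stop("newdata blocks must be named")
  Yc <- .outcomeIndicator(object@yTrain)
  prop <- colMeans(stats::model.matrix(~ object@yTrain - 1))
  names(prop) <- object@classLevels
  blockInd <- list()
  blockScores <- list()
  wSum <- 0
  agg <- NULL
  for (b in object@blockNames) {
    nb <- newdata[[b]]
    if (is.null(nb))
      stop("newdata lacks block '", b, "'")
    v <- if (is(nb, "OmicsBlock")) blockValues(nb) else as.matrix(nb)
    fid <- names(object@centers[[b]])
    if (!all(fid %in% rownames(v)))
      stop("newdata block '", b, "' lacks ",
           sum(!fid %in% rownames(v)), " model feature(s)")
    X <- t(v[fid, , drop = FALSE])
    X <- sweep(sweep(X, 2L, object@centers[[b]], "-"), 2L,
               object@scales[[b]], "/")
    H <- object@ncomp
    Tnew <- matrix(0, nrow(X), H)
    for (h in seq_len(H)) {
      Tnew[, h] <- X %*% object@loadings[[b]][, h]
      X <- X - tcrossprod(Tnew[, h], object@projection[[b]][, h])
    }
    Ttr <- object@scores[[b]]
    B <- solve(crossprod(Ttr), crossprod(Ttr, Yc))
    pred <- Tnew %*% B + matrix(prop, nrow(Tnew), 2L, byrow = TRUE)
    colnames(pred) <- object@classLevels
    rownames(pred) <- rownames(X)
    blockInd[[b]] <- pred
    rownames(Tnew) <- rownames(X)
    blockScores[[b]] <- Tnew
    w <- object@design[b, "outcome"]
    agg <- if (is.null(agg)) w * pred else agg + w * pred
    wSum <- wSum + w
  }
  agg <- agg / wSum
  blockLabels <- lapply(blockInd, function(p)
    factor(object@classLevels[max.col(p, ties.method = "first")],
           levels = object@classLevels))
  label <- factor(object@classLevels[max.col(agg, ties.method = "first")],
                  levels = object@classLevels)
  list(blockScores = blockScores, blockIndicator = blockInd,
       blockLabels = blockLabels, aggregated = agg, label = label,
       score = agg[, object@classLevels[2L]])
})
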