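#' @import methods
#' @importFrom stats var sd cor median rnorm runif rbinom quantile
NULL

#' OmicsBlock: one omics layer
#'
#' Container for a single omics layer as a feature x sample numeric matrix.
#' Missing measurements are encoded as `NA`; the missingness mask is therefore
#' `is.na(blockValues(x))`. Feature and sample identifiers are the matrix
#' dimnames and must be unique.
#'
#' @slot name single string labelling the layer (e.g. `"gene"`, `"protein"`).
#' @slot values numeric feature x sample matrix with unique dimnames; `NA`
#'   marks a missing measurement.
#'
#' @seealso [omicsBlock()] for the constructor, [filterMissing()],
#'   [knnImpute()], [normalizeBlock()], [topVarianceFilter()].
#' @export
setClass("OmicsBlock",
  representation(name = "character", values = "matrix"))

setValidity("OmicsBlock", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  v <- object@values
  if (!is.numeric(v))
    msg <- c(msg, "'values' must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "'values' must have feature rownames and sample colnames")
  else {
    if (anyDuplicated(rownames(v)))
      msg <- c(msg, "duplicate feature ids")
    if (anyDuplicated(colnames(v)))
      msg <- c(msg, "duplicate sample ids")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsBlock
#'
#' @param name block label.
#' @param values numeric feature x sample matrix; `NA` encodes missing
#'   entries. Must carry unique rownames (feature ids) and colnames
#'   (sample ids).
#' @return an [OmicsBlock-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
#' omicsBlock("protein", m)
#' @export
omicsBlock <- function(name, values) {
  new("OmicsBlock", name = name, values = as.matrix(values))
}

#' MultiOmicsDataset: aligned omics blocks with a binary phenotype
#'
#' Holds one or more [OmicsBlock-class] objects measured on the same samples
#' in the same order, the binary phenotype, an optional patient pairing label
#' per sample, and an optional table of continuous per-sample trait
#' covariates.
#'
#' @slot blocks named list of [OmicsBlock-class] objects sharing sample ids
#'   and sample order.
#' @slot y factor with exactly two levels, one value per sample. The second
#'   level is treated as the positive class throughout.
#' @slot patientId character vector of pairing labels (may be empty).
#' @slot traits data.frame of numeric per-sample covariates (may have zero
#'   columns).
#' @seealso [multiOmicsDataset()], [simulateMultiOmics()],
#'   [fitBlockSplsda()].
#' @export
setClass("MultiOmicsDataset",
  representation(blocks = "list", y = "factor",
                 patientId = "character", traits = "data.frame"))

setValidity("MultiOmicsDataset", function(object) {
  msg <- character()
  if (length(object@blocks) < 1L)
    msg <- c(msg, "at least one block required")
  if (is.null(names(object@blocks)) || anyDuplicated(names(object@blocks)))
    msg <- c(msg, "blocks must be uniquely named")
  ok <- vapply(object@blocks, is, logical(1), "OmicsBlock")
  if (!all(ok))
    return("all blocks must be OmicsBlock objects")
  sids <- sampleIds(object@blocks[[1L]])
  for (b in object@blocks) {
    if (!identical(sampleIds(b), sids))
      msg <- c(msg, "all blocks must share identical sample ids in identical order")
  }
  if (nlevels(object@y) != 2L)
    msg <- c(msg, "phenotype must have exactly 2 levels")
  if (length(object@y) != length(sids))
    msg <- c(msg, "phenotype length must equal the number of samples")
  if (length(object@patientId) &&
      length(object@patientId) != length(sids))
    msg <- c(msg, "patientId length must equal the number of samples")
  if (nrow(object@traits) && nrow(object@traits) != length(sids))
    msg <- c(msg, "traits must have one row per sample")
  if (length(msg)) msg else TRUE
})

#' Construct a MultiOmicsDataset
#'
#' @param blocks named list of [OmicsBlock-class] objects with identical
#'   sample ids in identical order.
#' @param y binary phenotype, coerced to a two-level factor; the second
#'   level is the positive class.
#' @param patientId optional pairing label per sample.
#' @param traits optional data.frame of numeric per-sample covariates.
#' @return a [MultiOmicsDataset-class].
#' @export
multiOmicsDataset <- function(blocks, y, patientId = character(),
                              traits = NULL) {
  if (is.null(names(blocks)))
    names(blocks) <- vapply(blocks, blockName, character(1))
  if (is.null(traits))
    traits <- data.frame(row.names = sampleIds(blocks[[1L]]))
  new("MultiOmicsDataset", blocks = blocks, y = as.factor(y),
      patientId = as.character(patientId), traits = traits)
}

#' BlockSplsdaModel: a fitted (multi)block sparse PLS-DA model
#'
#' Returned by [fitSplsda()] and [fitBlockSplsda()]. Stores, per block and
#' component, the unit-norm sparse loading vectors and latent scores, the
#' per-block deflation (projection) loadings needed to project new samples,
#' the outcome-side weights, the per-feature centering/scaling parameters
#' estimated at fit time, the keepX budgets, and the design matrix.
#'
#' @slot blockNames character vector of block names (outcome excluded).
#' @slot loadings named list; per block a p_b x ncomp matrix of sparse
#'   unit-norm loadings.
#' @slot scores named list; per block an n x ncomp matrix of latent scores.
#' @slot projection named list; per block the p_b x ncomp deflation loadings
#'   used to regress out earlier components when projecting new data.
#' @slot outcomeWeights 2 x ncomp matrix of outcome-side weights.
#' @slot centers,scales named lists of per-feature centering and scaling
#'   vectors applied before fitting.
#' @slot keepX named list; per block the integer vector of per-component
#'   nonzero-loading budgets.
#' @slot ncomp integer component count.
#' @slot design coupling design matrix over blocks and outcome.
#' @slot classLevels the two phenotype levels (second = positive class).
#' @slot yTrain training phenotype factor.
#' @export
setClass("BlockSplsdaModel",
  representation(blockNames = "character", loadings = "list",
                 scores = "list", projection = "list",
                 outcomeWeights = "matrix",
                 centers = "list", scales = "list",
                 keepX = "list", ncomp = "integer", design = "matrix",
                 classLevels = "character", yTrain = "factor"))

setValidity("BlockSplsdaModel", function(object) {
  msg <- character()
  if (length(object@classLevels) != 2L)
    msg <- c(msg, "exactly two class levels required")
  if (!identical(names(object@loadings), object@blockNames))
    msg <- c(msg, "loadings must be named by blockNames")
  if (length(msg)) msg else TRUE
})

## ---- generics ----

#' @rdname OmicsBlock-class
#' @param x an object.
#' @export
setGeneric("blockName", function(x) standardGeneric("blockName"))
#' @rdname OmicsBlock-class
#' @export
setGeneric("blockValues", function(x) standardGeneric("blockValues"))
#' @rdname OmicsBlock-class
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname OmicsBlock-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname OmicsBlock-class
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))
#' @rdname MultiOmicsDataset-class
#' @param x an object.
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))
#' @rdname MultiOmicsDataset-class
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))
#' @rdname MultiOmicsDataset-class
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))
#' @rdname MultiOmicsDataset-class
#' @export
setGeneric("traitTable", function(x) standardGeneric("traitTable"))
#' @rdname BlockSplsdaModel-class
#' @param object,x a model.
#' @export
setGeneric("modelLoadings", function(x) standardGeneric("modelLoadings"))
#' @rdname BlockSplsdaModel-class
#' @export
setGeneric("modelScores", function(x) standardGeneric("modelScores"))
#' @rdname BlockSplsdaModel-class
#' @export
setGeneric("selectedFeatures", function(x, ...) standardGeneric("selectedFeatures"))
#' @rdname BlockSplsdaModel-class
#' @export
setGeneric("classCentroids", function(x) standardGeneric("classCentroids"))

## ---- methods ----

#' @rdname OmicsBlock-class
setMethod("blockName", "OmicsBlock", function(x) x@name)
#' @rdname OmicsBlock-class
setMethod("blockValues", "OmicsBlock", function(x) x@values)
#' @rdname OmicsBlock-class
setMethod("featureIds", "OmicsBlock", function(x) rownames(x@values))
#' @rdname OmicsBlock-class
setMethod("sampleIds", "OmicsBlock", function(x) colnames(x@values))
#' @rdname OmicsBlock-class
setMethod("missingMask", "OmicsBlock", function(x) is.na(x@values))

#' @rdname MultiOmicsDataset-class
setMethod("blocks", "MultiOmicsDataset", function(x) x@blocks)
#' @rdname MultiOmicsDataset-class
setMethod("phenotype", "MultiOmicsDataset", function(x) x@y)
#' @rdname MultiOmicsDataset-class
setMethod("patientIds", "MultiOmicsDataset", function(x) x@patientId)
#' @rdname MultiOmicsDataset-class
setMethod("traitTable", "MultiOmicsDataset", function(x) x@traits)
#' @rdname MultiOmicsDataset-class
setMethod("sampleIds", "MultiOmicsDataset",
          function(x) sampleIds(x@blocks[[1L]]))

#' @rdname BlockSplsdaModel-class
setMethod("modelLoadings", "BlockSplsdaModel", function(x) x@loadings)
#' @rdname BlockSplsdaModel-class
setMethod("modelScores", "BlockSplsdaModel", function(x) x@scores)

#' @describeIn BlockSplsdaModel-class feature ids with a nonzero loading,
#'   per block, for component `comp` (default: any component).
#' @param comp component index or `NULL` for any.
#' @param ... unused.
setMethod("selectedFeatures", "BlockSplsdaModel", function(x, comp = NULL, ...) {
  lapply(x@loadings, function(L) {
    if (is.null(comp)) rownames(L)[rowSums(L != 0) > 0]
    else rownames(L)[L[, comp] != 0]
  })
})

#' @describeIn BlockSplsdaModel-class per-block class centroids in latent
#'   score space (classes x components).
setMethod("classCentroids", "BlockSplsdaModel", function(x) {
  lapply(x@scores, function(S) {
    t(vapply(x@classLevels, function(cl)
      colMeans(S[x@yTrain == cl, , drop = FALSE]), numeric(ncol(S))))
  })
})

## ---- show ----

setMethod("show", "OmicsBlock", function(object) {
  v <- object@values
  nmiss <- sum(is.na(v))
  cat(sprintf("OmicsBlock '%s': %d features x %d samples (%.1f%% missing)\n",
              object@name, nrow(v), ncol(v), 100 * nmiss / length(v)))
})

setMethod("show", "MultiOmicsDataset", function(object) {
  cat(sprintf("MultiOmicsDataset: %d samples, %d blocks\n",
              length(object@y), length(object@blocks)))
  for (b in object@blocks) {
    v <- b@values
    cat(sprintf("  %-10s %5d features (%.1f%% missing)\n",
                b@name, nrow(v), 100 * mean(is.na(v))))
  }
  cat("  phenotype: ",
      paste(sprintf("%s=%d", levels(object@y), tabulate(object@y)),
            collapse = ", "), "\n", sep = "")
  if (ncol(object@traits))
    cat("  traits: ", paste(colnames(object@traits), collapse = ", "),
        "\n", sep = "")
})

setMethod("show", "BlockSplsdaModel", function(object) {
  cat(sprintf("BlockSplsdaModel: %d block(s), %d component(s)\n",
              length(object@blockNames), object@ncomp))
  for (b in object@blockNames) {
    nz <- colSums(object@loadings[[b]] != 0)
    cat(sprintf("  %-10s keepX = %s (nonzero: %s)\n", b,
                paste(object@keepX[[b]], collapse = ","),
                paste(nz, collapse = ",")))
  }
  cat("  classes: ", paste(object@classLevels, collapse = " vs "),
      " (positive: ", object@classLevels[2L], ")\n", sep = "")
})

## ---- small shared internals ----

#' Run an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the previous RNG state so
#' library calls do not perturb the caller's random stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## round-half-up (base round() is banker's rounding)
roundHalfUp <- function(x) floor(x + 0.5)

## derive a bounded child seed from a base seed and a label/index
deriveSeed <- function(seed, label) {
  if (is.character(label))
    label <- sum(utf8ToInt(label) * seq_len(nchar(label)))
  (as.numeric(seed) * 7919 + as.numeric(label) * 104729) %% 2147483587 + 1
}

## subset a dataset's samples (duplicates allowed; ids made unique)
subsetSamples <- function(data, idx) {
  sids <- make.unique(sampleIds(data)[idx])
  bl <- lapply(blocks(data), function(b) {
    v <- blockValues(b)[, idx, drop = FALSE]
    colnames(v) <- sids
    omicsBlock(blockName(b), v)
  })
  tr <- traitTable(data)
  tr <- if (ncol(tr)) {
    out <- tr[idx, , drop = FALSE]; rownames(out) <- sids; out
  } else data.frame(row.names = sids)
  pid <- patientIds(data)
  multiOmicsDataset(bl, phenotype(data)[idx],
                    if (length(pid)) pid[idx] else character(), tr)
}
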