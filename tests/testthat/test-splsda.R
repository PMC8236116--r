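# Sparse PLS-DA core: soft thresholding, single-block and multiblock
# fits, prediction.

test_that("softSelect thresholds, normalizes, and keeps exact counts", {
  # lambda is the (keep+1)-th largest |v|: (3,-2,1), keep 2 -> (2,-1,0)/sqrt5
  expect_equal(softSelect(c(3, -2, 1), 2), c(2, -1, 0) / sqrt(5))
  # keep >= length: direction unchanged
  v <- c(1.5, -0.5, 2)
  expect_equal(softSelect(v, 3), v / sqrt(sum(v^2)))
  expect_equal(softSelect(v, 10), v / sqrt(sum(v^2)))
  # single dominant entry
  expect_equal(softSelect(c(5, 0, 0), 1), c(1, 0, 0))
  # exact sparsity for distinct magnitudes
  set.seed(1)
  for (keep in c(1, 3, 7)) {
    out <- softSelect(rnorm(20), keep)
    expect_equal(sum(out != 0), keep)
    expect_equal(sum(out^2), 1)
  }
  expect_error(softSelect(c(0, 0), 1), "all zero")
  expect_error(softSelect(c(1, 2), 0), "keep")
})

test_that("keep-all single-component fit matches the SVD oracle", {
  # oracle: dominant left singular vector of the block-vs-outcome
  # cross-covariance, computed independently with svd()
  worst <- 0
  for (i in 1:50) {
    set.seed(1000 + i)
    X <- matrix(rnorm(6 * 8), 6, 8,
                dimnames = list(paste0("f", 1:6), paste0("s", 1:8)))
    y <- rep(c("a", "b"), each = 4)
    fit <- fitSplsda(X, y, ncomp = 1)
    a <- modelLoadings(fit)$X[, 1]
    Xs <- scale(t(X))
    Yc <- scale(model.matrix(~ factor(y) - 1), scale = FALSE)
    sv <- svd(crossprod(Xs, Yc))$u[, 1]
    cosSim <- abs(sum(a * sv)) / sqrt(sum(a^2) * sum(sv^2))
    worst <- max(worst, 1 - cosSim)
  }
  expect_lt(worst, 1e-6)
})

test_that("a perfectly separating feature is the single keepX=1 selection", {
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    X <- matrix(rnorm(20 * 16), 20, 16,
                dimnames = list(paste0("f", 1:20), paste0("s", 1:16)))
    y <- rep(c("a", "b"), each = 8)
    X[7, ] <- rnorm(16, sd = 0.1) + ifelse(y == "b", 4, 0)
    fit <- fitSplsda(X, y, ncomp = 1, keepX = 1)
    identical(selectedFeatures(fit, comp = 1)$X, "f7")
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("duplicating every sample leaves the loadings unchanged", {
  set.seed(4)
  X <- matrix(rnorm(12 * 10), 12, 10,
              dimnames = list(paste0("f", 1:12), paste0("s", 1:10)))
  y <- rep(c("a", "b"), each = 5)
  X2 <- cbind(X, X); colnames(X2) <- paste0("s", 1:20)
  f1 <- fitSplsda(X, y, ncomp = 2, keepX = 4)
  f2 <- fitSplsda(X2, rep(y, 2), ncomp = 2, keepX = 4)
  expect_equal(modelLoadings(f1)$X, modelLoadings(f2)$X,
               tolerance = 1e-8)
})

test_that("fitted models are exactly sparse, orthogonal, and sign-fixed", {
  for (s in 1:5) {
    sim <- simulateMultiOmics(smallSimConfig(seed = 100 + s))
    kx <- list(gene = c(10L, 25L), protein = c(5L, 12L),
               peptide = c(7L, 30L))
    fit <- fitBlockSplsda(sim$data, ncomp = 2, keepX = kx)
    for (b in names(kx)) {
      L <- modelLoadings(fit)[[b]]
      expect_equal(unname(colSums(L != 0)), as.numeric(kx[[b]]))
      expect_equal(unname(colSums(L^2)), c(1, 1), tolerance = 1e-10)
      # largest-|.| loading entry is positive
      for (h in 1:2) expect_gt(L[which.max(abs(L[, h])), h], 0)
      S <- modelScores(fit)[[b]]
      expect_lt(abs(crossprod(S[, 1], S[, 2])), 1e-8)
    }
  }
})

test_that("keepX above the feature count saturates at all features", {
  sim <- simulateMultiOmics(smallSimConfig(seed = 3))
  fit <- fitBlockSplsda(sim$data, ncomp = 1,
                        keepX = list(gene = 10L, protein = 500L,
                                     peptide = 10L))
  expect_equal(sum(modelLoadings(fit)$protein[, 1] != 0), 80)
})

test_that("zero inter-omics design weight decouples into single-block fits", {
  sim <- simulateMultiOmics(smallSimConfig(seed = 11))
  d0 <- makeDesign(names(blocks(sim$data)), omicsOmicsWeight = 0)
  fitM <- fitBlockSplsda(sim$data, design = d0, ncomp = 2,
                         keepX = smallKeepX(10))
  for (b in names(blocks(sim$data))) {
    fitS <- fitSplsda(blocks(sim$data)[[b]], phenotype(sim$data),
                      ncomp = 2, keepX = 10)
    expect_equal(unname(modelLoadings(fitM)[[b]]),
                 unname(modelLoadings(fitS)[[1]]), tolerance = 1e-6)
  }
})

test_that("two identical fully-coupled blocks produce matching scores", {
  set.seed(8)
  v <- matrix(rnorm(30 * 20), 30, 20,
              dimnames = list(paste0("f", 1:30), paste0("s", 1:20)))
  y <- rep(c("a", "b"), each = 10)
  v[1:3, y == "b"] <- v[1:3, y == "b"] + 2
  ds <- multiOmicsDataset(list(b1 = omicsBlock("b1", v),
                               b2 = omicsBlock("b2", v)), y)
  D <- makeDesign(c("b1", "b2"), omicsOmicsWeight = 1)
  fit <- fitBlockSplsda(ds, design = D, ncomp = 1,
                        keepX = list(b1 = 10, b2 = 10))
  r <- cor(modelScores(fit)$b1[, 1], modelScores(fit)$b2[, 1])
  expect_gt(abs(r), 0.99)
})

test_that("component-1 budgets of 10 per block give a 10+10+10 selection", {
  sim <- simulateMultiOmics(smallSimConfig(seed = 17))
  fit <- fitBlockSplsda(sim$data, ncomp = 1, keepX = smallKeepX(10))
  sel <- selectedFeatures(fit, comp = 1)
  expect_equal(lengths(sel), c(gene = 10L, protein = 10L, peptide = 10L))
})

test_that("training predictions are perfect on separable data and a copy
           of a training sample reproduces its fitted label", {
  sim <- simulateMultiOmics(smallSimConfig(seed = 23))
  fit <- fitBlockSplsda(sim$data, ncomp = 1, keepX = smallKeepX(10))
  pr <- predict(fit, sim$data)
  expect_equal(mean(pr$label == phenotype(sim$data)), 1.0)
  newBlocks <- lapply(blocks(sim$data), function(b)
    blockValues(b)[, 5, drop = FALSE])
  prOne <- predict(fit, newBlocks)
  expect_equal(as.character(prOne$label), as.character(pr$label[5]))
})

test_that("single-block models aggregate to the block score itself", {
  set.seed(2)
  X <- matrix(rnorm(15 * 14), 15, 14,
              dimnames = list(paste0("f", 1:15), paste0("s", 1:14)))
  y <- rep(c("a", "b"), each = 7)
  fit <- fitSplsda(X, y, ncomp = 1, keepX = 5)
  pr <- predict(fit, list(X = X))
  expect_equal(pr$aggregated, pr$blockIndicator$X)
})

test_that("prediction fails informatively when features are missing", {
  sim <- simulateMultiOmics(smallSimConfig(seed = 29))
  fit <- fitBlockSplsda(sim$data, ncomp = 1, keepX = smallKeepX(5))
  nb <- lapply(blocks(sim$data), function(b) blockValues(b)[-1, ])
  expect_error(predict(fit, nb), "lacks")
})

test_that("fitting refuses blocks with missing values", {
  sim <- simulateMultiOmics(smallSimConfig(seed = 31, missing = TRUE))
  expect_error(fitBlockSplsda(sim$data, ncomp = 1, keepX = smallKeepX(5)),
               "missing values")
})
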