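# Missingness filter, k-NN imputation, normalization stand-ins,
# top-variance filter.

test_that("filterMissing applies the >= threshold and preserves order", {
  # feature missing in 2 of 4 samples is discarded at threshold 0.5
  m <- matrix(1, 3, 4, dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  m["b", 1:2] <- NA
  res <- filterMissing(omicsBlock("x", m))
  expect_equal(res$discarded, "b")
  expect_equal(featureIds(res$block), c("a", "c"))

  # counts 0..9 of 10 samples: exactly those with 0-4 missing survive
  m2 <- matrix(1, 10, 10,
               dimnames = list(sprintf("f%02d", 1:10), paste0("s", 1:10)))
  for (i in 1:10) if (i > 1) m2[i, seq_len(i - 1)] <- NA
  res2 <- filterMissing(omicsBlock("x", m2))
  expect_equal(featureIds(res2$block), sprintf("f%02d", 1:5))

  # no missing values: unchanged; and idempotence
  b3 <- randBlock(5, 6, seed = 1)
  expect_equal(blockValues(filterMissing(b3)$block), blockValues(b3))
  once <- filterMissing(omicsBlock("x", m2))$block
  twice <- filterMissing(once)
  expect_equal(blockValues(twice$block), blockValues(once))
  expect_length(twice$discarded, 0)

  # everything discarded is an error
  mAll <- matrix(NA_real_, 2, 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(filterMissing(omicsBlock("x", mAll)), "no feature")
})

test_that("knnImpute averages the k nearest neighbours' observed values", {
  # k = 1: copy the nearest neighbour's value
  m <- matrix(c(1, 5, 1.1, 5.0, 9, 50), 2, 3,
              dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
  m["f2", "s1"] <- NA
  out <- knnImpute(omicsBlock("x", m), k = 1)
  expect_equal(blockValues(out)["f2", "s1"], 5.0)  # s2 is nearest

  # equidistant neighbours with values 2 and 4 -> mean 3
  m2 <- matrix(c(0, NA, 1, 2, -1, 4), 2, 3,
               dimnames = list(c("f1", "f2"), c("s1", "s2", "s3")))
  out2 <- knnImpute(omicsBlock("x", m2), k = 2)
  expect_equal(blockValues(out2)["f2", "s1"], 3.0)

  # all k neighbours share value c -> imputed c; observed entries untouched
  m3 <- matrix(c(0, NA, 0.2, 7, -0.2, 7, 5, 7), 2, 4,
               dimnames = list(c("f1", "f2"), paste0("s", 1:4)))
  out3 <- knnImpute(omicsBlock("x", m3), k = 2)
  expect_equal(blockValues(out3)["f2", "s1"], 7)
  expect_equal(blockValues(out3)[, 2:4], m3[, 2:4])
  expect_false(anyNA(blockValues(out3)))

  # deterministic
  sim <- simulateMultiOmics(smallSimConfig(seed = 4, missing = TRUE))
  pb <- filterMissing(blocks(sim$data)$protein)$block
  expect_identical(blockValues(knnImpute(pb, 7)),
                   blockValues(knnImpute(pb, 7)))

  # k out of range
  expect_error(knnImpute(omicsBlock("x", m), k = 3), "k must")
})

test_that("knnImpute falls back to the feature mean with a warning", {
  # f2 observed only in s1... make a sample whose neighbours all lack f2
  m <- matrix(c(0, 9, 0.1, NA, 5, NA, 5.1, NA), 2, 4,
              dimnames = list(c("f1", "f2"), paste0("s", 1:4)))
  m["f2", 1] <- 9  # observed once overall
  m2 <- m; m2["f2", 3] <- NA
  # sample s4: f2 missing; nearest neighbour by f1 is s3 (also missing f2)
  ws <- capture_warnings(out <- knnImpute(omicsBlock("x", m2), k = 1))
  expect_true(any(grepl("falling back", ws)))
  expect_equal(blockValues(out)["f2", 4], 9)  # overall observed mean
})

test_that("knnImpute beats global-mean imputation on correlated samples", {
  sim <- simulateMultiOmics(simulationConfig(
    nPerClass = c(16L, 26L),
    blockSpecs = data.frame(name = "protein", nFeatures = 120L,
                            missingFrac = 0),
    nInformative = 60L, effectSize = 3, blockNoiseSd = 0.7, seed = 8))
  v <- blockValues(blocks(sim$data)$protein)
  set.seed(99)
  holdout <- sample(length(v), round(0.2 * length(v)))
  vNA <- v; vNA[holdout] <- NA
  keep <- rowMeans(is.na(vNA)) < 0.5
  vNA <- vNA[keep, ]; vRef <- v[keep, ]
  holdMask <- is.na(vNA)
  imp <- blockValues(knnImpute(omicsBlock("protein", vNA), k = 7))
  gm <- rowMeans(vNA, na.rm = TRUE)
  errKnn <- mean(abs(imp[holdMask] - vRef[holdMask]))
  errMean <- mean(abs(matrix(gm, nrow(vNA), ncol(vNA))[holdMask] -
                        vRef[holdMask]))
  expect_lt(errKnn, errMean)
})

test_that("normalization stand-ins behave as documented", {
  # log_median: a sample with raw median 8 is centered to 0
  m <- matrix(c(2, 8, 32, 4, 4, 4), 3, 2,
              dimnames = list(paste0("f", 1:3), c("s1", "s2")))
  out <- normalizeBlock(omicsBlock("x", m), "log_median")
  expect_equal(median(blockValues(out)[, "s1"]), 0)

  # reference_geomean: scale invariance per sample
  b <- rawBlock(matrix(exp(rnorm(20, 2)), 5, 4))
  v <- blockValues(b)
  v2 <- v; v2[, 2] <- v2[, 2] * 4
  n1 <- blockValues(normalizeBlock(rawBlock(v), "reference_geomean"))
  n2 <- blockValues(normalizeBlock(rawBlock(v2), "reference_geomean"))
  expect_equal(n1, n2)

  # complete-case geometric means become the divisors
  m3 <- matrix(c(1, 4, NA, 4, 16, 7), 3, 2,
               dimnames = list(paste0("f", 1:3), c("s1", "s2")))
  # complete-case features are f1 and f2: geomeans 2 and 8
  out3 <- blockValues(normalizeBlock(omicsBlock("x", m3),
                                     "reference_geomean"))
  expect_equal(out3["f1", ], log2(c(s1 = 1 / 2, s2 = 4 / 8)))
  expect_true(is.na(out3["f3", "s1"]))

  expect_error(normalizeBlock(rawBlock(matrix(c(-1, 2, 3, 4), 2, 2))),
               "positive")
  mAllNA <- matrix(c(NA, 1, 2, NA), 2, 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(normalizeBlock(omicsBlock("x", mAllNA), "reference_geomean"),
               "complete-case")
})

test_that("topVarianceFilter keeps the most variable features", {
  m <- rbind(f1 = c(1, 1, 1, 1), f2 = c(1, 2, 3, 4), f3 = c(0, 4, 0, 4))
  colnames(m) <- paste0("s", 1:4)
  b <- omicsBlock("x", m)
  expect_equal(sort(featureIds(topVarianceFilter(b, 2))), c("f2", "f3"))
  # constant feature never retained while others vary
  expect_false("f1" %in% featureIds(topVarianceFilter(b, 2)))
  # n = nFeatures: unchanged
  expect_equal(blockValues(topVarianceFilter(b, 3)), m)
  expect_error(topVarianceFilter(b, 0), "positive")
})

test_that("preprocessDataset routes blocks through the right stages", {
  sim <- simulateMultiOmics(smallSimConfig(seed = 6, missing = TRUE))
  # sparse peptide features may trigger the documented mean fallback
  res <- suppressWarnings(preprocessDataset(sim$data, topNVariance = 150L))
  bl <- blocks(res$data)
  expect_false(any(vapply(bl, function(b) anyNA(blockValues(b)),
                          logical(1))))
  expect_equal(nrow(blockValues(bl$gene)), 150)
  expect_equal(res$report$protein$retained +
                 res$report$protein$discarded, 80)
})
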