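# Differential expression, correlation, hypergeometric ORA, GSEA,
# cofactor testing, comparison utilities.

test_that("differential expression follows the sign convention and the
           null cases", {
  # IPH mean 4.0 vs non-IPH mean 3.0 -> log2FC = +1
  v <- rbind(f1 = c(3, 3, 3, 4, 4, 4),
             f2 = c(1, 2, 3, 1, 2, 3),
             f3 = c(5, 5, 5, 5, 5, 5))
  colnames(v) <- paste0("s", 1:6)
  y <- factor(rep(c("nonIPH", "IPH"), each = 3),
              levels = c("nonIPH", "IPH"))
  de <- differentialExpression(v, y)
  expect_equal(de$log2FC[de$feature_id == "f1"], 1.0)
  # identical groups: log2FC 0, t = 0, p = 1
  expect_equal(de$log2FC[de$feature_id == "f2"], 0)
  expect_equal(de$t[de$feature_id == "f2"], 0)
  expect_equal(de$p[de$feature_id == "f2"], 1)
  # constant feature flagged with p = 1
  expect_true(de$flagged[de$feature_id == "f3"])
  expect_equal(de$p[de$feature_id == "f3"], 1)
})

test_that("welch t-test matches stats::t.test feature by feature", {
  set.seed(7)
  v <- matrix(rnorm(20 * 12), 20, 12,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:12)))
  y <- factor(rep(c("nonIPH", "IPH"), c(5, 7)), c("nonIPH", "IPH"))
  de <- differentialExpression(v, y)
  for (i in c(1, 7, 20)) {
    ref <- t.test(v[i, y == "IPH"], v[i, y == "nonIPH"])
    expect_equal(de$t[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(de$p[i], ref$p.value, tolerance = 1e-10)
  }
})

test_that("paired design uses the within-pair differences", {
  set.seed(8)
  v <- matrix(rnorm(10 * 8), 10, 8,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:8)))
  y <- factor(rep(c("nonIPH", "IPH"), each = 4), c("nonIPH", "IPH"))
  pid <- rep(paste0("P", 1:4), 2)
  de <- differentialExpression(v, y, pairedBy = pid)
  ref <- t.test(v[3, y == "IPH"], v[3, y == "nonIPH"], paired = TRUE)
  expect_equal(de$p[3], ref$p.value, tolerance = 1e-10)
})

test_that("null differential expression is calibrated at the 5% level", {
  set.seed(11)
  v <- matrix(rnorm(10000 * 20), 10000, 20,
              dimnames = list(paste0("f", 1:10000), paste0("s", 1:20)))
  y <- factor(rep(c("a", "b"), each = 10), c("a", "b"))
  de <- differentialExpression(v, y)
  frac <- mean(de$p < 0.05)
  expect_gt(frac, 0.04); expect_lt(frac, 0.06)
})

test_that("pearsonWithP reproduces hand-computable cases and cor.test", {
  x <- c(1, 2, 3, 4)
  res <- pearsonWithP(x, 2 * x + 1)
  expect_equal(res$r, 1.0)
  # collinear-free zero case: (0,0),(1,1),(2,0)
  expect_equal(pearsonWithP(c(0, 1, 2), c(0, 1, 0))$r, 0)
  set.seed(3)
  a <- rnorm(30); b <- 0.5 * a + rnorm(30)
  ref <- cor.test(a, b)
  res2 <- pearsonWithP(a, b)
  expect_equal(res2$r, unname(ref$estimate))
  expect_equal(res2$p, ref$p.value, tolerance = 1e-12)
  expect_error(pearsonWithP(rep(1, 5), rnorm(5)), "variance")
})

test_that("hypergeometric upper tail matches exact enumeration", {
  # closed forms
  expect_equal(hypergeomOverrep(5, 5, 5, 20), 1 / choose(20, 5))
  expect_equal(hypergeomOverrep(0, 5, 5, 20), 1.0)
  expect_equal(hypergeomOverrep(3, 5, 5, 10), 126 / 252)
  # full enumeration oracle over all consistent (k, K, n) for N <= 12:
  # P(X >= k) = sum_j C(K,j) C(N-K, n-j) / C(N, n)
  for (N in c(6, 9, 12)) {
    for (K in 1:(N - 1)) for (n in 1:(N - 1)) {
      for (k in 0:min(K, n)) {
        js <- k:min(K, n)
        manual <- sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
        expect_equal(hypergeomOverrep(k, K, n, N), manual,
                     tolerance = 1e-12)
      }
    }
  }
  expect_error(hypergeomOverrep(6, 5, 5, 10), "inconsistent")
})

test_that("gsoa ranks the matching set first and BH-adjusts step-up", {
  universe <- sprintf("G%03d", 1:40)
  sets <- list(hit = universe[1:10], other = universe[21:30])
  res <- gsoa(universe[1:10], sets, universe)
  expect_equal(res$set[1], "hit")
  expect_equal(res$k[res$set == "other"], 0)
  expect_equal(res$p[res$set == "other"], 1)
  # BH on (0.01, 0.02, 0.03) -> all 0.03
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  # monotone: adjusted order never reverses raw order
  set.seed(4)
  p <- runif(50)
  expect_true(all(diff(p.adjust(sort(p), "BH")) >= 0))
  expect_error(gsoa("ZZZ", sets, universe), "no overlap")
})

test_that("GSEA running sum attains the documented extremes", {
  ranked <- data.frame(symbol = sprintf("G%02d", 1:40),
                       stat = seq(4, -4, length.out = 40))
  # all set members at the top, weight 0 -> ES = 1
  res <- prerankedGsea(ranked, sprintf("G%02d", 1:5), nPerm = 50,
                       weightExponent = 0, seed = 1)
  expect_equal(res$es, 1.0)
  # all members at the bottom -> ES < 0
  resB <- prerankedGsea(ranked, sprintf("G%02d", 36:40), nPerm = 50,
                        weightExponent = 1, seed = 1)
  expect_lt(resB$es, 0)
  # |ES| <= 1 when weight 0, any placement
  set.seed(2)
  for (i in 1:10) {
    set <- sample(ranked$symbol, 8)
    es <- prerankedGsea(ranked, set, nPerm = 10, weightExponent = 0,
                        seed = i)$es
    expect_lte(abs(es), 1)
  }
  expect_error(prerankedGsea(ranked, "ZZZ", 10), "intersect")
  expect_error(prerankedGsea(ranked, ranked$symbol, 10), "entire")
})

test_that("GSEA enrichment score agrees with fgsea's statistic", {
  set.seed(9)
  stats <- sort(rnorm(100), decreasing = TRUE)
  names(stats) <- sprintf("G%03d", 1:100)
  ranked <- data.frame(symbol = names(stats), stat = unname(stats))
  for (i in 1:5) {
    set <- sample(names(stats), 12)
    mine <- prerankedGsea(ranked, set, nPerm = 10, weightExponent = 1,
                          seed = i)$es
    ref <- fgsea::calcGseaStat(stats, selectedStats = sort(match(set, names(stats))),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("GSEA permutation p-values are null-calibrated", {
  ranked <- data.frame(symbol = sprintf("G%03d", 1:150),
                       stat = seq(3, -3, length.out = 150))
  set.seed(12)
  ps <- vapply(1:80, function(i) {
    set <- sample(ranked$symbol, 10)
    prerankedGsea(ranked, set, nPerm = 200, seed = 1000 + i)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("cofactor overrepresentation separates enriched from disjoint
           reference sets", {
  universe <- sprintf("G%03d", 1:200)
  targets <- universe[1:20]
  # full overlap in a 10x larger universe: p < 1e-3
  res <- srfCofactorTest(targets, list(mkl = targets,
                                       elf = universe[101:120]), universe)
  expect_lt(res$p[res$set == "mkl"], 1e-3)
  expect_equal(res$p[res$set == "elf"], 1)
  # 5x enrichment by construction beats the unenriched set in most seeds
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    sigT <- c(sample(universe[1:40], 15), sample(universe[41:200], 5))
    ref <- list(enriched = universe[1:40], flat = sample(universe, 40))
    r <- srfCofactorTest(sigT, ref, universe)
    r$p[r$set == "enriched"] < r$p[r$set == "flat"]
  }, logical(1))
  expect_gte(mean(wins), 0.95)
  expect_error(srfCofactorTest(targets, list(), universe), "no reference")
})

test_that("group comparison picks the test by normality", {
  set.seed(21)
  gaussA <- rnorm(20); gaussB <- rnorm(20, 1)
  res <- groupCompareTest(gaussA, gaussB)
  expect_equal(res$test, "t")
  skewA <- rexp(20); skewB <- rexp(20) * 3
  res2 <- groupCompareTest(skewA, skewB)
  expect_equal(res2$test, "wilcoxon")
  expect_lt(res2$p, 0.05)
})

test_that("component-trait correlations recover the planted trait link", {
  sim <- simulateMultiOmics(smallSimConfig(seed = 71))
  fit <- fitBlockSplsda(sim$data, ncomp = 2, keepX = smallKeepX(10))
  ctc <- componentTraitCorrelation(fit, traitTable(sim$data))
  # plaque_size is planted at rho = 0.74 with latent factor 1; component 1
  # tracks that factor, so the correlation is strong and significant
  r1 <- ctc[ctc$comp == 1 & ctc$trait == "plaque_size", ]
  expect_gt(abs(r1$r), 0.4)
  expect_lt(r1$p, 0.01)
})
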