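## Downstream statistics: differential expression, Pearson correlation
## with p-values, hypergeometric overrepresentation with BH adjustment,
## cofactor set testing, preranked GSEA, and small comparison utilities.

#' Differential expression between the two phenotype groups
#'
#' Per feature on log2-scale data: `log2FC = mean(positive class) -
#' mean(negative class)` (positive values mean higher expression in the
#' positive/IPH group), a two-sided t test (paired on the differences when
#' `pairedBy` pairs every sample one-to-one across groups, Welch
#' otherwise), and Benjamini-Hochberg adjustment across features. Constant
#' contrasts get `t = 0`, `p = 1` and are flagged.
#'
#' @param block an imputed [OmicsBlock-class] or feature x sample matrix
#'   (log2 scale).
#' @param y binary phenotype; second level = positive class.
#' @param pairedBy optional pairing label per sample; a paired test is used
#'   only if every label occurs exactly once per group.
#' @return data.frame with `feature_id`, `log2FC`, `t`, `p`, `padj`,
#'   `flagged`.
#' @export
differentialExpression <- function(block, y, pairedBy = NULL) {
  v <- if (is(block, "OmicsBlock")) blockValues(block) else as.matrix(block)
  if (anyNA(v))
    stop("differentialExpression: impute missing values first")
  y <- as.factor(y)
  stopifnot(nlevels(y) == 2L)
  neg <- y == levels(y)[1L]; pos <- y == levels(y)[2L]
  if (sum(neg) < 2L || sum(pos) < 2L)
    stop("differentialExpression: need >= 2 samples per group")
  paired <- FALSE
  if (!is.null(pairedBy) && length(pairedBy) == ncol(v)) {
    tabs <- table(pairedBy, y)
    paired <- all(tabs == 1L)
  }
  m1 <- rowMeans(v[, pos, drop = FALSE])
  m0 <- rowMeans(v[, neg, drop = FALSE])
  lfc <- m1 - m0
  if (paired) {
    ord0 <- order(pairedBy[neg]); ord1 <- order(pairedBy[pos])
    d <- v[, pos, drop = FALSE][, ord1, drop = FALSE] -
         v[, neg, drop = FALSE][, ord0, drop = FALSE]
    np <- ncol(d)
    md <- rowMeans(d)
    sdd <- sqrt(rowSums((d - md)^2) / (np - 1L))
    se <- sdd / sqrt(np)
    tstat <- ifelse(se > 0, md / se, 0)
    df <- rep(np - 1L, nrow(v))
  } else {
    n1 <- sum(pos); n0 <- sum(neg)
    v1 <- rowSums((v[, pos, drop = FALSE] - m1)^2) / (n1 - 1L)
    v0 <- rowSums((v[, neg, drop = FALSE] - m0)^2) / (n0 - 1L)
    se2 <- v1 / n1 + v0 / n0
    tstat <- ifelse(se2 > 0, (m1 - m0) / sqrt(se2), 0)
    df <- ifelse(se2 > 0,
                 se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v0 / n0)^2 / (n0 - 1L)),
                 1)
  }
  flagged <- tstat == 0 & lfc == 0 |
    (if (paired) df < 1 else FALSE)
  p <- ifelse(tstat == 0 & flagged, 1,
              2 * stats::pt(-abs(tstat), df))
  p[is.na(p)] <- 1
  data.frame(feature_id = rownames(v), log2FC = lfc, t = tstat, p = p,
             padj = stats::p.adjust(p, method = "BH"),
             flagged = flagged, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Pearson correlation with a t-based p-value
#'
#' Product-moment correlation; the two-sided p-value comes from
#' `t = r * sqrt((n-2) / (1-r^2))` against a t distribution with `n - 2`
#' degrees of freedom.
#' @param x,y numeric vectors of equal length `>= 3` with nonzero variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearsonWithP <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearsonWithP: zero variance input")
  n <- length(x)
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Correlate model components with sample traits
#'
#' One [pearsonWithP()] per (component, trait) pair, using the scores of
#' the chosen block.
#' @param model a [BlockSplsdaModel-class].
#' @param traits data.frame of numeric per-sample covariates (same sample
#'   order as at fit time).
#' @param block which block's scores to use (default: first).
#' @return data.frame with `comp`, `trait`, `r`, `p`, `n`.
#' @export
componentTraitCorrelation <- function(model, traits, block = NULL) {
  block <- block %||% model@blockNames[1L]
  S <- model@scores[[block]]
  rows <- list()
  for (h in seq_len(ncol(S)))
    for (tr in colnames(traits)) {
      res <- pearsonWithP(S[, h], traits[[tr]])
      rows[[length(rows) + 1L]] <- data.frame(
        comp = h, trait = tr, r = res$r, p = res$p, n = res$n)
    }
  do.call(rbind, rows)
}

#' Upper-tail hypergeometric overrepresentation p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` query genes
#' from a universe of `N` of which `K` belong to the set, the probability
#' of an overlap at least as large as the observed `k`.
#' @param k observed overlap.
#' @param K set size in the universe.
#' @param n query size.
#' @param N universe size.
#' @return exact upper-tail p-value.
#' @examples
#' hypergeomOverrep(3, 5, 5, 10)   # 126/252 = 0.5
#' @export
hypergeomOverrep <- function(k, K, n, N) {
  if (k > min(K, n) || K > N || n > N || k < 0)
    stop("hypergeomOverrep: inconsistent counts")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set overrepresentation analysis
#'
#' One hypergeometric test per set against the background universe, with
#' Benjamini-Hochberg adjustment across all tested sets. The query and
#' every set are first restricted to the universe.
#' @param symbols character vector of query gene symbols (e.g. a signature's
#'   `$symbol` column).
#' @param sets named list of gene-symbol sets (see [readGmt()]).
#' @param universe background symbols (platform/detectable genes).
#' @return data.frame with `set`, `k` (overlap), `K` (set size), `n`
#'   (query size), `N` (universe size), `p`, `padj`, sorted by `padj` then
#'   `p`.
#' @export
gsoa <- function(symbols, sets, universe) {
  universe <- unique(universe)
  N <- length(universe)
  query <- unique(intersect(symbols, universe))
  if (length(query) == 0L)
    stop("gsoa: query has no overlap with the universe")
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), universe)
    k <- length(intersect(query, set))
    data.frame(set = nm, k = k, K = length(set), n = n, N = N,
               p = if (length(set)) hypergeomOverrep(k, length(set), n, N)
                   else 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$padj, out$p, out$set), ]
  rownames(out) <- NULL
  out
}

## running-sum enrichment score for a hit indicator along a ranked list
.gseaES <- function(absStatW, hit) {
  nh <- sum(hit)
  N <- length(hit)
  delta <- numeric(N)
  tot <- sum(absStatW[hit])
  delta[hit] <- if (tot > 0) absStatW[hit] / tot else 1 / nh
  delta[!hit] <- -1 / (N - nh)
  rs <- cumsum(delta)
  rs[which.max(abs(rs))]
}

#' Preranked gene-set enrichment analysis
#'
#' Classic running-sum GSEA on a list ranked by a per-gene statistic
#' (typically log2 fold change, descending): hits increment the running
#' sum by `|stat|^weightExponent` (normalized over the in-set total),
#' misses decrement by `1/(N - s)`; the enrichment score ES is the signed
#' extremum. Significance is assessed by gene-label permutation: NES is ES
#' divided by the mean |ES| of same-sign permutations, and the p-value is
#' the same-sign permutation tail fraction `P(ES_perm >= ES | ES_perm of
#' matching sign)` (mirrored for negative ES).
#'
#' @param ranked data.frame with columns `symbol` (unique) and `stat`;
#'   sorted internally by decreasing `stat`.
#' @param set character vector of gene symbols; must intersect the list
#'   and not cover it entirely.
#' @param nPerm permutation count (default 1000).
#' @param weightExponent hit-weight exponent (default 1; 0 gives the
#'   unweighted Kolmogorov-Smirnov-like statistic with `ES` in `[-1,1]`).
#' @param seed integer seed for the permutations.
#' @return list with `es`, `nes`, `p`, `nHits`, `nPerm`.
#' @export
prerankedGsea <- function(ranked, set, nPerm = 1000L, weightExponent = 1,
                          seed = 1L) {
  stopifnot(all(c("symbol", "stat") %in% names(ranked)))
  if (anyDuplicated(ranked$symbol))
    stop("prerankedGsea: symbols must be unique in the ranked list")
  ord <- order(-ranked$stat)
  sym <- ranked$symbol[ord]
  stat <- ranked$stat[ord]
  hit <- sym %in% set
  nh <- sum(hit)
  if (nh == 0L)
    stop("prerankedGsea: set does not intersect the ranked list")
  if (nh == length(sym))
    stop("prerankedGsea: set covers the entire ranked list")
  w <- abs(stat)^weightExponent
  es <- .gseaES(w, hit)
  withSeed(seed, {
    esPerm <- vapply(seq_len(nPerm), function(i) {
      h <- logical(length(sym))
      h[sample.int(length(sym), nh)] <- TRUE
      .gseaES(w, h)
    }, numeric(1))
  })
  same <- if (es >= 0) esPerm[esPerm >= 0] else esPerm[esPerm < 0]
  if (length(same) == 0L) {
    nes <- NA_real_; p <- 1 / (nPerm + 1)
  } else {
    nes <- es / mean(abs(same))
    p <- if (es >= 0) mean(same >= es) else mean(same <= es)
    if (p == 0) p <- 1 / (length(same) + 1)
  }
  list(es = es, nes = nes, p = p, nHits = nh, nPerm = nPerm)
}

#' Cofactor-set overrepresentation test
#'
#' For each cofactor-regulated reference set (supplied as a named list,
#' e.g. from a GMT of MKL1/2- and ELF4-dependent target genes), tests
#' whether the signature's network members are overrepresented in the set
#' by an upper-tail hypergeometric test against the stated universe. The
#' universe is an explicit argument because the choice (all pathway targets
#' vs the whole background) materially changes the p-values.
#'
#' @param signatureTargets character vector of network-member symbols.
#' @param cofactorSets named list of reference sets.
#' @param universe background symbols.
#' @return data.frame with one row per cofactor set: `set`, `k`, `K`, `n`,
#'   `N`, `p`.
#' @export
srfCofactorTest <- function(signatureTargets, cofactorSets, universe) {
  if (length(cofactorSets) == 0L)
    stop("srfCofactorTest: no reference sets supplied")
  universe <- unique(universe)
  query <- unique(intersect(signatureTargets, universe))
  rows <- lapply(names(cofactorSets), function(nm) {
    set <- intersect(unique(cofactorSets[[nm]]), universe)
    k <- length(intersect(query, set))
    data.frame(set = nm, k = k, K = length(set), n = length(query),
               N = length(universe),
               p = if (length(set)) hypergeomOverrep(k, length(set),
                                                     length(query),
                                                     length(universe))
                   else 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-group comparison with a normality-driven test choice
#'
#' Shapiro-Wilk normality on each group decides between Student's t test
#' (both normal at `alpha`) and the two-sided Wilcoxon rank-sum test;
#' Wilcoxon uses the exact distribution up to n = 25 per group and the
#' normal approximation above.
#' @param x,y numeric samples.
#' @param paired paired comparison?
#' @param alpha normality-test level (default 0.05).
#' @return list with `test` ("t" or "wilcoxon"), `p`, `shapiroP`.
#' @export
groupCompareTest <- function(x, y, paired = FALSE, alpha = 0.05) {
  sh <- c(stats::shapiro.test(x)$p.value, stats::shapiro.test(y)$p.value)
  if (all(sh > alpha)) {
    p <- stats::t.test(x, y, paired = paired)$p.value
    list(test = "t", p = p, shapiroP = sh)
  } else {
    exact <- max(length(x), length(y)) <= 25
    p <- suppressWarnings(
      stats::wilcox.test(x, y, paired = paired, exact = exact)$p.value)
    list(test = "wilcoxon", p = p, shapiroP = sh)
  }
}
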