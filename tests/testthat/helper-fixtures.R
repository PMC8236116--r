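# Shared fixture builders. All data are generated in code under fixed
# seeds; sizes are desk-scale versions of the study's 3-block cohort.

# small three-block simulation in the cohort's 16 vs 26 shape
smallSimConfig <- function(seed = 1, effectSize = 2, missing = FALSE,
                           nPerClass = c(16L, 26L), nInformative = 10L) {
  simulationConfig(
    nPerClass = nPerClass,
    blockSpecs = data.frame(
      name = c("gene", "protein", "peptide"),
      nFeatures = c(200L, 80L, 120L),
      missingFrac = if (missing) c(0, 0.26, 0.39) else c(0, 0, 0)),
    nInformative = nInformative, effectSize = effectSize, seed = seed)
}

smallKeepX <- function(k = 10L)
  list(gene = k, protein = k, peptide = k)

# a raw-scale (positive-valued) block for normalization tests
rawBlock <- function(values, name = "raw") {
  m <- as.matrix(values)
  if (is.null(rownames(m))) rownames(m) <- paste0("f", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  omicsBlock(name, m)
}

# random labelled matrix helper
randBlock <- function(p, n, seed, name = "X") {
  set.seed(seed)
  m <- matrix(rnorm(p * n), p, n,
              dimnames = list(paste0("f", seq_len(p)),
                              paste0("s", seq_len(n))))
  omicsBlock(name, m)
}

# permute a dataset's phenotype labels (keeps blocks/traits)
permuteLabels <- function(data, seed) {
  set.seed(seed)
  y <- sample(as.character(phenotype(data)))
  multiOmicsDataset(blocks(data), factor(y, levels(phenotype(data))),
                    patientIds(data), traitTable(data))
}
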