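---
title: "Integrative multiblock sparse PLS-DA with stability-based signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative multiblock sparse PLS-DA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockSig)
```

# The problem

Carotid atherosclerotic plaques that have bled internally (intraplaque
hemorrhage, IPH) are at much higher risk of causing stroke than plaques
that have not. Transcriptomic, proteomic, and peptidomic profiles of the
same plaque tissue each carry part of the IPH signal, but mRNA and protein
abundances correlate poorly, so single-layer analyses miss shared
structure. `blockSig` implements an integrative classification workflow
for this setting: several aligned omics blocks, a binary phenotype, a
handful of samples, and tens of thousands of features.

The workflow is: preprocess each layer (missingness filter, k-NN
imputation, normalization, variance filtering), fit a design-coupled
multiblock sparse PLS-DA model, tune its budgets by cross-validated
balanced error rate, stabilize the feature selection by resampling,
collapse the selected features into a gene-symbol signature, and
characterize that signature with differential expression, trait
correlations, set overrepresentation, preranked GSEA, and independent
classifier-based validation. Because the motivating cohort data are not
redistributable, the package ships a synthetic multiomics generator with
planted ground truth; every claim the test suite makes is made against
that ground truth.

# The model

## Sparse PLS-DA on one block

Let $X$ be the $n \times p$ feature matrix of one block, centered and
unit-variance scaled per feature, and let $Y$ be the $n \times 2$
centered class-indicator matrix. For each component the algorithm seeks a
unit-norm loading $a$ maximizing covariance between the block score
$t = Xa$ and the outcome score $u = Yb$, with an $\ell_1$-style
constraint enforced by soft thresholding: given a budget `keepX`, the
update is

$$a \leftarrow \frac{g_\lambda(X^\top u)}{\lVert g_\lambda(X^\top u)\rVert_2},
\qquad g_\lambda(v)_i = \operatorname{sign}(v_i)\,(|v_i|-\lambda)_+,$$

where $\lambda$ is the `(keepX+1)`-th largest $|v_i|$, so exactly `keepX`
loadings stay nonzero for generic inputs (`softSelect()`). After
convergence the block is deflated by regression on its own score,
guaranteeing within-block score orthogonality; the next component is
extracted from the residual.

With a binary outcome the centered indicator matrix has rank one, which
has two consequences worth knowing. First, the outcome-side iteration
converges essentially immediately (the outcome score direction is fixed
up to sign). Second, the outcome must *not* be deflated between
components: deflating a rank-one $Y$ on its own score would annihilate it
and leave components two onward unsupervised. The package therefore
deflates only the X-blocks, which matches the regression-mode behavior of
the reference implementations of this model family.

## Multiblock coupling

For blocks $X_1,\dots,X_B$ a symmetric design matrix $C$ over blocks and
outcome states how strongly each pair of latent scores should covary. Per
component, loadings are updated cyclically: the update direction for
block $b$ is

$$d_b = C_{b,y}\,X_b^\top u + \sum_{j \ne b} C_{b,j}\, X_b^\top t_j,$$

passed through the same soft-thresholding operator at block $b$'s budget.
The default design (`makeDesign()`) uses 0.1 between omics blocks and 1.0
between every block and the outcome — weak enough that the outcome
dominates, strong enough that block components align. When the
inter-omics weights are exactly zero the coupling term vanishes and each
block's solution coincides with its single-block fit; the test suite
verifies this identity to $10^{-6}$, and verifies the keep-all
single-component solution against the SVD of the block-outcome
cross-covariance computed independently.

Convergence is declared when the largest loading change falls below
`tol = 1e-6` (at most 100 iterations). Sparse cyclic updates can land in
a limit cycle in which one boundary feature flips in and out of the
support with a sub-tolerance change of the loading values; fits reaching
the iteration cap with a change below $\sqrt{\text{tol}}$ are accepted as
converged, and anything larger is an error. The sign of each loading
vector is fixed after convergence (largest-magnitude entry positive),
flipping loading, score, and projection together, so output is
deterministic without perturbing the fixed point.

## Prediction

New samples are scaled with the training parameters, projected component
by component with the stored deflation loadings, and mapped to predicted
class-indicator values by regressing the training indicator on the
training scores. Each block assigns the class with the larger predicted
indicator value ("max.dist"); the block predictions are averaged with the
design's block-outcome weights into an aggregated score whose
positive-class column is the continuous score used for AUC. The paper
trail for this model family reports AUCs but not a distance rule; the
maximum-indicator rule is the simplest one consistent with producing a
continuous score, and is documented here as the package's choice.

# Tuning, resampling, and the signature

**Grids.** The single-omics budget grid spans 3–300 in widening steps (26
distinct candidates); the integrative grid spans 10–100 (14 distinct
candidates per component per omics). `enumerateGrid()` expands any
piecewise specification and deduplicates boundaries.

**Cross-validation.** Stratified 5-fold CV, repeated; each repeat derives
its fold seed as `seed + repeat`, per-class fold sizes differ by at most
one, and everything downstream of the split — feature scaling included —
is re-estimated inside the training fold. The tuning criterion is the
balanced error rate (mean of per-class error rates), which is insensitive
to the 16-vs-26 class imbalance of the motivating design; model
performance is summarized by accuracy and the exact rank-statistic AUC.
Tuning is greedy: budgets for earlier components are frozen while the
current component's candidate list is scanned, and, for the integrative
model, one shared candidate value is applied to all blocks per scan. The
full per-omics cross-product (14³ combinations per component) adds
nothing at desk scale and is intractable at the repeat counts this
protocol calls for. Ties prefer the smaller budget and then the smaller
component count.

**Stability selection.** With tuned parameters fixed, the model is refit
on resampled copies of the data: per copy and per class,
`round(0.8 * n_class)` samples are drawn *with replacement* (round half
up, so 16 and 26 samples yield 13 and 21 draws), preserving the phenotype
distribution. Absolute loading weights are summed per (block, component,
feature) across copies — absolute, because loading signs are arbitrary
across refits — and a feature's selection frequency is recorded. The
default of 200 copies is a desk-scale setting; production analyses of
this protocol use 10,000, and the ranking is stable well before that (the
suite checks recovery is non-degrading from 10 to 100+ copies).

**Signature.** The top `keepX` features per (block, component) by
aggregate importance are mapped to gene symbols and deduplicated keeping
each symbol's maximum importance; the component attributed to a recurring
symbol is the one where it achieved that maximum. This is how a
10+10+10 component-1 selection with eight protein/peptide-shared symbols
collapses to a 22-symbol signature.

# Preprocessing choices

* **Missingness filter:** features missing in $\ge$ 50% of samples are
  discarded (the comparison is `>=`, so a feature missing in exactly half
  the samples goes).
* **k-NN imputation** (`k = 7`): sample-neighbor, unsupervised. Distances
  are Euclidean over mutually observed features, divided by
  $\sqrt{m}$ where $m$ is the overlap count — without this scaling,
  distances collapse under 26–39% missingness. A missing value is the
  unweighted mean of the feature's observed values among the k nearest
  neighbors; if none of them observed the feature, the feature's overall
  mean is used (with a warning). Neighboring on samples rather than
  features is a documented choice; the upstream protocol does not state
  the orientation.
* **Normalization stand-ins:** the platform-specific transforms of the
  original data (Illumina VST + robust spline normalization; reference-
  based ratio scaling) need raw platform output that is out of scope.
  `normalizeBlock()` offers `log_median` (log2 + per-sample median
  centering) for array-like intensities and `reference_geomean`
  (per-sample division by the geometric mean of complete-case features,
  then log2) for abundance ratios. Both preserve the intent — variance
  stabilization and housekeeping-style reference scaling — and both are
  labeled deviations.
* **Variance filter:** the gene block keeps its `n` most variable
  features (default 10,000), ties broken lexicographically by feature id.

# The synthetic generator

`simulateMultiOmics()` emulates the cohort shape of the motivating study:
16 vs 26 samples, three blocks of roughly 10,000 / 943 / 2,637 features
(scalable down; the tests use 200 / 80 / 120), block-wise MCAR
missingness of 26% and 39% in the protein and peptide layers, paired
patient labels, and continuous plaque-trait covariates.

The planted signal enters through a low-rank latent model rather than
independent mean shifts: sample $i$ carries a latent score $z_i$ on
factor 1 with class means $\pm\delta_z/2$, and each informative feature
is $s\,z_i + \varepsilon$, $\varepsilon \sim N(0, \sigma^2)$. This makes
the cross-block covariance that the design-coupled model exploits
actually exist. The calibration ties the loading to the effect size,
$s = e/2$ and $\delta_z = 2\sqrt{e^2/4 + \sigma^2}$, which has two exact
consequences: each informative feature's standardized group difference is
$s\delta_z/\sqrt{s^2+\sigma^2} = e$ for every noise level, and a zero
effect size plants nothing at all, so "informative" features are then
exchangeable with noise features (the null tests rely on this).

Defaults: `effectSize = 2`, `blockNoiseSd = 2`. The residual SD matters
only through the latent separation $\delta_z = 2\sqrt{1+\sigma^2}\,$ (at
$e=2$): it is the ceiling on what any multi-feature classifier can do,
$\mathrm{AUC} \le \Phi(\delta_z/\sqrt2)$. At $\sigma = 2$ that ceiling is
$\Phi(3.16) \approx 0.999$, which places the default regime where the
motivating study's models operate (cross-validated AUC above 0.95) while
each individual feature remains a realistic, noisy marker (standardized
difference 2). Traits are affine functions of the standardized factor-1
scores plus calibrated Gaussian noise, $\rho z + \sqrt{1-\rho^2}\,
\epsilon$, with default target correlations 0.74, 0.64, and −0.62 —
the magnitudes of the component-trait correlations highlighted in this
literature. Extra latent factors (default one more) add class-neutral
correlated structure to a slice of the noise features.

What the generator does *not* emulate: batch effects, probe-level array
noise, reporter-ion chemistry, non-random missingness, heavy-tailed
abundance distributions, or correlated noise between specific feature
pairs beyond the low-rank factors. Passing tests on this generator
therefore demonstrate correctness of the algorithms under a known model,
not performance on real cohorts.

Because informative features are drawn before missingness is applied, a
planted feature can by chance exceed the 50% missingness filter; the
ground truth reports which informative features survive, and recovery
metrics are computed over survivors.

# Downstream statistics

* **Differential expression:** per-feature log2 fold change (positive =
  higher in the positive/IPH group) with an ordinary paired or Welch t
  test and BH adjustment. Empirical-Bayes variance moderation is
  deliberately not layered on top: the acceptance surface of this package
  is synthetic data with thousands of exchangeable features, where the
  ordinary test is exactly calibrated (the suite checks the null
  rejection rate at 5%).
* **Correlations:** Pearson r with the exact t-transform p-value,
  `componentTraitCorrelation()` pairs each component's scores with each
  trait.
* **Overrepresentation:** upper-tail hypergeometric p per gene set
  against an explicit background universe, BH across sets. Upper tail
  only — the protocol tests overrepresentation. The cofactor test
  (`srfCofactorTest()`) is the same statistic applied to
  cofactor-regulated reference sets; the universe is an explicit argument
  because published analyses of this kind rarely state it and the
  p-values are sensitive to the choice.
* **Preranked GSEA:** classic running sum with hit weights
  $|\mathrm{stat}|^w$ (default $w=1$) normalized over the in-set total
  and miss decrements $1/(N-s)$; ES is the signed extremum. Significance
  uses gene-label permutations (sample permutation is impossible from a
  preranked list): NES divides ES by the mean |ES| of same-sign
  permutations and the p-value is the same-sign tail fraction, which is
  uniform under the null (checked by KS in the suite).
* **Validation classifiers:** ridge-penalized logistic regression
  (`glmnet`, alpha 0, fixed small lambda — the unpenalized likelihood is
  ill-posed at $p \gg n$, and the common Python implementation this
  protocol names is L2-penalized by default), RBF SVM with
  `gamma = 1/n_features`, and a default decision tree. Per fold, features
  are standardized on the training fold only; AUC uses the classifier's
  continuous decision score; fold AUCs are averaged (pooling held-out
  scores per repeat is the alternative; averaging is the package's
  documented choice).

# Reproducibility and numerical notes

Every stochastic routine takes an explicit seed and restores the caller's
RNG state. `runPipeline()` derives per-stage seeds from the global seed
and the stage name, so inserting a stage never perturbs earlier stages'
randomness, and rerunning a config reproduces byte-identical artifacts.
Patient pairing is available to the differential-expression stage but is
*not* respected in CV fold construction, matching the protocol this
package follows; treat reported CV performance accordingly.

Desk-scale problem sizes used throughout the tests and the acceptance
script — blocks of 200/80/120 features, 42 samples, 50 CV repeats, 100
resample copies — are the package's chosen defaults for fast, exact
verification; all counts scale up by argument. Known limitations: binary
phenotypes only; no missing-data-tolerant fitting (imputation is
upstream); no nested cross-validation, so tuned-model CV estimates carry
the usual selection optimism (the suite demonstrates the leak a naive
pipeline would add, and that the package's in-fold re-estimation avoids
it).
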