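---
title: "Bitter-peptide QSAR with integrated descriptors and BOSS variable selection"
author: "peptideBOSS authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bitter-peptide QSAR with integrated descriptors and BOSS variable selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptideBOSS)
```

## The modelling problem

Short peptides released during protein hydrolysis are often bitter, which
limits the use of otherwise valuable bioactive hydrolysates as food
ingredients. The measurable quantity is the bitter-taste threshold `T`, the
lowest concentration (in mol/L) at which a sensory panel detects
bitterness. Modelling works on the **bitterness activity**

$$ \mathrm{activity} = \log_{10}(1/T), $$

so a dipeptide with a 19 mM threshold has activity
`-log10(0.019) = 1.72`, and more bitter peptides (lower thresholds) have
higher activities. We use base-10 logarithms, the usual convention for
`log(1/T)`-type QSAR responses.

A quantitative structure–activity relationship (QSAR) model predicts this
activity from numeric descriptors of the peptide's structure. For short
peptides the standard descriptors are **amino-acid scales**: published
tables assigning each of the 20 coded amino acids a fixed-length vector of
physicochemical parameters (hydrophobicity, bulk, electronic properties,
...). This package integrates 14 such scales — 3z, 5z, DPPS, MS-WHIM,
ISA-ECI, VHSE, FASGAI, VSW, T, ST, E, V, G and HESH, with 3, 5, 10, 3, 2,
8, 6, 9, 5, 8, 5, 3, 8 and 12 parameters respectively — for a total of 87
parameters per residue position. A peptide of length $L$ is encoded
position-wise into $87L$ variables: 174 for dipeptides, 261 for
tripeptides, 348 for tetrapeptides. Each variable is named
`N{position}-{set}-{parameter}` (N1 is the N-terminus), e.g. `N1-3z-1`.

Because the models are position-wise, they are **length-specific**:
datasets of mixed lengths are rejected rather than padded.

The numeric values of the 14 published scales are not redistributed with
the package; they are loaded from user-supplied delimited tables
(`loadDescriptorSet()`, `readRegistryManifest()`). For development and
validation, `syntheticScales()` builds registries with the canonical shape
but standard-normal values — synthetic stand-ins that carry no
physicochemical meaning.

## The regression model

With up to 348 variables and 23–52 samples, ordinary least squares is not
identifiable; the field's standard tool is **partial least squares (PLS)**
regression, which projects X onto a small number $A$ of latent components
chosen to covary maximally with the response. We implement single-response
PLS1 by NIPALS. With one response the component weight vector is
proportional to $X^\top y$, so each component is closed-form and the fit is
fully deterministic; no inner iteration or convergence tolerance is
involved.

Conventions, fixed once:

* **Autoscaling.** All X columns and y are centred and scaled to unit
  variance before fitting, using the sample ($n-1$) standard deviation
  (the chemometrics convention). The regression vector on this scale *is*
  the vector of **standardized regression coefficients** used for
  importance analysis; it is invariant to affine rescaling of any raw
  input column.
* **Zero-variance columns** (common in bootstrap subsets of
  categorical-like descriptor columns) are scaled to exactly zero and
  consequently receive a coefficient of exactly zero; they are flagged,
  not an error.
* **Component selection.** The number of components is chosen
  automatically as the $A \in \{1..A_{\max}\}$ maximizing the
  cross-validated $Q^2$, ties going to the smaller $A$;
  $A_{\max} = \min(10, n-1, p)$ by default, further capped by the smallest
  training-fold size.

## Validation statistics

Model fit is summarized by $R^2$ and RMSE on training predictions;
predictive ability by 5-fold cross-validation. Within each fold the
autoscaling is refit on the training portion only (no information leakage;
`scaleMode = "global"` reproduces the variant where scaling parameters come
from the full data). Held-out predictions are pooled over folds, then

$$ \mathrm{RMSECV} = \sqrt{\tfrac1n \sum_i (y_i - \hat y_i)^2},
\qquad Q^2 = 1 - \frac{\sum_i (y_i - \hat y_i)^2}{\sum_i (y_i - \bar y)^2}, $$

with $\bar y$ the **observed** mean of y. This preserves the baseline
identity: a model whose held-out predictions equal the observed mean gets
exactly $Q^2 = 0$. (Defining $\bar y$ as the mean *predicted* value would
break that identity, so we do not.) Folds are uniform, unstratified, sizes
differing by at most one, deterministic for a seed.

## BOSS variable selection

Most of the 87 parameters per position are redundant for any one response.
**Bootstrapping soft shrinkage (BOSS)** selects a small subset by combining
weighted bootstrap sampling of *variable space* with model population
analysis:

1. Start from uniform weights over all $p$ variables.
2. Draw 1000 bootstrap subsets: each draws (current pool size) variables
   with replacement, with probability proportional to the weights; the
   subset is the deduplicated support of the draws (≈63% of the pool under
   uniform weights).
3. Fit a PLS submodel per subset (automatic component selection) and score
   it by RMSECV. All submodels of a run share one fold assignment so their
   RMSECVs are comparable.
4. Extract the best 10% of submodels (lowest RMSECV; ties broken by
   smaller subset, then draw order). The new weight of each variable is
   its summed **absolute** standardized coefficient across the extracted
   models, normalized to sum one. Signed sums could cancel and produce
   negative weights, which bootstrap sampling cannot use, so magnitudes
   are summed.
5. The next pool is the union of variables the extracted models used;
   repeat from step 2 until one variable remains.

The winner is the subset with the smallest RMSECV seen during the whole
shrinkage. Two details that the method's description leaves open were fixed
as follows and are exposed in `bossConfig()`:

* **Draw count per subset = current pool size** (not the original $p$).
  This yields the characteristic ~63% shrinkage per iteration that gives
  the method its soft-shrinkage character.
* **Stagnation rule.** The union-of-best-models pool update cannot discard
  a handful of variables that are all genuinely useful, so the pool can
  stop shrinking short of size one. Once the pool has been static for
  `stallIterations` (default 5) consecutive iterations, the candidate
  space is fixed and the minimum-RMSECV subset has already been recorded,
  so the run terminates; `maxIterations` (default 100) remains a hard
  safety cap, and hitting it flags the result as unconverged.

Because the algorithm is stochastic, the analysis is repeated (100 runs in
the reference workflow; `repeatBOSS()`), each run re-randomizing folds and
bootstrap streams from derived seeds. Statistics are reported as mean ± SD
across runs, and **variable importance** combines two views:

* the **selection frequency** — the fraction of runs whose winning subset
  contains the variable; variables above a strict 60% cutoff are reported
  as important (`frequentVariables()`), and
* the **standardized coefficients** of the best model — the run with the
  smallest RMSECV, refit on the full dataset (`bestModelReport()`); the
  magnitude ranks importance, the sign gives the direction of the effect
  on bitterness.

## The synthetic-data generator

`generateDataset()` emulates the statistical structure of the real
datasets with known ground truth: random sequences of one length
(uniform over the 20 residues; duplicates allowed, as in real data),
descriptor encoding through any registry, and an activity

$$ y = X_s[, \mathrm{signal}] \cdot \beta + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2), $$

where $X_s$ is the column-standardized design matrix — effects are defined
on standardized columns so that effect sizes are comparable across
descriptor sets of different scales, mirroring the pipeline's autoscaling.
Thresholds are $10^{-y}$ clipped to a plausible molar range (default
$10^{-5}$–$1$ M; source thresholds are mM-scale).

The validation fixture used throughout the tests plants 5 signal variables
with unit effects among the 174 encoded dipeptide variables, at $n = 60$
and noise SD 0.2 — sample sizes and dimensionality matching the dipeptide
modelling setting, with a generous signal-to-noise ratio so that recovery
failures indicate algorithmic faults rather than statistical ambiguity.

What the generator does *not* emulate: sensory-panel measurement error
beyond additive Gaussian noise, the physicochemical correlation structure
of real published scales (synthetic scales are independent normals; real
descriptor sets are mutually correlated), and composition biases of
literature-compiled peptide sets. Passing recovery tests therefore
demonstrate algorithmic correctness, not field performance on real
bitterness data.

Note one structural property the generator *does* share with real data:
all 87 parameters of a position are functions of the same categorical
residue, so within-position columns are linearly dependent (rank ≤ 19 per
position). Selection can thus legitimately return a proxy correlated with
a planted variable; the recovery criterion (≥4 of 5 planted variables) is
designed around this.

## Numerical and design choices

* PLS1/NIPALS coefficient paths are computed for all $1..A_{\max}$ in one
  pass; the compiled kernel (RcppArmadillo) and the pure-R `fitPLS()` are
  the same algorithm and are held equal by tests.
* Degenerate inputs: response deflated to zero before $A_{\max}$ components
  (rank deficiency) truncates the path, repeating the last informative
  coefficient vector; constant y in a training fold scales by 1.
* Ties: component selection and submodel ranking break ties toward
  parsimony (smaller $A$, smaller subset), then draw order — making every
  run deterministic for its seed.
* All randomness flows through R's RNG under explicit seeds (`withSeed()`
  restores the caller's RNG state); per-run and per-stage seeds are derived
  from a master seed, so every artifact is reproducible end to end.
* Peptide thresholds are stored in molar units; table readers accept a
  `units` column (`M`/`mM`) and normalize, since source literature reports
  mM.

## Problem sizes used in the test suite

The packaged tests and the acceptance script run the complete pipeline at
sizes chosen to exercise every code path while completing quickly on one
CPU: the sparse-signal recovery study uses 50 repeated BOSS runs at the
default 1000 subsets per iteration on the 60 × 174 dipeptide fixture; the
null-model calibration uses 200 pure-noise replicates at $n = 24$; the
bootstrap-law check uses 10,000 repetitions at $p = 100$. The pipeline
itself has no size limits beyond memory.

## Known limitations

* The 14 published scale tables are not bundled; reproducing the original
  bitterness models additionally requires transcribing the peptide
  threshold lists and scale values from the literature into the supported
  table formats.
* Only single-response PLS1 is implemented (the bitterness activity);
  multi-response PLS and orthogonalized variants are out of scope.
* The exact component-selection rule ("rules based on Q²") and the PLS
  implementation of the original MATLAB workflow are unspecified; the
  maximize-Q² rule here is this package's declared convention, so selected
  component counts need not match published ones even on identical data.
* BOSS run time scales roughly with `nSubsets × iterations × n × pool`;
  very wide problems (thousands of variables) will want a smaller
  `nSubsets` during exploration.
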