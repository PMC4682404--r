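---
title: "Principal component analysis for designed experiments: methods and design notes"
author: "depca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Principal component analysis for designed experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depca)
```

## The problem

Ordinary PCA summarizes a sample-by-item matrix **X** through the singular
value decomposition **X** = **U D V**\*, with sample scores
**Y**~s~ = **X V** and (here) item scores **Y**~i~ = **X**\***U**. Applied
to experimental data — transcriptome, proteome, toxicology panels — this
has three recurring defects:

1. **No generality.** The axes and the unit of size are functions of the
   particular matrix, so scores from different experiments cannot be
   compared or integrated.
2. **Noise and bias sensitivity.** Every sample gets equal weight, so
   individual differences among replicates bend the axes, and a group
   over-represented in the matrix drags the leading axes toward itself.
   These are not single-item outliers (robust SVD does not help); they are
   small differences spread over many items.
3. **Hard-to-interpret axes**, because the axes mix the design's group
   structure with replicate-level fluctuation.

`depca` addresses all three by separating *finding* the axes from
*applying* them:

* **Reference centering.** The origin of the component space is an
  experiment-defined reference *r*: the item-wise mean of a designated
  control group, or the grand mean when no control exists
  (`computeReference()`). Centered data `X[k, l] = s[k, l] − r[l]` express
  each sample as its difference from the reference, and a score of zero
  means "no difference from the control".
* **Training data.** Axes are identified by SVD of a training matrix
  **T** whose rows are group representatives — means by default, trimmed
  means or medians when outlying replicates are a concern
  (`buildTraining()`, `fitAxes()`). Averaging repeats reduces noise;
  building one row per group removes group-size bias. **T** is *not*
  re-centered before the SVD: the reference already defines the center of
  rotation, and subtracting T's column means again would silently restore
  the grand-mean origin the method replaces. `test-pca-equivalence.R`
  pins this down.
* **Scaling.** Because each loading column is a unit vector over the
  m~f~ functional items, a sample score grows like √m~f~ (each of the
  m~f~ inner-product terms contributes on the order of m~f~^−1/2^).
  Dividing by √m~f~ (`scaleSampleComponents()`) yields the average
  contribution per item, so scores keep the same magnitude whether axes
  were found in all items or in a filtered subset. Item scores are
  divided by √n~t~, the number of training rows, for the same reason
  (`scaleItemComponents()`). After both scalings, samples and items can
  be drawn on identical axes (`jointComponentTable()`).
* **Sharing.** An `AxisModel` — loadings, singular values, reference,
  n~t~, m~f~, sign convention — serializes to a text container
  (`saveAxisModel()`), so another laboratory can project its own samples
  onto the same axes (`applyAxisModel()`) and classify unknown material
  by nearest group representative (`classifySamples()`).

## Zero replacement as a fail-safe

Missing cells of **X** are replaced with exactly 0, and the same
replacement removes whole items (e.g. genes negative in the ANOVA
filter, via `zeroOutItems()`). Zero means "no difference from the
reference", so every replacement moves scores *toward* the origin —
conservative with respect to claiming an effect. m~f~ counts the items
not excluded; per-sample missing cells do not change m~f~. The
alternative — a per-sample m~f~ — would give each sample its own scale
divisor, destroying the comparability the scaling exists to provide, and
no consistent definition of per-sample scaling exists once items are
shared across samples; we therefore use the single matrix-level m~f~
throughout.

## The ANOVA filter

Where probe-level data exist, expression changes are screened per gene
with an additive two-factor fixed-effects model,
`value ~ probe + group` (probe sensitivity plus group effect, no
interaction), and the group factor's F test at a raw per-gene threshold
of 0.01 (`anovaGroupTest()`). Notes on the conventions adopted:

* An F test has no two-sided variant; the threshold is applied to the
  standard one-sided F p value.
* No multiple-testing correction by default (the screen is a filter, not
  an inference); a Benjamini–Hochberg mode is available via
  `adjust = "BH"`.
* Genes with < 2 probes, designs with < 2 groups, zero residual degrees
  of freedom, constant values, or missing cells are *untestable*: never
  positive, never an error.
* Internally the least-squares fits are batched: genes sharing a probe
  count share one design matrix, so a single multi-response QR
  factorization handles thousands of genes. Tests verify the resulting F
  against an explicit sum-of-squares decomposition and against
  `anova(lm(...))`.
* Without probe-level data, `geneLevelGroupTest()` offers a one-way
  ANOVA on gene-level values — an approximation, since the probe term
  has already been absorbed by summarization.

## Deterministic signs

An SVD fixes each axis only up to a joint sign of the matched columns of
**V** and **U**. To make shared models reproducible, `unifySigns()`
negates both columns whenever the loading of largest absolute value in
that column of **V** is negative (ties broken by the lowest item index).
The convention is idempotent and preserves **U D V**\* exactly.

## Numerical choices

* **Axis retention**: singular values below `tolRank = 1e-12` times the
  largest are numerically null and dropped; retained axes never exceed
  min(n~t~, m~f~). Without the cutoff, null axes would contribute pure
  rounding noise to scaled scores.
* **Trimmed mean**: default trim fraction 0.2 per tail. With fewer than
  5 samples per group trimming is meaningless and degrades to the mean
  with a warning; a fraction that would trim an entire group is an
  error.
* **Item reconciliation** when applying a shared model: items are
  matched by id; model items absent from the new matrix contribute 0
  (fail-safe, toward the origin), matrix items unknown to the model are
  dropped, and both counts are logged.
* **Classification**: Euclidean distance on scaled components over a
  configurable number of leading axes (default all retained), ties
  broken by training-row order. The original analyses establish
  separation visually; a metric had to be fixed and Euclidean distance
  in the scaled space is the natural choice because that space is where
  magnitudes are comparable.
* **Text precision**: all writers emit `%.12g`, so shared axis files
  reproduce scores to about 1e-10 across platforms.

## What the simulator emulates — and what it does not

`simulateExperiment()` generates group-structured expression data:
item value = baseline + loadings · latent(group) + N(0, σ). The default
configuration is a toxicology-style design: 7 groups × 5 repeats — a
control `C` at the latent origin, three "toxic" groups (`G1`, `G3`,
`G5`) sharing a strong first latent axis with spread on the second, and
three "nontoxic" groups near the control — 2000 items of which a
quarter load on 2 latent axes, latent effect 3 × the individual-noise
sd, and the control group as reference. Optional regimes:

* `outlierFraction` / `outlierMagnitude`: whole samples receiving offset
  spikes in ~10% of items;
* `heterogeneousItemFraction`: item subsets whose latent contribution
  jitters per sample (gene clusters with high within-group variance);
* `heterogeneousGroup`: one group whose samples carry extra per-item
  individual noise — the "within-group-variable group" used to
  demonstrate group bias. The jitter sd defaults to the latent effect
  scale, a clearly heterogeneous regime.

Everything is reproducible bit-for-bit from the seed, and generation
consumes the RNG in a fixed order.

The simulator does **not** emulate array-specific artifacts (spatial
effects, cross-hybridization), heavy-tailed single-item outliers as the
dominant noise, correlated baseline drift between batches, or realistic
gene–gene correlation beyond the low-rank latent structure. Passing
tests therefore demonstrate the algebraic and statistical properties of
the method — scaling law, axis contracts, calibration, bias response —
not the biological fidelity of any particular microarray data set.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run the method at desk scale:
random matrices up to 20 × 500 for the factorization contracts,
10 × 200 for the scaling law, 10,000 null genes (3 probes, 2 groups × 4
samples) for filter calibration, 50 seeds of the 7 × 5 design at 300–400
items for classification and bias sensitivity, and 20 seeds for range
stability. These sizes make every claim checkable in seconds while
keeping the Monte-Carlo standard errors small relative to the asserted
tolerances; the properties checked are size-invariant (the scaling law
in particular is exact at any m~f~).

## Known limitations

* The group-bias and classification demonstrations depend on the
  synthetic regimes described above; real data add structure the
  simulator omits.
* `geneLevelGroupTest()` is not the probe-level test; with few
  replicates it is noticeably less powerful.
* Robust SVD alternatives are deliberately not implemented: on this
  class of noise (many small differences, not single-item outliers)
  they do not help, and the training-data mechanism is the intended
  remedy.
* Scores of samples far outside the training envelope are extrapolations;
  classification distances remain well-defined but the nearest
  representative may be meaningless. Inspect `distance` rather than
  trusting the label alone.

## A worked sketch

```{r example}
sim <- simulateExperiment(simulationConfig(nItems = 300,
                                           nInformative = 150, seed = 1))
fit <- depcaFit(sim$matrix, sim$design)
fit$model
round(componentScores(fit$trainingScores)[, 1:2], 3)
cls <- classifySamples(fit$sampleScores, fit$trainingScores)
table(groupOf(sim$design)[cls$sample_id], cls$nearest)
```

The training representatives separate along the first two scaled axes
(toxic groups share sPC1), every sample classifies into its own group,
and saving the model with `saveAxisModel()` lets any later experiment
reproduce these coordinates.
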