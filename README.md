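# depca — principal component analysis for designed experiments

`depca` is an R package for summarizing grouped, repeated-measurement
matrix data — bulk or single-cell expression, proteome or metabolome
panels, toxicology screens — with principal components that remain valid
*outside* the data set they were computed from. It is aimed at analysts
who need to compare component scores across experiments, classify new
samples on previously established axes, or keep axes interpretable in
the presence of replicate noise and unbalanced group sizes.

## The method

Ordinary PCA of a sample-by-item matrix **X** = **U D V**\* gives scores
**Y**<sub>s</sub> = **X V** whose directions and magnitudes depend on the
particular matrix: noise and over-represented groups bend the axes, and
the unit of size changes with the number of items. `depca` makes three
changes:

1. **Reference centering.** Data are centered on an experiment-defined
   reference *r* (control-group mean, or grand mean):
   `X[k, l] = s[k, l] − r[l]`. Missing or removed items become exactly 0
   — "no difference from the reference" — so they pull scores toward the
   origin, never away (fail-safe).
2. **Training-data axes.** Axes come from the SVD of a training matrix
   **T** of *group representatives* (means, trimmed means or medians of
   each group's centered samples): **T** = **U**<sub>T</sub>
   **D**<sub>T</sub> **V**<sub>T</sub>\*. Samples are then projected as
   **Y**<sub>s</sub> = **X V**<sub>T</sub>, items as
   **Y**<sub>i</sub> = **T**\***U**<sub>T</sub>. Averaging repeats
   suppresses noise; one row per group removes group-size bias; **T** is
   *not* re-centered (the reference is the center of rotation).
3. **Scaling.** A sample score is proportional to √m<sub>f</sub>, the
   square root of the number of functional items (each loading column is
   a unit vector over m<sub>f</sub> items). Scaled scores
   **Z**<sub>s</sub> = m<sub>f</sub><sup>−1/2</sup> **Y**<sub>s</sub> and
   **Z**<sub>i</sub> = n<sub>t</sub><sup>−1/2</sup> **Y**<sub>i</sub>
   have a size unit independent of how many items (or training rows)
   were used, so scores are comparable across item subsets and
   experiments, and samples and items can be shown together on identical
   axes.

The fitted `AxisModel` (loadings, singular values, reference,
n<sub>t</sub>, m<sub>f</sub>, deterministic sign convention) serializes
to a plain-text container, so axes can be shared between laboratories
and unknown samples classified by nearest group representative in the
scaled component space.

A per-gene filter is included for probe-level data: an additive two-way
ANOVA, `value ~ probe sensitivity + group effect`, keeping genes whose
group effect is significant at 0.01; negative genes are zero-replaced.

## A worked example

```r
library(depca)
sim <- simulateExperiment(simulationConfig(nItems = 300,
                                           nInformative = 150, seed = 1))
fit <- depcaFit(sim$matrix, sim$design)
fit$model
#> AxisModel: 6 axes over 300 items; n_t = 7, m_f = 300
#>   singular values: 72.77 34.73 16.22 8.215 7.564 ...
#>   sign convention: largest_loading_positive
round(componentScores(fit$trainingScores)[, 1:2], 3)
#>     sPC1   sPC2
#> C  0.000  0.000
#> G1 2.461  1.158
#> G2 0.101  0.793
#> G3 2.452 -0.001
#> G4 0.159  0.000
#> G5 2.353 -1.210
#> G6 0.106 -0.766
```

The simulated design mirrors a toxicology screen: a mock control `C`
(the reference, hence at the origin), three toxic compounds `G1, G3, G5`
and three nontoxic ones `G2, G4, G6`, five repeats each. On the scaled
axes the first component separates toxic from nontoxic compounds
(sPC1 ≈ 2.4 vs ≈ 0.1) and the second separates the toxic compounds from
one another — the axes read directly as design contrasts. Classifying
every sample against the training representatives recovers the design
perfectly:

```r
cls <- classifySamples(fit$sampleScores, fit$trainingScores)
table(groupOf(sim$design)[cls$sample_id], cls$nearest)
#>      C G1 G2 G3 G4 G5 G6
#>   C  5  0  0  0  0  0  0
#>   G1 0  5  0  0  0  0  0
#>   ...  (all 35 samples on the diagonal)
```

`saveAxisModel(fit$model, "axes.tsv")` writes the axes; any later
experiment can `loadAxisModel()` + `applyAxisModel()` to score its own
samples in the same coordinates.

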