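---
title: "Neighbourhood collaborative filtering for drug-response imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighbourhood collaborative filtering for drug-response imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiwcf)
```

## The problem

Large drug screens expose panels of cancer cell lines to compound libraries
and record a sensitivity value per (cell line, drug) pair — the natural log
of the IC50 concentration, or an activity area. The resulting matrices are
incomplete: assays fail, compounds join a screen late, lines drop out. Many
downstream analyses (biomarker discovery, drug repositioning) want the full
matrix, so the missing entries must be imputed.

The premise of this package is the recommender-system analogy: cell lines
behave like users, drugs like items, and similar cell lines respond
similarly to the same drug. Imputation then becomes neighbourhood
collaborative filtering with side information — gene-expression profiles for
the cell lines, binary structural fingerprints for the drugs.

## The model

**Baseline.** Observed responses carry strong additive row and column
effects. With $\mu$ the mean of all observed entries, the baseline for entry
$(u,i)$ is $b_{ui} = \mu + b_u + b_i$, where the biases are regularised
means computed in closed form in two passes — drugs first,

$$b_i = \frac{\sum_{u \in U(i)} (r_{ui}-\mu)}{\lambda_2 + |U(i)|}, \qquad
  b_u = \frac{\sum_{i \in U(u)} (r_{ui}-\mu-b_i)}{\lambda_3 + |U(u)|},$$

with $U(\cdot)$ the observed index sets and $\lambda_2 = 5$,
$\lambda_3 = 2$ by default. Drug biases are estimated before cell-line
biases because the cell-line pass consumes the drug-adjusted residuals.
Rows or columns with no observations get bias zero (they cannot occur after
loading, which drops them, but the contract is defined).

**Similarities.** Three definitions, on each axis:

* `coef` — side information only: Pearson correlation of expression
  profiles (cell lines), Jaccard coefficient of fingerprints (drugs);
* `rpcc` — response only: Pearson correlation of two rows/columns of the
  response matrix over their pairwise-complete positions;
* `mrpcc` — the elementwise product of the two, promoting pairs consistent
  in both views.

Raw similarities $w$ are then shrunk by each pair's support
$w \leftarrow \frac{|U(i,j)|}{|U(i,j)|+\lambda_4}\,w$ (default
$\lambda_4 = 50$; the factor is exactly $1/2$ when the overlap equals
$\lambda_4$) and case-amplified
$w \leftarrow w\,|w|^{\rho-1}$ (default $\rho = 2.5$), which exaggerates
strong weights and suppresses weak ones while preserving sign and ranking.
The pipeline order is fixed: raw → shrink → amplify.

**Prediction.** For a target $(u,i)$, the $k$ most similar drugs with an
observed response in cell line $u$ and the $k$ most similar cell lines with
an observed response to drug $i$ are selected among candidates with strictly
positive amplified weight; each orientation contributes a weighted mean of
baseline residuals and the final estimate averages the two corrections on
top of $b_{ui}$. If one orientation has no usable neighbours its term is
dropped (no halving); if both are empty the baseline is returned and
flagged as a fallback.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `lambdaDrug` ($\lambda_2$) | 5 | shrinks drug biases toward 0 |
| `lambdaCell` ($\lambda_3$) | 2 | shrinks cell-line biases toward 0 |
| `lambda4` | 50 | support scale of similarity shrinkage |
| `rho` | 2.5 | case-amplification power ($\ge 1$) |
| `kCell` | 20 | cell-line-oriented neighbourhood size |
| `kDrug` | 5 | drug-oriented neighbourhood size |
| `minOverlap` | 3 | minimum pairwise overlap for a defined RPCC |
| `srThreshold` | 1 | sensitive/resistant cut in SD units |

The neighbourhood sizes are asymmetric because screened drug panels are an
order of magnitude smaller than cell-line panels (tens of drugs versus
hundreds of lines); a drug-side neighbourhood of 5 keeps only close
structural/behavioural analogues, while 20 cell lines is small relative to
a panel of several hundred. Both are surfaced in every result's
configuration snapshot because reported accuracy depends on them.

## Numerical choices and edge cases

* Correlations over pairwise-complete positions are computed by masked
  cross-products, clamped to $[-1, 1]$ and symmetrised to remove float
  asymmetry. Pairs with overlap below `minOverlap`, or with zero variance
  on the overlap, get similarity 0 — the "no usable evidence" value that
  the shrinkage limit also produces.
* Constant expression profiles have undefined correlations; these are set
  to 0 with a warning.
* The similarity diagonal is zeroed after amplification, so an item can
  never be its own neighbour.
* Only strictly positive amplified weights are eligible as neighbours: with
  mixed-sign weights the denominator $\sum w$ can approach zero and the
  interpolation degenerates. A consequence worth knowing: the product
  definition `mrpcc` turns two negative factors into a positive weight, so
  a pair dissimilar in both views ranks as similar. This is inherent to the
  product definition and is kept as defined.
* Orientation-term denominators below $10^{-12}$ are treated as empty.
* Neighbour ties are broken by label order (stable sort), making every
  result bitwise reproducible.
* Cross-validation masks the held-out fold out of the training matrix
  before the baseline and every response-derived similarity are computed;
  a metamorphic test perturbs held-out values and asserts that nothing
  used to predict them changes.
* Undefined per-drug metrics (fewer than two test values, or a constant
  vector) are excluded from drug averages and counted, rather than coerced
  to 0, to avoid biasing the averages.

The sensitive/resistant subsets ($PCC_{S/R}$, $RMSE_{S/R}$) are the cell
lines whose observed response deviates from the drug's observed mean by
more than `srThreshold` standard deviations, both tails. Definitions of
"extreme responders" vary across studies; this mean ± t·SD rule is the
simplest symmetric choice and is configurable.

## What the synthetic generator emulates

`generateSynthetic()` draws
$r_{ui} = \mu_0 + b_u + b_i + \langle c_u, d_i\rangle + \varepsilon$ with
Gaussian biases ($\mathrm{sd}\,b_u = 1$, $\mathrm{sd}\,b_i = 1.5$ — drugs
differ in potency far more than lines differ in general resistance), unit
Gaussian latent factors of rank $d = 3$, and noise at 20% of the latent
signal's SD by default. Expression is a linear readout of the cell factors
plus noise; fingerprints threshold a linear readout of the drug factors at
zero (≈50% bit density, all-zero rows resampled). Masking is uniform at
rate $q$ (defaults to 0.2; presets mirror the two public panel shapes:
652 × 135 with $q = 0.197$ and 491 × 23 with $q = 0.0375$).

Default panel size is 200 × 30 — large enough for stable bias recovery and
meaningful neighbourhoods, small enough that a full 10-fold CV takes about
a second.

What it does **not** emulate: missingness in real screens is not random
(drugs are tested on chosen subpanels); responses are heteroscedastic and
bounded; tissue types induce block structure; expression similarity is
driven by lineage far more than by drug-response-relevant programs. Tests
passing on this generator therefore demonstrate correctness of the
machinery and sane statistical behaviour under the model's own assumptions,
not performance on any real panel.

Two deliberate variations of the generator appear in the test-suite
conditions:

* *Noiseless rank-2 panels* (all noise channels zero) isolate the
  interpolation's own error: cross-validated drug-averaged PCC exceeds
  0.95, the residual gap being the neighbour-averaging bias that no
  neighbourhood method escapes at finite $k$.
* *Degraded side channels* (side-information noise SD 5 against a latent
  signal SD of $\sqrt{3}$) emulate the empirical situation in real panels
  where expression and structure are far weaker response predictors than
  response profiles themselves: there, `rpcc` clearly beats `coef` and
  `mrpcc` matches or slightly exceeds `rpcc`. With clean side channels the
  three definitions converge — the ordering is a property of the
  information content of the inputs, not of the code path.

## Evaluation protocol

`crossValidate()` partitions observed entries (not rows or columns)
uniformly into 10 folds of near-equal size, holds each fold out in turn,
refits everything on the rest, and pools each drug's test predictions
across the folds of a repetition before computing per-drug PCC/RMSE. The
summary reports unweighted drug-averaged means and the SD across drugs
pooled over repetitions. One repetition is the default; the statistic
stabilises quickly and repetitions scale linearly in cost.

```{r cv-example}
sim <- generateSynthetic(syntheticConfig(m = 60, n = 12, seed = 3))
crossValidate(sim$response, sim$expression, sim$fingerprints,
              definition = "mrpcc", folds = 10, seed = 1)
```

As an optional integration check on real data, the published panel
matrices distributed by the method's authors can be downloaded, read with
`readResponseMatrix()` / `readSideMatrix()`, and run through
`crossValidate()`; on the denser activity-area panel the drug-averaged PCC
should land in the low-to-mid 0.7s. This requires a network download and is
deliberately not part of the test suite.

## Known limitations

* Performance degrades with matrix sparsity: `rpcc`/`mrpcc` lean on
  co-observed responses, and heavily incomplete panels leave them
  shrunk toward zero (by design).
* The prediction loop is plain R over target entries; imputing very large
  panels (hundreds of thousands of entries) takes minutes, not seconds.
* Only the closed-form two-pass baseline is provided, not iterated
  alternating re-estimation.
* Interpolation weights are fixed by the similarity pipeline, not learned
  by least squares.
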