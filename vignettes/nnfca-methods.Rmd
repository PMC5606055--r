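---
title: "Sensitivity-ranked feature selection and coupled-connection networks for CHD risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensitivity-ranked feature selection and coupled-connection networks for CHD risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nnfca)
```

## The problem and the model

A coronary-heart-disease (CHD) risk predictor is fit to a cohort table: one
record per subject with continuous measurements (age, BMI, total cholesterol,
HDL, systolic and diastolic blood pressure, triglyceride, hemoglobin),
categorical conditions (sex, thyroid disease, chronic renal failure,
hepatitis B/C, cirrhosis, smoking, three-level diabetes status), and a binary
outcome — high risk if any of five component conditions (hypertension,
dyslipidemia, stroke, myocardial infarction, angina) is present, low risk
otherwise.

The predictor is a single-hidden-layer feed-forward network with logistic
activations in hidden and output layers:

$$ p(\mathbf{x}) = \sigma\!\big(\mathbf{w}^\top \sigma(W^\top \mathbf{x} + \mathbf{b}) + c\big). $$

What distinguishes the method from a plain multilayer perceptron is an
explicit binary input→hidden **connectivity mask**. Training (full-batch
gradient descent on the mean cross-entropy) zeroes the gradient at masked
positions every step, so masked weights are *exactly* zero before, during and
after training — a hard structural constraint, not a penalty. The mask is
learned from the data in two stages.

### Stage 1: perturbation sensitivity and stepwise elimination

The sensitivity of feature $i$ in a trained network is

$$ \mathrm{Sen}(X, x_i) = \frac{1}{N}\sum_{k=1}^{N}
   \big|\,\mathrm{NNout}_k(X_{x_i+\delta}) - \mathrm{NNout}_k(X)\,\big|, $$

the mean absolute change of the predicted probability when column $i$ is
shifted by a small $\delta$. Absolute differences are used inside the sum:
without them, records whose predictions move in opposite directions would
cancel, and a feature the network relies on heavily could score near zero.

Features are ranked by descending sensitivity (rank 1 = most sensitive, ties
broken by original column order so the ranking is deterministic). The
lowest-ranked feature is removed, the network retrained on the remainder,
validation accuracy recorded, and the process repeated. Sensitivities are
recomputed after every removal — the retrained network redistributes its
weights, so ranks frozen from the first profile would be stale.
`stepwiseEliminate()` traces the full curve out to `maxRemove` stages and
`selectBestStage()` picks the stage of maximal validation accuracy, ties
going to fewer removals. Computing the full curve and taking the global
maximum was a deliberate choice over early stopping at the first dip:
accuracy curves under retraining are noisy, and a one-stage dip frequently
recovers (the packaged reference curve itself rises again after early
stages). The curve is cheap, and the global maximum is a pure function of it.

### Stage 2: feature-correlation analysis and coupled connections

For each selected feature $j$, the whole dataset is *amplified*: column $j$
is shifted by $\delta$ in every record. All feature sensitivities are
recomputed on the amplified data, and

$$ \mathrm{cell}(i, j) = \big|\,\mathrm{Sen}(X_{x_j+\delta}, x_i) -
   \mathrm{Sen}(X, x_i)\,\big| $$

fills an $F \times F$ sensitivity-change matrix. Feature $i \ne j$ is a
**candidate** correlate of $j$ when $\mathrm{cell}(i,j)$ meets or exceeds the
column-$j$ average; a pair $\{i, j\}$ is declared **correlated** only when
candidacy holds in both directions (mutuality). Groups are the connected
components of the pair graph; `buildGroupMask()` then allocates
`hiddenPerGroup` hidden units per group and allows connections only from a
group's features to its own block. Correlated features thus share hidden
units (coupled connections); everything else is decoupled.

Three conventions here were genuinely open and are fixed as follows:

* **Column means include the diagonal** (the amplified feature's own cell).
  On the packaged reference matrix this reproduces eight of nine stored
  column averages exactly at three decimals, which is the strongest internal
  evidence for either convention. The diagonal is nevertheless excluded from
  *candidacy* — a feature is never its own correlate.
* **Thresholding is ≥ with a tolerance `tol`.** On a full-precision computed
  matrix the right tolerance is 0 (the default): cells are of order
  $10^{-5}$ and any absolute slack swamps the rule. When replaying a matrix
  printed at three decimals, `tol = 5e-4` absorbs the rounding of the stored
  cells and averages.
* **Groups are connected components**, not per-pair blocks: the reference
  analysis yields three pairs sharing one feature (DBP), and merging them
  into one coupled block is the reading consistent with "correlated features
  share hidden units". (`hiddenPerGroup` is configurable; with the default 1
  the nine-feature reference example yields a 9–6–1 network with exactly 9
  active input connections.)

### What the correlation stage can and cannot detect

The sensitivity change $\mathrm{cell}(i,j)$ is, to leading order, a mixed
second derivative of the network output along $x_i$ and $x_j$. It is large
when $i$ and $j$ act *jointly* through shared hidden units — which is what
"coupled in generating the output" means operationally. It is therefore a
detector of **joint importance in the trained predictor**, not of marginal
correlation in the input columns: two features can be strongly correlated in
the data, but if the network uses only one of them, amplifying either barely
moves the other's sensitivity. Simulation bears this out: on the default
synthetic cohort the most frequent mutual pairs are those linking the
strongly informative features (age, SBP, diabetes), with the planted
input-correlated SBP–DBP pair detected in a minority of replicates. Users
should read detected pairs as "features the model treats as interacting",
not as estimates of the input correlation structure; for the latter, ordinary
correlation measures on the raw columns are the right tool.

## Preprocessing and data handling

All features are min-max scaled to $[0,1]$ before training or sensitivity
analysis: continuous features by their training-split range, categoricals by
level index over levels − 1 (so the three-level diabetes status becomes 0 /
0.5 / 1). A common scale is a prerequisite for the method, because one
$\delta$ magnitude is applied to every feature; on raw scales a 0.001 shift
of age (years) and of total cholesterol (mg/dL) would be incommensurable.
Scaling parameters are returned for reuse on validation data, re-application
with identical parameters is a no-op, and a constant feature scales to 0
with a warning.

Cohort loading excludes records in a fixed order: any missing field (empty
cell or literal `"Null"`) first, then age below 30, each record counted once
under the first rule it violates. The order is a convention (nothing in the
data dictates it); it matches the order in which the rules are usually
stated, and the `ExclusionReport` class enforces the arithmetic identity
`final = raw − missing − under-age` as a validity condition. Splits are
stratified by outcome (default 70/30, fixed seed) so both classes appear in
both partitions.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `deltaMin`, `deltaMax` | 1e-4, 1e-3 | scaled-feature units | small enough that sensitivity approximates a local derivative; the lower bound keeps $\delta$ bounded away from 0 |
| `nHidden` | 4 | units | the reference topology (16-4-1) for dense stages |
| `learningRate` | 2.0 | — | full-batch descent on a *mean* cross-entropy gradient needs large steps; at 2.0 the loss decreases monotonically and training reaches the logistic-regression ceiling on unit-scaled cohorts of a few thousand records in under a second, while 0.1 leaves the model at the majority-class rate |
| `epochs` | 600 | — | past convergence at the default rate; the elimination loop stays at seconds per stage |
| `initScale` | 0.5 | — | uniform ±0.5 start, the usual scale for logistic units on [0,1] inputs |
| `threshold` | 0.5 | probability | classification cutoff for accuracy/PPV/NPV |
| `tol` | 0 (computed), 5e-4 (printed replays) | sensitivity units | see above |
| `hiddenPerGroup` | 1 | units | smallest coupled block; configurable when groups are large |

Each feature's $\delta$ is drawn from a generator seeded by
`seed + feature index`, so a feature's sensitivity is identical whether
computed alone or inside a profile, and independent of evaluation order; the
amplification step reuses the same per-feature draws so a cell isolates the
amplification effect rather than a re-randomized $\delta$. A per-record draw
mode exists (`perRecord = TRUE`) but the shared draw is the default for
reproducibility.

## Evaluation

`confusionMetrics()` computes PPV = TP/(TP+FP), NPV = TN/(TN+FN) and
accuracy at the 0.5 cutoff, flagging PPV/NPV as undefined (NA) when a
denominator is empty. `rocAuc()` is the rank (Mann–Whitney) statistic — the
probability that a random positive outscores a random negative, ties counted
half — which equals the trapezoidal area under the empirical ROC curve and
is invariant to monotone rescoring. `aucCi()` is a class-stratified
percentile bootstrap (default 95 %, ≥100 resamples); stratification keeps
both classes in every resample. The logistic-regression baseline is an
ordinary `stats::glm` maximum-likelihood fit on the identical split and
scaling, with a flag when the fit reports complete separation.

## The synthetic cohort generator

Real national-survey cohorts cannot be shipped, so `simulateCohort()`
generates tables with known ground truth: all features start as correlated
standard-normal latents (a Gaussian-copula construction — the simplest that
plants both marginal scales and pairwise correlations), continuous features
become mean + sd·z clamped to their bounds, binaries threshold the latent at
the configured prevalence, ordinals cut it at cumulative level
probabilities. The outcome is Bernoulli with a logit linear in the
unit-scaled features plus optional pairwise interaction terms, and
`calibrateIntercept()` bisects the intercept to a target prevalence on a
large probe draw.

`defaultCohortConfig()` emulates the marginal scales of a Korean national
health-survey CHD cohort: 4146 records, nine features (age 52.5 ± 12 years
in [30, 92], BMI 23.97 ± 3.2, total cholesterol 191 ± 36 mg/dL, HDL 51.8 ±
12, SBP 119 ± 16 mmHg, DBP 75.8 ± 10, triglyceride 139 ± 70 mg/dL, smoking
prevalence 0.199, diabetes status 0.633/0.240/0.127), outcome prevalence
calibrated to 0.269. The published tables report means and ranges but no
dispersions; the standard deviations above were chosen once at realistic
survey scale (roughly a sixth to a quarter of the observed range, less for
the heavy-tailed triglyceride). Log-odds effects are planted on age (2.5),
SBP (2.0) and diabetes (1.5) per unit of scaled feature, and one correlated
pair SBP–DBP at ρ = 0.7 carries a joint interaction of 2.5 — sized at the
scale of the largest main effect so the pair genuinely drives the outcome
jointly rather than being decorative.

What the generator does **not** emulate: survey design weights, multi-wave
structure, missingness mechanisms, non-Gaussian joint shapes beyond the
copula, or the real (unknown) dependency structure of the survey. Passing
tests on these cohorts therefore demonstrate that the algorithms recover
*planted* structure under clean conditions, not that they would recover the
corresponding structure in the real survey.

Problem sizes used by the test suite: unit tests run on cohorts of 3–600
records; simulation studies use 20 replicate seeds at n = 600 (planted
ranking and elimination) and n = 4146 (full-pipeline recovery), with
bootstrap intervals at 150–200 resamples.

## Numerical choices and degenerate inputs

* Cross-entropy probabilities are clamped to [1e-12, 1−1e-12]; a non-finite
  loss aborts training with the epoch number.
* `epochs = 0` returns the initialized network unchanged; an elimination
  stage whose retraining fails (e.g. a class collapses) truncates the curve
  with a warning rather than failing the run.
* Rank ties break by column order; stage-accuracy ties break toward fewer
  removals; both make the pipeline a pure function of its seeds.
* A simulation correlation structure that is not positive definite is
  rejected at `chol()` with a configuration error.
* Network topologies are validated structurally: every hidden unit needs an
  incoming connection and every input must reach the output, so a fully
  disconnected feature is rejected at construction rather than silently
  carried.

## The packaged reference tables and their inconsistencies

`inst/extdata/` ships two plain-CSV reference fixtures from a published
nine-feature CHD analysis: a 9 × 9 sensitivity-change matrix (with its
stored column-average row and, implicitly, its candidate annotations) and a
12-stage elimination-accuracy curve. Replaying them exercises the decision
logic bit-exactly: the curve's maximum sits at stage 7, leaving the
nine-feature selected set, and the matrix yields exactly the three mutual
pairs BMI–DBP, To_chole–DBP, SBP–DBP, six groups, and a 9-connection coupled
mask.

Three internal inconsistencies of the reference tables are worth recording,
because the package treats them explicitly rather than papering over them:

1. **The SBP column average.** The stored average is 0.017 but the column's
   cells re-average to 0.0178 (rounds to 0.018). When a stored average row
   is present it is kept as authoritative — this is required for the SBP
   column's DBP cell (0.017) to qualify as a candidate, without which the
   SBP–DBP pair would be lost — and the matrix class's validity check allows
   stored means to deviate from recomputed ones by up to 1e-3.
2. **The triglyceride candidate annotation.** The BMI cell in that column
   (0.037) exceeds the column average (0.010, itself computed including
   0.037), so the thresholding rule yields {BMI, To_chole} where the
   annotation lists only To_chole. The rule's output is used; the
   discrepancy does not change the mutual pairs, because triglyceride is not
   a candidate in BMI's column.
3. **Cell magnitudes.** Cells of 0.001–0.496, with the self-amplification
   diagonal close to each feature's baseline sensitivity, cannot arise from
   any shift of at most 1e-3 on unit-scaled features (computed cells are
   orders of magnitude smaller even at amplification of half the feature
   range). The reference magnitudes are inconsistent with the stated
   formulas; the package implements the formulas and treats the reference
   *decisions* (candidates, pairs, best stage), not the magnitudes, as the
   replayable fixture.

## Known limitations

* The method's correlation stage detects joint importance, not input
  correlation (discussed above).
* Sensitivities scale linearly with $\delta$, so their absolute values are
  only meaningful relative to one another within a profile.
* Full-batch gradient descent with a fixed rate is deliberately simple; no
  momentum, regularization or multi-layer variants are provided.
* Accuracy-based stage selection inherits the noise of a single validation
  split; with small cohorts the selected stage can vary across split seeds.
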