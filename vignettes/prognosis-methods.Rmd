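---
title: "Methods: outcome construction, model comparison, and rule extraction"
author: "xaiPrognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: outcome construction, model comparison, and rule extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xaiPrognosis)
```

This vignette is the package's own account of its models and the design
choices behind them: what is computed, under which assumptions, which
knobs matter, and what the synthetic test bed does and does not show about
real data.

## 1. Clinical outcomes from BPRS totals

The 24-item Brief Psychiatric Rating Scale total has a hard floor of 24
(one point per item), so a raw total is an interval scale with an
arbitrary origin. Percent change is origin-sensitive; computing it on the
raw scale would understate improvement. `rescaleBprs()` therefore shifts
the scale so the floor is zero (24 → 0), and `labelImprover()` defines an
*Improver* as a strictly greater than 20% decrease of the rescaled total
from baseline to follow-up. Two boundary decisions are pinned:

- **Exactly 20% is a non-Improver.** The definition is a strict
  inequality; the boundary case is resolved against improvement.
- **Inclusion needs a rescaled baseline ≥ 5** (raw ≥ 29): below that, a
  single point of change exceeds 20% and the label would be dominated by
  measurement granularity. Note that at exactly 5, a one-point drop is
  exactly 20% and still labels as non-Improver under the strict rule;
  resolution at the inclusion boundary is therefore coarse but
  well-defined.

The continuous outcome `computeDelta()` is follow-up minus baseline
(improvement negative). The sign convention is a package choice; RMSE, the
metric used for the continuous task, is sign-invariant. The rescaling
offset cancels in the difference, which a property test pins.

`outcomeTable()` never drops rows: healthy controls, patients missing
follow-up, and patients below the inclusion floor are flagged with a
reason, and Improver labels exist only for included patients.

## 2. Protocol adjustment

Subjects were scanned under two task protocols on different scanners, an
additive nuisance on every activation measure. `adjustForProtocol()`
regresses each measure on a protocol indicator and returns *standardized
residuals*: raw residual divided by `sqrt(RSS/(n − 2))`, the usual
regression definition with model degrees of freedom. Consequences worth
knowing:

- Residuals are mean-zero and exactly orthogonal to protocol (tested to
  1e-9), so any additive protocol shift is removed.
- Standardization rescales each feature to roughly unit residual sd. The
  operation is therefore *not* idempotent in scale — re-adjusting an
  already adjusted column re-standardizes it — and thresholds learned on
  adjusted features live on the adjusted scale.
- Adjustment is fit on the pooled control + patient sample, once, before
  any train/test split. This mirrors the analysis sequence this package
  implements (adjusted values are the inputs to learning) and puts
  control and patient means on a common scale for the rule-context
  report. The alternative — refit inside every training fold — is
  leakage-free but changes the feature scale per fold; the choice is
  documented rather than hidden.

## 3. The learners

All learners sit behind one interface (`classifierSpec()`, `fitModel()`,
`predictModel()`). Standard algorithms delegate to established
implementations: Naive Bayes (Gaussian, e1071), polynomial-kernel SVM
(e1071, inhomogeneous kernel with `coef0 = 1`), random forest
(randomForest, 500 trees), and a C4.5-style decision tree via rpart with
information-gain splitting. Three components are implemented in the
package because no installed library provides them in the needed form:

- **K\*** — instance-based classification under an entropic
  transformation distance, `K*(y, x) = −ln P*(y | x)`. For real-valued
  features the elementary transformation density is exponential in the
  absolute difference with per-feature scale `x0`, normalized over the
  training candidates. The blend parameter `b` (default 0.2) fixes `x0`
  per feature and query through the sphere-of-influence equation: the
  effective number of contributing instances equals
  `m0 + b (N − m0)`, with `m0` the count of nearest-distance instances.
  Class votes sum the normalized transformation probabilities per class.
  The implementation is exact (no sampling), so small-n tests can check
  it against a direct computation from the definition.
- **AdaBoost** — SAMME over depth-1 rpart stumps (50 rounds), which
  handles both the binary task and the binned multiclass routing below.
- **The deep model** — a multilayer perceptron in plain matrix code:
  ReLU hidden layers (defaults 8–32–16–8 for four-ROI inputs; 128–64–8
  when the input is the 252-wide voxel vector), a single output neuron
  (sigmoid + binary cross-entropy for classification, linear + MSE for
  regression), Adam (lr 1e-3, β₁ = 0.9, β₂ = 0.999), minibatches of 32,
  up to 500 epochs with loss-plateau early stopping (tolerance 1e-4,
  patience 20), He-initialized weights from a derived seed. Continuous
  targets are standardized internally and predictions mapped back, so
  the learning rate is scale-free. The fitted state retains all weights;
  `activations()` recomputes every neuron's post-nonlinearity output for
  any instance, which the rule-extraction stage requires. The "252" in
  the voxelwise layout is read as the input width (it equals the voxel
  feature count), with 128–64–8 hidden; a different reading (252 as a
  first hidden layer) can be configured via `params$hidden`.

**Continuous outcome routing.** Learners that need nominal targets
(Naive Bayes, AdaBoost, J48, random forest) see the continuous outcome
through `binContinuousOutcome()`: ten equal-width bins spanning the
training range, labels 0–9, out-of-range test values clamped to edge
bins, and the bin midpoint as the predicted value — so their RMSE is
bounded below by the quantization. Regressors (linear, SVM, K\*, deep)
predict directly.

**SVM exponent search.** `svmExponentSearch()` evaluates exponents
ascending from 1 under the repeated-holdout harness and stops at the
smallest exponent whose successor gains less than 0.5 accuracy
percentage points (the plateau tolerance is a package choice; "plateau"
is otherwise undefined).

## 4. The comparison harness

`makeSplits()` draws R random 90/10 partitions; the test size is pinned
to `floor(0.1 n)` (8 of 82). Stratified splitting (largest-remainder
apportionment with at least one instance per class) is available and
recommended for synthetic runs to stabilize class-wise accuracy cells;
plain splitting reproduces the simpler protocol, with single-class
training sets re-drawn from a dedicated stream (bounded, logged).
`runHarness()` evaluates *all* classifiers on the *same* split sequence,
making every downstream comparison paired. Summaries report, per
classifier, the across-repetition mean of per-repetition accuracy
(overall, among true Improvers, among true non-Improvers, skipping empty
cells) or per-repetition RMSE, with normal-approximation 95% CIs
(`mean ± 1.96 sd/√R`; a percentile bootstrap would also be defensible,
but the normal form matches the symmetric intervals reported in this
literature). `poolShallow()` averages the six shallow methods per
repetition before summarizing, which is why the pooled CI is narrower
than any member's.

**McNemar construction.** Repeated holdout gives each instance many test
appearances. To obtain one paired 2×2 table, each instance is
dichotomized per classifier as correct iff the fraction of its test
appearances predicted correctly exceeds ½ (ties count as incorrect and
are reported). The discordant counts b, c enter the exact two-tailed
binomial test `p = min(1, 2 P(X ≤ min(b,c)))`, `X ~ Bin(b+c, ½)` — exact
because discordant counts are small at n ≈ 82. This per-instance
majority-correctness reading is the only construction of "average
correct vs. incorrect predictions" that yields a valid paired table from
a repeated-holdout ledger; it is asserted prominently in tests. No
multiple-comparison correction is applied across the McNemar family.

## 5. Rule extraction

The explanation pipeline runs on the binary task only (quantile-binning
the continuous outcome for rules would be underpowered at these sample
sizes).

1. **Binarization** (`binarizeActivations()`): hidden unit j is *active*
   for instance i iff its post-ReLU output is strictly positive (the
   natural threshold for rectified-linear units; "active" has no other
   canonical definition). Continuous inputs have no on/off state, so
   each input feature contributes indicator nodes `feature > t`, with t
   drawn from a per-feature information-gain scan over midpoints of
   consecutive sorted values (top 3 per feature by default). This is
   what makes a continuous-feature threshold rule expressible as a node
   selection. Instances are split into X⁺ (Improvers) and X⁻ by label.
2. **Cover** (`solveSetCover()`): select disjoint node sets A⁺, A⁻
   minimizing `|A⁺| + |A⁻| + penalty × slack`, where slack counts
   uncovered instances (an X⁺ row activating no A⁺ node, symmetrically
   for A⁻) and cross-class activations of selected nodes. The penalty
   (default 10) makes separation dominate parsimony; slack keeps the
   program feasible on non-separable data, and instances whose
   activation row appears in both classes — unseparable by construction
   — are reported. The integer program is solved exactly by branch and
   bound: each side reduces to weighted set cover with per-row slack
   (node weight `1 + penalty × violations`), bounded by a
   cheapest-cover-rate relaxation; disjointness conflicts are branched
   node-by-node. Within the time budget optimality is proven (verified
   against exhaustive enumeration, `bruteForceCover()`, on hundreds of
   random tables); past it, the incumbent is returned with a gap flag.
3. **Translation** (`extractRules()`): selected input nodes become
   threshold literals directly (A⁺ → Improver rules, A⁻ → non-Improver
   rules); selected hidden nodes are translated through a single-literal
   surrogate — the input threshold whose indicator best agrees with the
   node's activation pattern, agreement reported. Rules are ranked by
   training-label accuracy, rules whose marginal fidelity contribution
   is negative are dropped (making the fidelity curve monotone), and the
   reported set is the shortest ranked prefix retaining ≥ 95% of full
   fidelity — only the most predictive rules are output, so the rule set
   may underperform the full network by design. The fallback class for
   uncovered instances is chosen to maximize fidelity, which is why a
   single-rule set reads as the two-sided
   `feature > t → Improver, ≤ t → non-Improver`.
4. **Context** (`ruleContextReport()`): each single-feature threshold is
   situated against the healthy-control and patient means (with 95%
   CIs) of that feature — a plausible biomarker threshold should be
   intermediate to the two group means.

## 6. The synthetic test bed

`generateCohort()` draws cohorts with the structure the analysis
assumes; its defaults *are* the study conditions and are not tuned per
test:

- 82 patients / 138 controls by default; Improver rate 0.573; group
  means of the planted adjusted feature 0.15 (controls) and −0.13
  (patients); class-conditional Gaussian sds 0.989 / 1.109, backed out
  of published 95% CIs at the published group sizes under a normality
  assumption (only means and CIs are in print — the CI-derived sd is an
  assumption, noted, not resolvable from published data).
- The planted rule is `L_DLPFC > 0.017 → Improver`. Because the
  improver rate is a free parameter, a single Gaussian cannot
  simultaneously match the group mean and put exactly that probability
  mass above the threshold; the generator draws the class first
  (Bernoulli 0.573) and the feature from side-truncated Gaussians whose
  common location is root-found so the mixture mean equals the group
  mean. A sampling gap of ±0.05 beta units around the threshold keeps
  planted labels unambiguous, mirroring the margin used for BPRS
  construction below.
- Label noise flips a configurable fraction of labels after the rule is
  applied; ground truth (pre-noise class, flip indicator, planted rule)
  is exported for recovery tests.
- Baseline raw BPRS is a rounded Gaussian at 42.7 (sd 9.7) clamped to
  [29, 120]; follow-up is built from the assigned label with a margin
  around the 20% boundary (Improvers: rescaled decrease in (25%, 80%],
  floor-rounded; non-Improvers: [0%, 20%), ceiling-rounded), so
  re-deriving labels from the written BPRS pairs reproduces the
  generator's labels with zero mismatches — an invariant test.
- A protocol shift (default +0.5 beta units for AX-1) is added to raw
  features and must vanish under adjustment.
- Voxelwise mode appends 252 voxel features, 63 per ROI (the 4-way
  equal split is a design decision; published material fixes only the
  total). A voxel is its ROI beta plus equicorrelated noise; with zero
  noise sd every voxel equals its beta exactly.

What passing tests show — and what they do not: the synthetic bed has a
genuinely planted, nearly axis-aligned rule, Gaussian features, and
additive protocol effects. Recovery there demonstrates the machinery is
correct and calibrated, not that real frontoparietal data contain a
comparably clean threshold; non-Gaussian tails, feature correlations
beyond the voxel blocks, diagnosis-subtype mechanisms and scanner
effects other than an additive shift are deliberately not modeled.

One subtlety the tests exercise: the generator plants the rule on its
own adjusted scale, but the pipeline re-standardizes features on the
realized sample, an affine map that shifts recovered thresholds by the
pooled sample mean (~0.05 here). Recovered thresholds are therefore
compared to the planted 0.017 with a tolerance of half a feature sd, and
rule *form* and *feature identity* are the primary recovery criteria.

## 7. Problem sizes and numerical choices

Test and acceptance runs scale the protocol down to keep the full suite
fast while leaving every mechanism exercised: synthetic cohorts of
n = 200 patients, 100 holdout repetitions (not 1000), 20 seeded cohorts
for rule recovery with deep training capped at 200 epochs, and holdout
accuracy measured on 3 of them; the solver-oracle equivalence uses 200
random tables of ≤ 12 neurons. At these sizes the deep learner's mean
holdout accuracy on 10%-label-noise cohorts sits around 0.84, inside the
[0.80, 0.95] band implied by the noise ceiling (1 − noise = 0.9 in
expectation; the band is asserted on the mean across cohorts, since
single-cohort accuracy fluctuates by a few points). Other pinned
numerics: seed propagation by stage-name hashing (adding a stage never
perturbs another stage's stream); cover tie-breaks lexicographic by node
order in the oracle; zero-residual-variance features adjust to all-zeros
with a warning; degenerate single-bin outcomes warn; empty A⁺/A⁻ yield
an empty rule set with coverage 0.

## 8. Known limitations

- Shallow learner hyperparameters are the canonical defaults of their
  R implementations, not bit-for-bit reproductions of any other tool's
  defaults; contracts (not implementations) are what the tests pin.
- The exact ILP formulation of the cover step is a faithful
  reconstruction from its stated constraints (disjointness, cover X⁺ not
  X⁻), with the slack formulation added because real activation tables
  are rarely perfectly separable; objective weights are package choices.
- Whether input-layer indicator nodes participate in the cover alongside
  hidden units is configurable (`includeInput`); both are included by
  default, which is what lets the reported rule be a direct input
  threshold.
- The pooled shallow baseline excludes the regression baseline by
  default; membership is configurable (`poolShallow(methods = ...)`).
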