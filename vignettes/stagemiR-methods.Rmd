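---
title: "stagemiR: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stagemiR: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements: the
models and their assumptions, the parameters that matter and their defaults,
the numerical choices, and what the synthetic-data tests do and do not show
about real cohorts.

## The analysis

The package studies stage-specific miRNA biomarkers in a breast-cancer-like
cohort: per-sample miRNA quantifications in reads per million (rpm), each
sample labeled with a coarse tumor stage (1–4), `normal` for unaffected
tissue, or `X` for unassessable stage, and flagged as tissue- or
blood-derived. Stage X samples and blood-derived samples are excluded before
analysis: blood shows essentially the same miRNA composition in cancer and
normal samples, so it cannot separate stages. Under the cohort composition
the package's generator defaults to (113 normal, 111/350/131/11 tumor
stages 1–4, 5 Stage X, 486 blood; 1207 samples in all), the exclusions
retain exactly 716 tissue samples — an identity the test suite checks.

Every downstream question is binary and per-stage: stage-*k* tumor tissue
versus normal tissue. Four feature-selection routes feed one evaluation
harness.

## Fold-change screening

For each miRNA, FC = mean(tumor rpm) / mean(normal rpm), reported also as
log2 FC (two-fold ≡ 1, four-fold ≡ 2). Edge conventions: a positive tumor
mean over a zero normal mean is `Inf` and ranks above every finite
up-regulation (mirroring the convention that a zero tumor mean yields FC 0,
extreme down-regulation); 0/0 is `NaN` and excluded from calls. No
pseudocount is added — published per-stage tables report FC exactly 0, so a
pseudocount would change the statistic being reproduced.

P-values come from the two-sided rank-sum test by default (exact for small
untied groups), chosen for robustness to the heavy right skew of rpm; a
t-test on log2(rpm + 1) is selectable (`de_test(method = "t_log2")`).
Multiple testing is handled by Benjamini–Hochberg step-up adjustment
(`stats::p.adjust`, cross-checked in the tests against a brute-force
step-up oracle). Up/down lists require adjusted p < 0.05 (configurable) and
take the 10 most extreme fold changes per direction, ties broken
lexicographically by miRNA id so output is deterministic.

## Chi-square relevance

Each feature is discretized into equal-frequency (quantile) bins — default
4; quantile bins are robust to rpm skew and the count is configurable — and
cross-tabulated against the class label. The score is Pearson's
χ² = Σ (O−E)²/E without continuity correction; zero-margin rows/columns are
dropped with a warning, and constant features are flagged uninformative and
score 0. Tied values always share a bin, so heavily zero-inflated miRNAs
collapse gracefully.

## Neighborhood component analysis

NCA learns one weight $w_r$ per miRNA in the distance
$d_w(x_i, x_j) = \sum_r w_r^2 |x_{ir} - x_{jr}|$. A kernel
$k(z) = e^{-z/\sigma}$ maps distances to similarities, and sample $j$ is
chosen as the reference for sample $i$ with probability
$p_{ij} = k(d_w(x_i,x_j)) / \sum_{j' \ne i} k(d_w(x_i,x_{j'}))$, $p_{ii}=0$.
The soft leave-one-out probability of correct classification is
$p_i = \sum_{j \ne i} p_{ij}\,1[y_i = y_j]$, and the objective
$$F(w) = \frac{1}{n}\sum_i p_i \;-\; \lambda \sum_r w_r^2$$
is maximized; the solver equivalently minimizes the loss $1 - F(w)$.

Design notes:

- **Normalization is over kernel similarities, not raw distances.** The
  reference probability must increase as a neighbor gets closer; the package
  therefore normalizes $e^{-d_w/\sigma}$ (the kernel's stated purpose),
  which also makes $p_{ij}$ a proper softmax with rows summing to 1.
- **Gradient.** The analytic gradient of the loss is
  $\frac{\partial L}{\partial w_r} = \frac{2 w_r}{n\sigma} \sum_i \Big[
  \big(\textstyle\sum_j p_{ij} \ell_{ij}\big) \sum_k p_{ik} a_{ik,r}
  - \sum_j p_{ij} \ell_{ij} a_{ij,r} \Big] + 2\lambda w_r$,
  with $\ell_{ij} = 1[y_i \ne y_j]$ and $a_{ij,r} = |x_{ir} - x_{jr}|$. The
  test suite validates it against central finite differences on 20+ random
  instances to relative error ≤ 1e−5, and the acceptance script recomputes
  that check at every run.
- **Solver.** Deterministic gradient descent from all-ones weights with an
  Armijo backtracking line search (sufficient-decrease constant 1e−4, step
  doubled after each accepted iterate). The objective trace is therefore
  non-increasing by construction — a tested invariant. Convergence when the
  loss decrease falls below `tol` (default 1e−6) or after `max_iter`
  (default 100; the pipeline uses 60) iterations. Under heavy regularization
  the approach to zero is geometric, so tests of that regime allow up to 200
  iterations. When $n^2 p$ is small enough to afford the memory
  (≤ 4×10⁷ entries), pairwise absolute differences are precomputed once and
  each iteration reduces to two matrix products; otherwise a per-feature
  loop computes the same quantities exactly.
- **Numerical stability.** Row-wise distance shifts are subtracted before
  exponentiation (they cancel in the softmax), so distant clusters cannot
  underflow an entire row.
- **Transform.** Features are z-scored before fitting (default) so
  $\sigma = 1$ is meaningful across rpm scales spanning orders of
  magnitude; `identity` and `log2(rpm+1)` + z-score are exposed because it
  is genuinely unknown which representation a given study used. Constant
  features get scale 1 to avoid division by zero.
- **Defaults.** $\sigma = 1$ (the conventional kernel width after
  standardization), $\lambda = 1/n$ (scales the penalty with the averaging
  in the data term; no published value exists to adopt).
- Features are ranked by $w_r^2$ — the objective is invariant to the sign
  of any weight (tested), so magnitude is the only meaningful ordering.
  All-zero weights fall back to lexicographic order flagged degenerate.

## MRMR with the mutual-information quotient

Relevance of a set $S$ is $V_S = \frac{1}{|S|}\sum_{x \in S} I(x, y)$ and
redundancy $W_S = \frac{1}{|S|^2}\sum_{x,z \in S} I(x, z)$, with plug-in MI
estimates (bits by default) on the same equal-frequency bins as the
chi-square screen, for consistency. Greedy forward addition selects the
candidate maximizing $\mathrm{MIQ} = V/W$ of the augmented set;
the incremental implementation is tested for exact agreement with an
exhaustive oracle that re-evaluates the definitions at every step.

Choices where the procedure is underdetermined:

- **Self-pairs are included in $W$** (the double sum read literally), so
  $W \ge H(x)/|S|^2 > 0$ for non-constant features and the quotient is
  always defined. `include_self = FALSE` is available.
- **First pick**: with $S$ empty the quotient is taken over the candidate
  alone, $I(x, y)/H(x)$ — the natural $|S|=1$ limit. Note this normalizes
  relevance by entropy, so the first feature maximizes the *quotient*, not
  raw relevance, when candidate entropies differ.
- **Constant features** are excluded up front (MI with them is
  identically 0 and their entropy is 0); a message reports the count.
- Ties break lexicographically; column permutations of the input do not
  change the selection (tested).

## Evaluation

Stratified 5-fold cross-validation: within each class, shuffled indices are
dealt round-robin to folds, keeping per-fold class fractions within one
sample of the global fraction; each sample is tested exactly once, and the
per-fold accuracies (TP+TN)/total are averaged. The classifier is a linear
maximum-margin SVM with unit cost — no kernel tricks, no tuning — with
features standardized on the training fold only. Any
`list(train=, predict=)` pair can be substituted.

Feature selection for NCA/MRMR/chi-square is **re-run inside each training
fold by default** (`selection = "per_fold"`), so the reported accuracy is
free of selection leakage; `selection = "once"` reproduces the
select-then-validate alternative, since published analyses rarely state
which was used. Fold-change panels are selected once from the full DE table,
matching how published up/down tables are constructed.

Small strata: a class smaller than the fold count is an error; a class that
cannot put ≥ 2 samples in every fold reduces the fold count with a warning.
An 11-sample stage-4 stratum thus still runs 5 folds (2–3 positives per
fold).

**Calibration caveat.** On effect-free data a unit-cost linear SVM with
more features than samples does not default to majority voting — it overfits
separable noise and scores near 0.5 regardless of class balance. The
package's null-calibration checks therefore use a balanced tumor/normal
design (mirroring the near-balanced 113 vs 111 stage-1 contrast), where the
chance rate and the majority rate coincide; with strongly unbalanced null
classes, accuracy below the majority rate is expected classifier behavior,
not selection leakage.

## Consensus biomarkers

Per stage, the intersection of the NCA and MRMR top-50 rankings, ordered by
NCA rank (order matters only for reporting). The intersection can
legitimately be empty; evaluation then returns an explicit empty report
rather than an error. Consensus at depth $k_1$ is a subset of consensus at
$k_2 \ge k_1$ (tested).

## The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions under
which every selection method is validated.

- **Model.** Each miRNA draws a baseline mean from a log-normal —
  `baseline_log_mean = 2`, `baseline_log_sd = 2` (natural-log scale),
  giving median rpm ≈ 7.4 with a heavy right tail from ~0.01 to hundreds of
  rpm, the qualitative shape of rpm data. Each sample observes
  baseline × log-normal noise (`noise_log_sd = 0.6`). A planted effect
  multiplies the mean of one miRNA in tumor-tissue samples of one stage by
  its fold change; because the noise is multiplicative and cancels in group
  means, the empirical tumor/normal mean ratio converges to the configured
  fold change (tested at two sample sizes).
- **Defaults are the study conditions**: the 1207-sample composition above,
  1881 miRNAs, and 10 up (FC 4) + 10 down (FC 0.25) planted markers per
  stage on disjoint miRNAs, mirroring the 10 + 10 shape of per-stage DE
  report tables. Blood and Stage X samples are generated signal-free,
  directly encoding why they are excluded.
- **What it does not emulate:** integer count noise (values are continuous
  rpm; rounded read counts are provided only for IO-layer tests),
  miRNA–miRNA correlation (features are independent given their means),
  library-size artifacts, batch effects, and stage-to-stage effect overlap
  (real dysregulation is shared across stages; planted markers are
  stage-exclusive). Passing tests therefore demonstrate correctness of the
  *methods* under a favorable, known-truth regime — not expected accuracy
  on real cohorts, where published per-stage accuracies vary widely.

## Problem sizes used in tests and the acceptance script

Recovery checks use 200 features with 80 + 80 or 100 + 100 samples; null
calibration uses 20 effect-free cohorts of 25 + 25 samples × 100 features;
the end-to-end pipeline profile is 200 miRNAs with 60 normal and
40/60/40/12 tumor samples (plus 2 Stage X and 20 blood to exercise the
exclusions). These desk-scale sizes keep the full suite fast while leaving
every stratum large enough for stratified 5-fold CV.

## Known limitations

- NCA cost is O(n²p) per iteration; cohorts of thousands of samples with
  the full 1881-feature vector require patience or pre-screening.
- Plug-in MI and χ² on 4 quantile bins are biased upward for tiny samples;
  bin count is configurable but not adaptive.
- Only coarse stages are modeled; sub-stage labels (IIA/IIB) are rejected
  rather than mapped.
- Accuracy is the only evaluation metric, matching the procedure being
  reproduced; no ROC/PR analysis, and no classifier tuning by design.
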