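---
title: "Error consistency: model, procedures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error consistency: model, procedures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecvalid)
```

## The problem

Repeated randomized hold-out validation (K-fold cross-validation repeated
`m` times) yields a population of trained models and a distribution of
accuracies. The usual summary — mean accuracy and its SD — treats the models
as interchangeable. They often are not: two models with identical accuracy
can err on largely different samples, and whichever one is deployed will
carry its own idiosyncratic failure profile into the real world. Error
consistency makes that disagreement measurable.

## The statistic and its degeneracies

For error sets $E_i, E_j$ (the held-out samples models $i$ and $j$
misclassified, tracked by sample id), the pairwise error consistency is the
Jaccard index

$$\mathrm{EC}_{ij} = \frac{|E_i \cap E_j|}{|E_i \cup E_j|} \in [0, 1].$$

Only the $n(n-1)/2$ upper-triangular pairs carry information; `ecvalid`
enumerates them in lexicographic $(i, j)$ order so that serialized pair
tables are reproducible byte for byte. The summary is the mean (AEC) and the
sample standard deviation (denominator $n-1$; the choice of denominator is a
convention we fix and document — at the pair counts involved it is
numerically immaterial, but it must be pinned for reproducibility).

Two degenerate cases are handled as first-class values, not errors:

* **Both sets empty.** Two perfect models have no errors upon which to be
  consistent; $0/0$ is undefined and is represented as `NA`, propagated
  through `pairwise_ec()` and only separated out (with a warning and an
  explicit count) in `summarize_ec()`. A report renders this as an `NA` cell
  with a footnote rather than a fabricated number.
* **One set empty.** The intersection is empty but the union is not, so the
  value is a genuine 0.

## The two validation procedures

Both procedures repeat K-fold cross-validation `m` times with independently
reshuffled folds (defaults `K = 5`, `m = 500`; `m` high for statistical
reliability of the summary, reducible for exploration).

**Internal** (`run_internal`): the K fold error sets of one repetition are
disjoint (folds partition the ids) and their union is the repetition's
*master error set* over all N samples. This gives `n = m` error sets, makes
full use of the data, and yields the exact identity
$\mathrm{OA}_r = 1 - |E_r|/N$, which the test suite asserts bitwise.

**External** (`run_external`): every fold-trained model additionally
predicts one fixed, id-disjoint validation set, giving `n = m K` error sets
on a common support. Because the literature is ambiguous about which
accuracy is "the" OA in this design, both families are reported under
distinct names — per-repetition fold-test OA and per-model validation-set
accuracy — and neither is privileged.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `K` | 5 | folds per repetition; folds differ by ≤ 1 in size (per class when stratified) |
| `m` | 500 | repetitions; AEC precision grows with the number of set pairs, ~`m²/2` |
| `stratified` | `TRUE` | per-class fold balance; prevents empty-class folds on small medical datasets. The protocol this package follows does not specify stratification; we default to it and expose the flag rather than guess silently |
| `master_seed` | 1 | root of a counter-based seed sequence (`derive_seeds`); repetition `r` always consumes seed `r` of the sequence, so any single repetition is re-runnable in isolation |
| `pairwise_cap` | 2000 | beyond this many sets the pair table is streamed into running moments instead of materialized (`n(n−1)/2` growth) |

Classifiers arrive *configured*: hyperparameter tuning happens once, before
validation, never inside the repetition loop, so all `m` repetitions probe
one fixed learning procedure.

## Mock classifiers as exact oracles

Because error sets are defined over sample identity, ids travel with feature
rows through the engine. That lets two mocks make consistency outcomes
exactly predictable:

* `planted_error_classifier(S, truth)` errs exactly on `S ∩ H` for any
  held-out `H`. Under the internal approach the master set is exactly `S`
  every repetition (folds partition ids), forcing AEC = 1, SD = 0 and
  OA = $1 - |S|/N$ — an identity the acceptance tests check literally.
  With `S = ∅` it realizes the perfect-classifier degeneracy.
* `random_error_classifier(rate, truth)` draws a fresh error set of size
  $k = \mathrm{round}(rate \cdot N)$ at every fit. Two independent draws
  have $\mathbb{E}|E_i \cap E_j| = k^2/N$ and
  $\mathbb{E}|E_i \cup E_j| = 2k - k^2/N$, so the ratio-of-expectations
  approximation to the expected pairwise consistency is $k/(2N-k)$ — the
  *independence baseline* that a consistency estimate must recover. For
  rate 0.2 on $N = 100$ this is $20/180 \approx 0.111$. The test tolerance
  (0.005) is three Monte-Carlo standard errors of an `m = 200` run's AEC,
  measured beforehand with a standalone simulation of the same
  draw-per-fold mechanism (40 replicates: SE 0.0017; the bias of the
  ratio-of-expectations approximation, +0.0004, is well inside it).

The reference learner presets (`svm-rbf`, `rf-100`, `logreg`, `boost-dt`)
run through exactly the same engine path as the mocks; no code is
special-cased on the classifier kind. The boosted-tree preset uses gradient
boosting (xgboost), the boosted-decision-tree implementation available here.

## Synthetic data: what it emulates and what it does not

`generate_boundary_dataset` draws two isotropic unit-variance Gaussian
classes with centroids `class_separation` apart along the first feature
axis. This geometry was chosen because it has an analytic anchor: the
Bayes-optimal rule thresholds the first feature, and for balanced classes
its accuracy is $\Phi(\mathrm{sep}/2)$ (`boundary_bayes_accuracy`; the
general-prior form shifts the threshold to the likelihood-ratio point). The
tests verify the generator against this closed form at $n = 5000$ within
two Monte-Carlo standard errors. Errors of a well-trained classifier
concentrate on the ambiguous mid-plane samples — the high-consistency
regime. `generate_label_noise_dataset` instead flips exactly
`round(rate·n)` labels of a separable problem and records the flipped ids
as metadata (never visible to classifiers) — errors then attach to the
flipped samples, and the training noise pushes consistency down.

What passing tests on these fixtures shows: the statistic, the engine
mechanics, the degeneracies and the qualitative learner contrast behave as
designed. What they do not show: behavior under the marginal distributions,
feature correlations, categorical encodings and class imbalances of real
clinical datasets — synthetic Gaussians are deliberately idealized, and no
claim about any particular real dataset follows from them.

## Sample-size analysis

`downsample_experiment` takes stratified subsamples without replacement at
a proportion grid (default {0.2, …, 1.0}, 10 draws per proportion, reduced
`m = 50` per point — per-point repetition counts for this preliminary
analysis are not standardized anywhere, so desk-scale defaults are chosen
and recorded in the output). Each point is one full internal-approach run
under its own derived seed; at proportion 1.0 the subsample is the full
dataset, so the point reproduces `run_internal` exactly under that seed —
the anchor the acceptance suite checks. Subsamples too small to support
`2K` stratified folds are skipped with a warning rather than crashing the
grid.

`fit_trend` uses Cleveland's locally weighted regression (`stats::lowess`)
with span 0.75 by default; local *linear* fitting reproduces exactly linear
point sets to machine precision (a property the tests exploit) and points
with undefined AEC are excluded from the consistency fit and re-entered as
gaps, not zeros. `rolling_correlation` sorts the (percentage, metric) pairs,
slides a window of consecutive pairs, and computes the Pearson correlation
per window (Spearman is exposed as an option — for monotone but nonlinear
trends the rank correlation is the one that saturates at 1); a percentile
bootstrap within each window (default 500 draws) gives the interval.
Constant windows have undefined correlation and yield `NA` without error.
Default window sizes of roughly 5–20% of the pair count are sensible
starting points; the choice is the user's.

## Numerical and design notes

* Pairwise values are computed via a logical incidence matrix and one
  `tcrossprod`, giving exact integer intersection/union counts — no
  floating-point set arithmetic. `0/0` becomes the `NA` sentinel.
* All randomness flows from one `master_seed` through `derive_seeds`
  (counter-based): identical seeds give byte-identical machine outputs,
  including across separate CLI invocations, which the suite checks by
  hashing files. Machine outputs contain no timestamps for this reason.
* Fold balance: fold labels are assigned as a shuffled
  `rep(sample(K), length.out = n)` within each class, so per-class fold
  sizes differ by at most one and which folds take the remainder is
  randomized.
* Reports round to presentation precision (integer percentages, one-decimal
  SDs, the `"82 (0.5)/89 (2.7)"` cell style) while every emitted CSV keeps
  full precision; the suite recomputes each report number from the CSVs.
* Error classes: invalid inputs raise `ecvalid_invalid_input`, classifier
  contract violations raise `ecvalid_contract_error` (with repetition/fold
  context); the CLI maps them to exit codes 2 and 3.

## Problem sizes used in the checks

The test and acceptance fixtures use deliberately modest sizes chosen as
the smallest that make each property unambiguous: planted-error exactness
at $N = 100$, $m = 20$; the independence baseline at $N = 100$, $m = 200$;
the learner contrast at $n = 800$, $f = 4$, separation 2, $m = 25$ (large
enough that a linear learner and a 100-tree forest reach statistically
matched accuracy, which is the premise of comparing their consistencies);
the down-sampling curve at $n = 300$, $f = 8$ (enough features that the
classifier genuinely improves with more data, so there is a learning curve
to detect). Scaling `m` up changes precision, not behavior.

## Known limitations

* Multi-class problems are supported throughout, but the mocks' "wrong
  label" is a fixed cyclic shift — adequate for forcing errors, not a model
  of realistic confusion structure.
* Undefined AEC is reported, not raised; downstream code must handle `NA`.
* The external approach assumes the validation set fits in memory alongside
  the training set; there is no out-of-core path.
* No nested cross-validation for tuning, no regression tasks, no
  probabilistic/weighted error sets: error identity is binary by design.
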