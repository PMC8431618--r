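---
title: "Multi-criteria benchmarking of binary diagnostic classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-criteria benchmarking of binary diagnostic classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdmbench)
```

## The problem

When several classifiers are evaluated on the same diagnostic task, no
single one usually dominates: the most accurate model is rarely the most
specific, and almost never the smallest. Picking "the best" model is
therefore a multi-criteria decision problem, not a single-metric argmax.
This package implements one complete, reproducible pipeline for it:

1. **Metrics** — ten criteria per cross-validation fold from hard-label
   predictions, fold-aggregated to mean ± sd.
2. **Decision matrix** — alternatives × criteria, with each criterion
   tagged *beneficial* (larger is better) or *non-beneficial*.
3. **Normalization** — direction-aware ratio scaling onto (0, 1].
4. **Weighting** — objective entropy weights, or an externally supplied
   vector.
5. **Ranking** — PROMETHEE II outranking flows, cross-checked by VIKOR
   compromise ranking.

The package ships a fully transcribed case study: 19 ImageNet-pretrained
CNN architectures fine-tuned for binary melanoma diagnosis on balanced
dermoscopic-image folds (98–100 test images per class per fold), with all
published intermediate tables as fixtures.

## The criteria

From the confusion counts tp, tn, fp, fn of one fold:

* accuracy $(tp+tn)/n$ and its complement, classification error;
* sensitivity $tp/(tp+fn)$ and the false-negative rate $1 - \mathrm{sen}$;
* specificity $tn/(tn+fp)$ and the false-positive rate $1 - \mathrm{spe}$;
* precision $tp/(tp+fp)$;
* F1 $= 2\,\mathrm{pre}\cdot\mathrm{sen}/(\mathrm{pre}+\mathrm{sen})$;
* Matthews correlation coefficient
  $(tp\,tn - fp\,fn)/\sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)} \in [-1, 1]$;
* model complexity: parameter count in millions.

Degenerate denominators use the common conventions: precision 0 when
nothing is predicted positive, F1 = 0 when precision + sensitivity = 0,
MCC = 0 when any marginal is zero. These are documented and tested — the
source material is silent on them.

Two naming quirks are worth stating. First, some sources swap the names
"miss rate" and "fall-out"; the package follows the *formulas* (FPR =
fp/(fp+tn), FNR = fn/(fn+tp)) and ignores the labels. Second, the positive
class is always a caller-supplied label — it is never inferred from sort
order, because nothing about the string "melanoma" makes it alphabetically
special.

Fold aggregation uses the arithmetic mean and the **sample** (n − 1)
standard deviation. That choice is pinned by the case study itself: the
ResNet101 fold accuracies (81.82, 94.44, 96.97, 98.99, 99.49) give sd 7.28
with the n − 1 denominator and 6.51 with the population denominator, and
only the former matches the published summary. A single fold yields an
`NA` sd rather than a misleading zero. Note that the mean of per-fold F1
is *not* the F1 of mean precision and mean sensitivity; fold summaries
must be produced by averaging per-fold values, which is what
`aggregate_folds()` does.

Internally all rates are fractions; the percent scale (including MCC — a
convention worth flagging, since an MCC "of 88.96" is 0.8896) appears only
in reports and fixtures. Normalization is ratio-based per column, so the
scale choice cannot affect any downstream number.

## Normalization and weighting

With column extremes taken over the supplied alternatives only, beneficial
columns are divided by their maximum ($\bar x_{ij} = x_{ij}/\max_i
x_{ij}$) and non-beneficial columns inverted through their minimum
($\bar x_{ij} = \min_i x_{ij}/x_{ij}$). Every column then attains 1 at
its optimum and all entries lie in (0, 1]; every criterion is
max-oriented from here on, which is why strict positivity of the raw
matrix is enforced with an error naming the offending cell.
Normalization is computed at full floating precision; 4-dp rounding is a
report-time choice. For the threshold preference used below only
within-column orderings matter, and those are identical at both
precisions for the case-study data.

Entropy weights measure how much a criterion discriminates: columns are
turned into distributions $p_{ij} = x_{ij}/\sum_i x_{ij}$, the entropy
$e_j = -\frac{1}{\ln m}\sum_i p_{ij}\ln p_{ij}$ is 1 exactly for a
uniform column, and the weight is the normalized contrast $w_j = (1 -
e_j)/\sum_k (1 - e_k)$. Consequences worth knowing: weights are
non-negative and sum to 1; a constant column gets weight 0; weights are
invariant to positive rescaling of any column; and a matrix whose columns
are *all* uniform has no discriminating criterion — that is an error, not
a uniform fallback. The $1/\ln m$ constant sums over alternatives within
a column; that is the only reading under which $e_j \le 1$.

**The case-study weight vector is not an entropy output.** The published
analysis prints ten weights (0.9648, 0.8044, …, −0.0315) whose signs fall
exactly on the four non-beneficial criteria and whose magnitudes exceed 1
— both impossible for entropy weights, which are non-negative and sum
to 1. Whatever post-processing produced them is not recoverable from the
source, so the package treats the printed vector as authoritative
*user-supplied* input (`load_weights()`, stored verbatim with signs) and
uses its magnitudes in the ranking methods. `entropy_weights()` remains
the first-class route for new data; the reproduction profile simply does
not pretend the printed vector came from it.

## PROMETHEE II

For each ordered pair (a, b) and criterion j, the deviation is
$d_j(a,b) = \bar x_{aj} - \bar x_{bj}$ and the *usual* (threshold)
preference is $P_j = 1$ if $d_j > 0$, else 0. The source's stated
function ("0 if d ≤ 0 and 1 if d ≥ 0") assigns both values at d = 0;
P(0) = 0 is the standard resolution and the only one with
$\pi(a,a) = 0$. Ties do occur in the case study (two models share a
5.3 M parameter count; two share a specificity), so the tie rule is
load-bearing, not cosmetic.

The global preference index is $\pi(a,b) = \sum_j w_j P_j(a,b)$, and the
flows are

$$\phi^+(a) = \tfrac{1}{m-1}\sum_b \pi(a,b),\qquad
  \phi^-(a) = \tfrac{1}{m-1}\sum_b \pi(b,a),\qquad
  \phi = \phi^+ - \phi^-.$$

Both the averaged form above and the *summed* form (no $1/(m-1)$) are
first-class: they are identical up to the positive factor $m-1$, so
rankings never differ, but the published case-study flows (e.g. 150.84
for the winner with 19 alternatives and weight magnitudes of total ≈ 9.4)
are only reachable on the summed scale, so the reproduction profile pins
`convention = "summed"`. Net flows always sum to zero (an antisymmetry of
π), which the tests assert on every run, and a strictly dominant
alternative attains the maximal possible $\phi$.

With the printed *signed* weights the published flows are not recovered;
with magnitudes they are, to the precision the 4-dp normalized fixture
allows (|Δ| ≤ 1e−3, ranking exact). Signed use stays available behind
`weight_signs = "signed"` for sensitivity analysis.

## VIKOR

VIKOR aggregates per-criterion regrets against the ideal: with best and
worst values $x_j^*, x_j^-$ per criterion (direction-aware on raw
matrices; max/min after normalization), each alternative gets the group
utility $S_i = \sum_j w_j (x_j^* - x_{ij})/(x_j^* - x_j^-)$ and the
individual regret $R_i = \max_j$ of the same terms, combined as

$$Q_i = v\,\frac{S_i - S^*}{S^- - S^*} + (1-v)\,\frac{R_i - R^*}{R^- - R^*},$$

ranked ascending. The mixing weight defaults to $v = 0.5$ (the consensus
convention; the source never states its value — exposed as config). The
default input is the normalized matrix with weight magnitudes, matching
the "same weights, same matrix" setup of the PROMETHEE run; a raw-matrix
mode implements the pre-normalization best/worst rules as well. Edge
cases: a zero-range criterion is an error naming the criterion; if
exactly one of the S- or R-ranges is degenerate that Q term is defined
as 0; if both are, the input cannot discriminate and that is an error.

Q = 0 is *not* guaranteed for some alternative in general: it requires
one alternative to attain both the minimum S and the minimum R (and
symmetrically for Q = 1). In the case study that is exactly what happens
— ResNet101 takes both minima and SqueezeNet both maxima — so the
endpoints Q = 0 and Q = 1 are structural and hold for every v, which is
what the tests assert.

**What is deliberately not asserted.** The published intermediate Q
values (for example 0.07998 for the runner-up) could not be reproduced
under any single documented convention we examined (raw vs normalized
matrix, signed vs magnitude weights, a range of v). The reproduction
therefore reports computed and published Q side by side and restricts
assertions to the endpoints, the rank extremes, and structural
properties (Q ∈ [0, 1], weight-rescaling invariance, S-monotonicity).
Under the pinned conventions the VIKOR ranking also swaps two mid-field
models relative to the published VIKOR column; the published
PROMETHEE-vs-VIKOR comparison itself (14 of 19 identical positions) is
preserved as a fixture and reproduced by `compare_rankings()` on the
published rank columns.

## A documented inconsistency in the transcribed tables

The published per-fold accuracy table and the summary table disagree for
two models, and the fixtures keep both as printed. DenseNet201's folds
(86.36, 91.94, 96.46, 97.98, 97.47) average 94.04 with sd 4.91, against
a printed 93.94 ± 4.97; reading fold 2 as 91.44 reproduces *both*
printed values exactly, so the fold table demonstrably carries a typo.
NasnetMobile's folds average 86.564 → 86.56 against a printed 86.57
(its sd matches; a last-digit rounding artifact, consistent with the
summary having been computed from unrounded fold values). The
fixture-consistency test pins this true state; the strict all-19
assertion in the acceptance suite fails on exactly those two rows, by
design. No ranking quantity is affected: the decision matrix is built
from the summary-table means, which are consistent with the normalized
matrix and everything downstream.

## The synthetic generator

`simulate_predictions()` emulates what the case study measures: per test
fold, each positive case is predicted positive independently with
probability equal to the model's sensitivity, each negative predicted
negative with probability equal to its specificity. Stratified fold
sizes differ by at most one per class, larger folds first; for 491/500
cases in five folds this gives test folds of 99, 98, 98, 98, 98
positives — so four of five training cycles hold the canonical 393
positives and one holds 392, a ±1 the source arithmetic glosses over and
the generator documents rather than hides. Seeding is explicit and the
caller's RNG state is restored, so identical seeds give bit-identical
tables and no hidden global randomness leaks.

What the generator does *not* emulate: correlation across models (real
benchmarks evaluate all models on the same test images, so their errors
correlate), within-fold difficulty structure, and any image-level
signal. Passing tests on synthetic data therefore validate the decision
pipeline — metrics, normalization, weighting, both rankings, planted
dominance recovered in 50/50 seeded runs — not the behaviour of any real
classifier family. `planted_dominance_matrix()` plants a strictly
dominant alternative direction-aware, which both methods must rank first;
that is an identity check on the ranking stack, not an empirical claim.

## Problem sizes and determinism

The test suite runs on small matrices (m ≤ 10, k ≤ 6), 200-case
prediction vectors for the metric oracle, 1000 cases per class for
sensitivity-recovery checks (200 per class per fold), and 50 seeded
dominance runs; the whole suite completes in a few seconds. Oracles are
independent re-derivations (per-case counting loops, brute-force
pairwise triple loops, closed-form entropy for a 3 × 2 matrix, a
hand-derived 3-alternative VIKOR example). Every stochastic test fixes
its seed. Rank ties anywhere break deterministically by alternative id
and are documented in the outputs.
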