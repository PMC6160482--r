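---
title: "Emotional modulation signatures: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emotional modulation signatures: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emfdd)
```

## The modelling idea

Acoustic features of a child's utterances are strongly driven by the
emotional valence of what is being said, and only weakly — if at all — by
a developmental diagnosis. `emfdd` therefore never classifies utterances.
It estimates, for each subject, a personal *emotional modulation
function*: the coefficient vector of a multilinear regression mapping the
subject's per-valence feature-moment profile onto the valence scale
(−1, 0, +1). Diagnosis classification then operates on these per-subject
coefficient vectors. The working assumptions are:

* valence can be treated as a numeric, equally spaced scale, so Pearson
  correlation and linear regression against {−1, 0, +1} are meaningful;
* a subject's feature values respond approximately linearly to valence,
  so the modulation is captured by slopes (and the shape of the
  within-class distributions by skewness and kurtosis);
* the *distribution* of modulation coefficients differs between
  diagnostic groups, even where per-utterance feature distributions do
  not.

## Stages and their parameters

**Per-subject feature selection** (`select_features()`). A feature enters
the shared set when its absolute Pearson correlation with the subject's
valence sequence strictly exceeds `threshold` (default 0.7,
dimensionless); per-subject sets are unioned so every subject contributes
the features that are emotionally informative *for them*. Zero-variance
columns count as correlation 0 rather than erroring, so constant nuisance
columns are harmless. By default the union runs over all subjects —
selection uses valence annotations only, never the diagnosis — which
mirrors the reference protocol; `select_features(subjects = ...)` supports
a strict mode in which cross-validated callers restrict selection to
training subjects, because the protocol above does let the held-out
subject's valence structure influence the shared set (not its label).
Optional greedy redundancy pruning (`redundancy_threshold`, default off;
0.95 recommended) visits candidates in decreasing order of their strongest
per-subject correlation (ties to the earlier column) and drops a candidate
whose pooled-utterance correlation with a kept feature reaches the
threshold, so at threshold 1 only exact collinearity is removed. The
reference analysis mentions mutual-correlation redundancy removal without
a procedure; this greedy rule is this package's deterministic choice, and
whether pruning preceded or followed the valence rule being unknown, it is
applied after.

**Moment aggregation** (`per_valence_moments()`). Per feature and valence
class we use the population central moments `m_r = mean((x - mean(x))^r)`:
mean, skewness `m3 / m2^1.5`, and non-excess kurtosis `m4 / m2^2`. The
printed source formulas omit the `1/N` normalizations and use a
sum-of-squares "σ"; we adopt the standard scale-free definitions
deliberately, so moments are comparable across features of different
magnitude. A class with zero variance gets skewness and kurtosis 0 and a
degeneracy flag instead of `NaN`, keeping subjects with locally constant
features usable. `min_per_valence` (default 3 utterances) is the floor
below which within-class skewness and kurtosis stop being meaningful;
validation excludes such subjects explicitly rather than silently.

**Modulation fit** (`estimate_emf()`). The per-subject system has 3
equations and `3 * n_opt` unknowns, so the printed normal-equation inverse
does not exist for more than one feature; we compute the minimum-norm
least-squares solution through the singular value decomposition (rank
tolerance `max(dim) * eps * max(singular value)`), which coincides with
the normal equations whenever they are solvable and interpolates the
targets exactly whenever the moment matrix has full row rank. The moment
matrix is not standardized and carries no intercept column — scaling is
deferred entirely to the classifier — and diagnostics (rank, residual
norm) are kept per subject. Note one consequence of the minimum-norm
choice: coefficient magnitudes shrink roughly inversely with the moment
magnitudes, so the signature is a genuinely nonlinear function of the
underlying modulation slopes.

**Dynamic selection cascade** (`dfs_select()`). Three gates per held-out
subject:

* *C1, Fisher score*: `SB/SW` with `SB` the squared deviations of the two
  class means from the global mean and `SW` the summed per-class
  population variances; kept iff strictly above `fds` (default: the 50th
  percentile of the training scores, resolved per fold — scale-free across
  feature magnitudes). `SW = 0` with separation gives `+Inf` (always
  kept); with no separation, 0.
* *C2, Mahalanobis ratio*: per feature, the squared distance of the test
  value to the nearer class, squared again and divided by the distance to
  the farther class (unbiased class variances); kept iff strictly below
  `mr` (default 1). Small values mean "close to one class, far from the
  other"; large values flag outliers (far from both) and ambiguity. The
  printed formula references the ratio to a fixed first class; run
  end-to-end that removes, for every test subject of the second class,
  exactly the discriminative coefficients, driving their recall to zero —
  incompatible with the reference results and with the stated purpose of
  the step. The cascade therefore references the nearest class (identical
  to the printed form whenever the test value is nearer class 1);
  `dfs_thresholds(mr_reference = "first")` restores the literal reading.
* *C3, class probability*: the larger of the two fitted Gaussian class
  densities at the test value. The default mode expresses the threshold in
  z-units — keep if the test value is within `p` (default 2.5) class
  standard deviations of the nearest class mean — which is equivariant
  under per-feature rescaling; `p_mode = "density"` applies the literal
  density threshold for fidelity.

Degenerate statistics propagate as the documented 0/∞ conventions rather
than raising, so cross-validation never aborts on a pathological fold. If
C3 leaves nothing the C1 mask is used, and if that is empty all features
are used (flagged); selection is stateless across test subjects. No
threshold values are reported for the reference analysis; all three
defaults are this package's choices and are exposed in `dfs_thresholds()`.

**Classifier and evaluation** (`loso()`). Linear-kernel SVM with the
margin penalty fixed at 1 and per-feature standardization fitted on the
training fold only (constant columns pass through unscaled); the held-out
subject never influences scaling. Decision scores are signed distances to
the hyperplane, oriented so larger means DD; AUC uses the Mann–Whitney
rank form with ties counted ½. `TN/(TN+FN)` is reported as NPV and
additionally under `for_reported`, because the reference figure labels
this quantity FOR while the conventional false omission rate is its
complement (`for_standard`); both are derivable from every report. The
4-class label coding is fixed by declaration as TD = 0, PDD-NOS = 1,
SLI = 2, AD = 3.

**Baselines** (`baseline_evaluate()`, `valence_lda_accuracy()`). FS1
ranks features by absolute Welch t between DD and TD utterances (top 100
by default; zero standard error ranks last), FS2 reuses the valence rule
on the training partition. The cross-validation unit defaults to the
subject (all of a subject's utterances held out together), preventing
subject leakage; utterance-level stratified folds are available for
literal fidelity to a per-utterance protocol. The valence-recognition
check fits a per-subject three-class LDA by leave-one-utterance-out, with
a ridge-regularized fallback (pooled within-class covariance plus
`1e-6 * mean(diag)` on the diagonal) for singular scatters, flagged when
used.

## What the synthetic cohorts emulate

`cohort_config()` reproduces the statistical skeleton the method assumes,
with defaults mirroring the reference cohort: 68 TD, 10 PDD-NOS, 13 SLI,
11 AD subjects; 15 negative, 6 neutral and 5 positive utterances per
subject (the emotional layout of the story-telling stimulus); 19 signal
features (the count retained in the reference analysis) plus 21 nuisance
features. Signal feature values follow `a_ij * e + b_ij + ε` with subject
slopes drawn around group means, offsets `b_ij ~ N(0, 1)` and
`ε ~ N(0, 0.1²)`; group separation defaults to a slope shift of
`effect_size = 0.6`, three within-group standard deviations
(`within_group_sd = 0.2`), with the noise a tenth of the unit signal
scale. The subgroup shift patterns (all-positive; negative every third
feature; negative every fourth) are distinct — so four-class structure
exists for selection-frequency profiling — and mutually positively
correlated, so the three disorder modes share a half-space around the TD
centre and binary separability is governed by `effect_size` alone;
antipodal patterns would place TD at the midpoint of two disorder modes
and make TD-vs-DD unseparable by any linear rule at any effect size.
`mode = "sign_flip"` builds the paradigm-contrast cohorts: TD slopes
centred at `+slope_mean`, all DD slopes at `-slope_mean`, which with
balanced valence counts makes every per-utterance marginal identical
across groups — only the modulation carries the diagnosis, the utterance
baseline must fail, and any residual baseline skill would indicate
leakage.

What the generator does *not* emulate: real acoustic feature
distributions (heavy tails, inter-feature correlation structure,
RASTA-PLP/MFCC dynamics), annotation noise in valence labels, variable
utterance counts across subjects, or age/sex structure. Passing tests
therefore demonstrate that the pipeline recovers planted linear modulation
structure and manufactures none under the null — not that it attains any
particular accuracy on clinical recordings.

## Problem sizes and numerical tolerances

The test suite and the acceptance script run full cohorts of 102 subjects
(≈2650 utterances, 57 signature coefficients) for the strong-effect,
null and permutation checks, 36-subject balanced cohorts (1080 utterances)
for the paradigm contrast, and hundreds of randomized small instances for
oracle equivalence: correlations, moments and cascade statistics to
1e−10, the pseudoinverse fit to 1e−8 against an independently computed
generalized inverse. Determinism is pinned by a single integer seed per
run; fold order is the subject order of first appearance.

## Known limitations

* The valence scale is treated as numeric and equally spaced; ordinal
  treatments are out of scope.
* Only the two-class (TD vs DD) decision is modelled; the subgroup sizes
  that motivate this also mean subgroup recalls have wide uncertainty.
* The minimum-norm signature is basis-dependent through the moment
  blocks; permuting features permutes coefficients within blocks, but
  adding or removing a feature changes all coefficients.
* With N_opt = 0 (no feature passes the threshold) the pipeline stops
  with an explicit error rather than guessing a fallback set.
* The DFS thresholds interact; the shipped defaults behave well across
  feature scales but are not tuned to any particular corpus.
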