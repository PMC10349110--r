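---
title: "Scoring and modelling forensic face-comparison proficiency tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and modelling forensic face-comparison proficiency tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facefuse)
```

## The measurement problem

Forensic facial image comparison is evaluated with proficiency tests: a
fixed inventory of 1-to-1 face-pair comparisons, each either a *same
person* or a *different people* pair, judged on an 11-point ordinal support
scale from −5 (extremely strong support for different people) to +5
(extremely strong support for same person), with 0 meaning the comparison
is *inconclusive*. The canonical inventory this package is organised
around has 20 items — 13 same-person and 7 different-people pairs, with
stated photo time gaps of 0–2 years (3 items), 2–8 years (13) and 8+ years
(4) — taken by several qualitatively different kinds of observer: novices,
naturally skilled super-recognizers, trained forensic examiners, whole
forensic laboratories submitting one team decision, and facial-recognition
networks contributing real-valued similarity scores.

Four analyses make up the pipeline, and each answers a different question:

1. **How accurate is each observer?** Rating-scale AUC.
2. **How does each observer use the scale?** Signal-detection bias and
   response profiles.
3. **Do observers rank the items the same way?** Spearman similarity
   structure by trial type.
4. **How accurate are pooled judgments?** Resampled score fusion.

## Accuracy: the rating-scale AUC

An observer's accuracy is the probability that a randomly chosen
same-person item received a higher rating than a randomly chosen
different-people item, ties counting one half — the tie-corrected
Mann–Whitney statistic. `rating_auc()` computes it from mid-ranks;
`roc_points()` independently sweeps a decision cutoff across the observed
rating values and integrates the empirical ROC by trapezoids. The two
agree to machine precision on every input, which the test suite asserts on
thousands of random instances; the dual computation is the package's
internal oracle for the accuracy stage.

Two conventions matter and are fixed throughout:

* **Ties contribute 0.5 per tied pair.** This is the convention under
  which the rank statistic and the trapezoidal ROC area coincide exactly.
* **Missing responses are dropped for that observer only** — no
  imputation. An observer with an entire truth class missing has no
  defined AUC and is excluded with a warning.

Because the statistic depends only on ranks, machine similarity scores are
scored without any rescaling.

## Response style: signal detection over decisive responses

The scale is collapsed by sign: positive ratings are "same person"
decisions, negative ratings "different people", and 0 is a non-decision.
Hit and false-alarm rates are computed over decisive responses only; the
equal-variance Gaussian model then gives sensitivity `d' = z(H) − z(F)`
and criterion `c = −½(z(H) + z(F))`, with negative `c` a liberal bias
toward "same person".

Numerical conventions:

* **Boundary correction.** With 13 same-person items a perfect hit record
  is common, and `z(1)` is infinite. When either raw rate is 0 or 1 the
  log-linear correction is applied to both rates — 0.5 added to each
  response count, 1 to each denominator — and flagged in
  `correction_applied`. The correction shrinks extreme criteria slightly
  toward 0 at 20 items; at a few hundred items per observer it is rarely
  triggered and the estimators are unbiased (the recovery tests quantify
  this).
* **Inconclusive handling is a documented sensitivity toggle.** The
  default excludes 0 from both numerator and denominator (a non-decision);
  `inconclusive = "different"` instead counts 0 as a conservative
  "different people" decision, so the convention used by any external
  report can be matched.
* **Errors are sign errors only.** A 0 response is never an error. The
  headline profile statistics are exact count ratios: the inconclusive
  rate (share of non-missing responses equal to 0) and the
  high-confidence misidentification share (share of all errors that are
  +4/+5 responses on different-people items).

## Similarity structure

Whether two observers *rank the items alike* is a different question from
whether they are accurate, and it is trial-type specific: two observers
can agree perfectly about which same-person pairs look most alike while
ordering the different-people pairs in opposite ways. `correlation_matrix()`
therefore restricts to one trial type before correlating observers.

With at most 11 distinct values on at most 13 items, ties dominate, so
Spearman's rho is computed as the Pearson correlation of mid-ranks (the
tie-aware form). Observers with fewer than two non-missing responses or a
single distinct response value on a trial type cannot support a rank
correlation; they are excluded and logged with the reason. Block
agreement is the plain (unweighted, un-Fisher-transformed) average of the
relevant matrix entries, off-diagonal only within a group; a relabelling
argument collapses groups, e.g. everything human versus the machine block.

## Fusion

A nominal group's judgment is the element-wise arithmetic mean of its
members' per-item ratings. Machine scores are first mapped onto the
rating range by a per-scorer min–max affine map over the analysed item
set (minimum score → −5, maximum → +5) — computed once, not per resample,
so a scorer's fused contribution is composition-independent. The fused
vector is scored with `rating_auc()`; `run_fusion()` repeats the draw
1000 times (by default) per composition and reports the full AUC
distribution with median and range. Sampling is without replacement
within a draw (a nominal group is made of distinct individuals) and with
replacement across draws; named-observer entries hold a particular member
(e.g. the best-performing network) fixed in every draw. Medians rather
than means summarise the skewed resampled distributions.

Averaging helps because members' errors partly cancel: the benefit is
largest when errors are independent and vanishes as members become copies
of one another. Both ends of that spectrum are asserted by tests: fusing
duplicates of one observer is exactly an identity on AUC (rank
invariance), and the pair-versus-singleton gain shrinks monotonically as
the generator's shared-component loading pushes member correlation toward
one.

## The synthetic observer model

Every stage above is validated against synthetic studies with known
generating parameters, because real proficiency-test responses are
confidential. The generator (`generate_study()`) is an equal-variance
Gaussian signal-detection model:

* Item *i* carries evidence mean `+d*_j/2` (same-person) or `−d*_j/2`
  (different-people) for observer *j*, plus a standard-normal **shared
  item component** `u_i` with loading `lambda_shared` (idiosyncratic noise
  scaled so total noise variance is 1). The shared component is what makes
  human observers rank items alike.
* The latent evidence is discretized onto the 11-point scale by bands
  around the observer's criterion `c*_j` whose half-widths grow from a
  base of 0.4 z-units as a geometric series with ratio `1/kappa`: large
  `kappa` compresses the outer boundaries toward the criterion and piles
  responses onto −5/+4/+5, reproducing the confidence-extreme style.
  Evidence in the innermost band yields a 0 response with probability
  `p_inconclusive` — inconclusives are emitted where the evidence is
  genuinely weakest.
* Machine scorers emit continuous scores: class separation plus
  `lambda_shared · u_i`, **minus** `nu · u_i` on different-people items
  only, plus Gaussian noise (`noise_sd`). At `nu = 0` machines rank items
  like humans; for `nu > lambda_shared` their ordering of
  different-people pairs anti-correlates with human ratings while
  same-pair agreement is untouched. This one knob decouples the two trial
  types, which is exactly the representational-divergence signature the
  similarity analysis is designed to detect.

Under this model the closed-form expected AUC of a human observer is
`pnorm(d*/sqrt(2))`, which anchors the generator's calibration and the
recovery tests.

### Default study conditions

`enfsi_synthetic_config()` fixes a default study of 20 items (13/7) and
106 novices, 37 super-recognizers, 16 examiners, 19 laboratories and 10
machine scorers. Parameters were set once, by inverting the model at
group statistics representative of published proficiency-test outcomes,
and are not data-fitted:

| group | d* | c* | kappa | p_inconclusive | targets |
|---|---|---|---|---|---|
| novice | 1.01 | −0.20 | 1.0 | 0.05 | AUC 0.762 |
| super_recognizer | 2.25 | −1.08 | 1.8 | 0.02 | AUC 0.880, strongly liberal, ~0.3% inconclusive |
| forensic_examiner | 1.90 | −0.10 | 0.8 | 0.46 | AUC 0.910, neutral, ~9% inconclusive |
| forensic_laboratory | 2.75 | 0.00 | 1.0 | 0.30 | AUC 0.974 |
| dnn | 1.04 | — | — | — | AUC 0.876, nu = 0.75 |

Derivations: `d* = sqrt(2) · qnorm(AUC)` for groups with moderate response
styles; the super-recognizer value is raised above that inversion because
their extreme response style (kappa = 1.8) concentrates both truth classes
at +5 and the resulting ties depress the rating-scale AUC — the committed
value restores the target accuracy under the discretizer, calibrated by
simulating the generator at large item counts. The machine value lives on
its own score-noise scale (total class variance `lambda^2 + noise_sd^2`,
not 1). `p_inconclusive` values solve `rate = p_inc · P(evidence in the
innermost band)` at each group's `d*` and `c*`. `nu = 0.75` was chosen so
the human × machine block correlation splits by trial type at roughly the
magnitude reported for real human/network comparisons (≈ +0.3 same-pair,
≈ −0.2 different-pair). Between-observer jitter (sd 0.2–0.35 on `d*` and
`c*`) gives groups realistic internal spread.

### What the generator does and does not emulate

It reproduces the statistical structure the analyses consume: ordinal
scale use, bias, extremeness, inconclusive behaviour, inter-observer
correlation, machine divergence, missingness handling. It does **not**
emulate item-difficulty heterogeneity beyond the shared component, the
time-gap covariate (carried in the key but not used by the evidence
model), machine–machine architecture clusters, or laboratory-internal
deliberation (laboratories are simply high-`d*` single observers).
Passing tests therefore demonstrate correctness of the estimators and the
qualitative signatures, not fidelity to any particular real cohort.

### Recovery conventions

Estimator-recovery cohorts are generated with `lambda_shared = 0` and
`p_inconclusive = 0`. Both choices are deliberate: the shared component
makes per-observer criterion errors correlated across a cohort (the
group-mean error then cannot shrink with cohort size — an item-sampling
effect, not an estimator defect), and inconclusive censoring removes
evidence near the criterion, slightly shifting the decisive-response
population rates. Each mechanism is validated by its own tests
(block-structure signs and monotonicity; inconclusive-rate monotonicity)
rather than being folded into the recovery bounds. The committed recovery
bound — mean absolute criterion error at most 0.1 over a 100-observer ×
200-item cohort — was calibrated once with an oversized pilot (30
independent replications spanning MAE 0.067–0.093).

## Problem sizes and determinism

All simulation-backed tests use fixed seeds and modest sizes chosen for
statistical headroom: 200–1000 items for estimator recovery, 60–100 items
for structure and fusion properties, 1000 resamples per fusion
composition, 2000 items for the single-observer closed-form AUC check
(within three standard errors by the Hanley–McNeil formula). Reported
study-level summaries average 30 replicate 20-item studies, because a
single draw of 20 items sharing one item component moves every observer's
accuracy together by several points. Every
generator and fusion call saves and restores the global RNG state, so
package functions never perturb a user's random stream; identical
configurations produce byte-identical output tables, and the pipeline
manifest records the seeds and toggles needed to re-run a bundle
bit-identically.

## Known limitations

* With only 7 different-people items, per-observer statistics on the
  20-item inventory are coarse: criterion estimates shrink toward 0
  whenever the boundary correction triggers, and single-observer AUCs move
  in steps of 1/91.
* The exclusion rule for degenerate observers ("fewer than two distinct
  response values on a trial type") subsumes the stricter
  "only one response made" reading; both trigger the same exclusion here.
* Block means average correlations directly; no Fisher transform is
  applied, matching common reporting practice but slightly compressing
  extreme averages.
* The fusion analysis models statistical pooling of independent judgments;
  it does not model interacting committees.
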