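# facefuse

Analysis toolkit for **forensic face-comparison proficiency tests**: the
kind of test in which forensic facial examiners, super-recognizers, whole
laboratories and facial-recognition networks each judge a set of 1-to-1
face-pair comparisons ("same person or different people?") on an 11-point
ordinal support scale from −5 (*extremely strong support for different
people*) through 0 (*inconclusive*) to +5 (*extremely strong support for
same person*).

The package is written for researchers and forensic-science practitioners
who need to score such tests, characterise *how* different kinds of
expertise differ beyond raw accuracy, and quantify the benefit of pooling
diverse experts:

- **Accuracy** — per-observer rating-scale ROC curves and AUC, computed as
  the tie-corrected Mann–Whitney rank statistic

  `AUC = [ #(same, different) pairs with r_same > r_diff + ½ · #ties ] / (n_same · n_diff)`,

  which is identical to the trapezoidal area under the rating-threshold
  ROC and invariant to any monotone transform of an observer's ratings, so
  integer human ratings and real-valued machine similarity scores are
  scored on the same footing.
- **Response style** — equal-variance signal-detection profiling of
  decisive (non-zero) responses: hit rate *H*, false-alarm rate *F*
  (log-linear corrected at the boundaries), sensitivity `d′ = z(H) − z(F)`
  and criterion `c = −½·(z(H) + z(F))` (negative = liberal toward "same
  person"), plus response-scale usage, error-by-confidence distributions,
  inconclusive rates and the share of errors that are high-confidence
  misidentifications.
- **Similarity structure** — observer × observer tie-aware Spearman
  correlation matrices computed separately for same-person and
  different-people pairs, with the degenerate-observer exclusion rule,
  block-average agreement between groups, and diverging-palette heatmaps.
- **Fusion** — wisdom-of-crowds score fusion: resample nominal groups
  (e.g. one examiner + one network), average their per-item ratings
  (machine scores min–max rescaled onto the rating range first), score the
  fused ratings with AUC, repeat 1000 times, and compare compositions by
  median accuracy.
- **Synthetic observers** — a generative model (Gaussian evidence +
  shared item component + 11-point discretizer + divergent machine
  scorers) that emulates a full proficiency study with controllable
  sensitivity, bias, confidence extremeness, inconclusive use and
  human/machine representational divergence, so the whole pipeline is
  testable without access to confidential test data.

## Worked example

A small example study (two examiners, two super-recognizers, two novices,
two machine scorers on the standard 20-item inventory) ships with the
package:

```r
library(facefuse)

key <- load_item_key(system.file("extdata", "example_key.csv", package = "facefuse"))
mat <- load_ratings(system.file("extdata", "example_ratings.csv", package = "facefuse"),
                    key, value_kind = "raw_score")

group_auc_summary(mat)
#> <group_accuracy> mean rating-scale AUC by group
#>              group n mean_auc      sd_auc
#>  forensic_examiner 2    92.0% 0.003885202
#>   super_recognizer 2    90.7% 0.000000000
#>                dnn 2    86.8% 0.046622425
#>             novice 2    82.6% 0.002266368
```

Examiners and super-recognizers sit at the top; the machine scorers match
them closely and the novices trail. Signal detection separates the *styles*
behind similar accuracies:

```r
sdt <- sdt_summary(human_submatrix(mat))
sdt[, c("observer_id", "group", "d_prime", "criterion_c")]
#>   observer_id             group  d_prime criterion_c
#> 1       ex001 forensic_examiner 1.636341 -0.56482351
#> 2       ex002 forensic_examiner 2.303817  0.23108558
#> 3       sr001  super_recognizer 1.992026 -0.43006403
#> 4       sr002  super_recognizer 1.645432 -0.98002689
#> 5      nov001            novice 1.569973  0.28258415
#> 6      nov002            novice 1.240439 -0.05427046
```

Both super-recognizers show a liberal criterion (c < 0, a bias toward
declaring "same person"); the examiners straddle neutrality. A full run —
accuracy, response profiles, similarity heatmaps, fusion comparison and a
JSON manifest — comes from one config:

```r
cfg <- system.file("extdata", "example_config.yaml", package = "facefuse")
run_pipeline(cfg, out_dir = "facefuse_out")
```

or, from a shell, via the thin CLI wrapper:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "facefuse.R", package = "facefuse"))') \
    simulate --seed 1 --out facefuse_out
```

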