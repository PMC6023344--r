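# trizone

Trichotomization of quantitative diagnostic tests: negative, inconclusive
and positive decision zones.

## The problem

A quantitative diagnostic test or biomarker rarely separates diseased from
non-diseased subjects cleanly: the two score distributions overlap, and
scores in the overlap are genuinely inconclusive. Forcing every score
through a single cut-point hides this, concentrates decision errors on the
subjects whose scores are least informative, and — because repeated
measurements of the same subject fluctuate — makes those borderline
decisions unreliable on retest. The remedy is to report three zones
instead of two: scores below a lower cut-point are called negative, scores
above an upper cut-point positive, and the band in between is declared
inconclusive, prompting retesting, a better instrument, or watchful
waiting.

`trizone` implements the three established ways of locating that band for
a marker with (approximately) bi-normal class distributions, plus
everything needed to evaluate and compare them:

* **TG-ROC** (`tgroc_zones()`): pin the lower cut-point so the outer
  sensitivity is a chosen value (e.g. `Se(lower) = 0.95`, limiting false
  negatives in the negative zone to 5% of diseased subjects) and the upper
  cut-point likewise for specificity. Under the bi-normal model the
  cut-points are exact normal quantiles,
  `lower = mu1 + sd1 * qnorm(1 - Se)` and `upper = mu0 + sd0 * qnorm(Sp)`;
  on raw data they are the observed scores that first meet the targets.
* **Grey zone** (`grey_zone()`): start from the clinical context instead.
  Given a pre-test probability *p* and required post-test probabilities,
  the odds form of Bayes' theorem
  (`post odds = pre odds x LR`) yields the minimum positive and maximum
  negative likelihood ratios, `LR+ = Se/(1-Sp)`, `LR- = (1-Se)/Sp`; the
  joint solution
  `Sp = (LR+ - 1)/(LR+ - LR-)`, `Se = LR+ (1 - LR-)/(LR+ - LR-)` gives the
  minimum Se/Sp, and the cut-points follow by the TG-ROC mechanics.
* **Uncertain interval** (`ui_binormal()`, `ui_nonparametric()`): work
  outward from the intersection of the two class densities — the score at
  which a decision is a coin flip and which equals the Youden-optimal
  threshold (`intersection_binormal()`, `youden_threshold()`). The
  interval `[L, U]` around the intersection *I* is sized so that, for the
  scores inside it, within-interval sensitivity
  `(F1(U) - F1(I)) / (F1(U) - F1(L))` and the analogous specificity equal
  a target just above 0.5 (default 0.55): inside the interval the test is
  barely better than chance, outside it decisions are sharper.

Evaluation uses 3×2 tables (`three_by_two()`) and outer-section metrics
(`outer_metrics()`, `outer_metrics_binormal()`): the proportion of
subjects who actually receive a decision, the prevalence among them, their
Se/Sp/accuracy, and the net yield (correct decisions as a fraction of
*all* subjects, `yield = accuracy x proportion`). A test–retest simulator
(`simulate_retest()`, `decision_consistency()`) quantifies how unreliable
decisions inside the uncertain band are, and synthetic generators
(`synth_fixture()`, `sample_binormal()`, `box_cox()`) provide
reproducible example data, including a right-skewed creatine-kinase-like
marker normalized by a Box–Cox transform.

## Worked example

A carrier-detection-like marker: 75 carriers vs 134 non-carriers,
right-skewed scores, higher values indicating carriership.

```r
library(trizone)

ck  <- synth_fixture("dmd", seed = 7)     # 75 diseased / 134 non-diseased
lam <- estimate_lambda(ck)                # -0.279: Box-Cox exponent
fit <- fit_binormal(transform_sample(ck, lam)$sample)

grey_zone(fit, post_pos = 0.95, post_neg = 0.05, pretest = mean(ck$labels))
#> Grey zone (pretest = 0.3589, post-test targets 0.95 / 0.05)
#>   required LR+ >= 33.9467, LR- <= 0.0940
#>   minimum se = 0.9085, sp = 0.9732
#> Decision zones: inconclusive band [2.14016, 2.35978] (higher scores indicate disease)

ui <- ui_binormal(fit, 0.6, 0.6)
ui
#> Bi-normal uncertain interval (targets se = 0.6, sp = 0.6)
#> Decision zones: inconclusive band [2.20763, 2.3331] (higher scores indicate disease)
#>   intersection 2.26435; within-interval se = 0.6000, sp = 0.6000

outer_metrics_binormal(fit, mean(ck$labels), ui$zones)
#> Outer-section metrics (decided records only):
#>   proportion decided 0.7693, prevalence 0.3553
#>   se 0.7736, sp 0.9423, accuracy 0.8824, net yield 0.6788
```

Reading the output: to guarantee a 95% post-test probability of
carriership after a positive call and 5% after a negative one, at the
sample prevalence of 0.36 the marker would need `Se >= 0.91` and
`Sp >= 0.97`; the resulting grey zone covers the transformed-score band
2.14–2.36 (`inv_box_cox()` maps it back to the raw scale). The uncertain
interval is much narrower — it withholds only the 23% of subjects whose
scores are nearly uninformative — and the subjects outside it are
diagnosed with 88% accuracy, for a net yield of 68% correctly diagnosed
subjects overall. Recomputing the post-test probabilities from the
grey zone's own outer sections gives 0.92 / 0.09 rather than the
pre-selected 0.95 / 0.05: requirements imposed on the full sample are not
inherited by the subgroup that actually gets a decision.

## Command line

A thin CLI wraps the same functions (installed under `exec/`, or run via
`Rscript -e 'trizone::trizone_cli()' --args ...`):

```sh
trizone simulate --fixture dmd --seed 7 --out ck.tsv
trizone ui --file ck.tsv --ui-se 0.6 --ui-sp 0.6 --parametric --lambda -0.279
trizone bayes --pretest 0.10 --post-pos 0.7 --post-neg 0.001
trizone tables            # the two prevalence reference tables
```

Reports are flat key–value documents (`--format tsv` or `json`); errors
exit non-zero with a single machine-parsable line on stderr.

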