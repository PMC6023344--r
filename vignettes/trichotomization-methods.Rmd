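---
title: "Trichotomization methods: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trichotomization methods: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trizone)
```

## The setting

A quantitative marker is measured on subjects who either have a target
condition (labels 1) or do not (labels 0). The package's working model is
bi-normal: within each class the scores are normally distributed,
`X | D=0 ~ N(mu0, sd0^2)` and `X | D=1 ~ N(mu1, sd1^2)`, possibly after a
monotone Box–Cox transformation of the raw scale. All method mathematics
assumes the diseased class lies *above* the non-diseased class; markers
where disease lowers the score (`direction = "lower"`) are handled once,
centrally, by negating scores on entry and mapping thresholds back
(negate and swap) on exit, so no formula needs a second variant.

Three definitions of the inconclusive middle band are implemented. They
answer different questions:

* **TG-ROC** asks: *which outer scores support decisions at a pre-chosen
  Se and Sp?* The cut-points are the exact quantiles
  `lower = mu1 + sd1 * qnorm(1 - se_target)`,
  `upper = mu0 + sd0 * qnorm(sp_target)` (or their empirical
  counterparts). Both are prevalence-independent.
* **The grey zone** asks: *which scores support the post-test
  probabilities this clinical setting requires?* Pre-test odds times
  likelihood ratio gives post-test odds, so the requirements translate
  into a minimum `LR+` and maximum `LR-`, thence into a minimum (Se, Sp)
  pair, and the cut-points follow by the TG-ROC mechanics.
* **The uncertain interval** asks: *which scores are so uninformative
  that deciding on them is close to coin-flipping?* It brackets the
  intersection of the class densities and fixes the within-interval Se
  and Sp at a target just above one half.

## Parameters that matter

| parameter | where | default | meaning |
|---|---|---|---|
| `se_target`, `sp_target` | `tgroc_zones()` | 0.95 | outer-zone Se/Sp; 0.90 and 0.95 are the conventional choices; higher targets always widen the band |
| `pretest` | `grey_zone()` | sample prevalence | pre-test probability of disease; the sample prevalence is an uninformed stand-in, used with a logged notice |
| `post_pos`, `post_neg` | `grey_zone()` | 0.95 / 0.05 | required probability of disease after a positive / negative call; must straddle `pretest` |
| `ui_se`, `ui_sp` | `ui_binormal()`, `ui_nonparametric()` | 0.55 | within-interval Se/Sp; must lie in (0.5, 1): at 0.5 the interval is empty (a coin flip exactly), larger values admit more of the overlap |
| `reliability` | `simulate_retest()` | — | test–retest correlation r of two measurements of the same subject, in (0, 1] |

All probabilities are dimensionless; thresholds inherit the score units.

## Conventions and degenerate inputs

**Closed inconclusive band.** A score exactly on a cut-point is
inconclusive; negative and positive decisions require strict
inequalities. On discrete scales the threshold score itself is the
natural first member of the doubtful middle, and a degenerate band
`[L, L]` then flags only the scores equal to `L`. The companion tie rule
used everywhere (curves, empirical thresholds, within-interval counts):
a score at a candidate cut-point counts as positive for sensitivity and
as not-negative for specificity, i.e. `Se(t) = P(X >= t | D=1)`,
`Sp(t) = P(X < t | D=0)`.

**Labels.** Only the exact coding {0, 1} is accepted. Any other coding is
an error at ingestion, never silently recoded.

**Collapsed zones.** When a test is strong enough (or targets lax enough)
that the computed lower cut-point reaches or crosses the upper one, no
middle zone is needed: the zones collapse to a single cut-point at the
midpoint of the crossed pair, the result carries `collapsed = TRUE`, and
a warning is raised rather than an error — a strong test is not a failure
mode.

**Infeasible requirements.** `grey_zone()` rejects specifications with
`post_neg >= pretest` or `post_pos <= pretest` (vacuous or unattainable),
and reports which likelihood-ratio constraint fails when a requirement
implies `LR+ <= 1` or `LR- >= 1`. The joint minimum (Se, Sp) from
admissible constraints is automatically inside `[0, 1]`.

## Numerical choices

**Minimum Se/Sp from the likelihood-ratio requirements.** Both
constraints are solved with equality:
`Sp = (LR+ - 1)/(LR+ - LR-)`, `Se = LR+ (1 - LR-)/(LR+ - LR-)`. This
joint-equality rule reproduces the tabulated minimum pairs across the
whole prevalence range and both worked clinical settings, and it is the
unique pair from which the required ratios can be recovered exactly
(round-trip tested to 1e-10). Full-precision values feed the
thresholding step; two- or four-decimal values appear only in reports,
rounded half-up (so 0.00905 prints as 0.0091, and integer-valued ratios
like 171 print without decimals).

**Density intersection.** Equating the two normal log-densities gives a
quadratic; with equal SDs the intersection is the midpoint of the means.
With unequal SDs there are two crossings and the one maximizing
`Se + Sp` is returned — the crossing at which the non-diseased density
falls below the diseased one. For well-separated markers this is the
root between the two means; for weak markers with strongly unequal SDs
the maximizing crossing can lie outside the means, and choosing it keeps
the identity "intersection = Youden threshold" intact (verified
numerically to 1e-6 over a 5x5 grid of models).

**Bi-normal uncertain interval.** The defining system — within-interval
sensitivity `(F1(U) - F1(I)) / (F1(U) - F1(L)) = ui_se` and specificity
`(F0(I) - F0(L)) / (F0(U) - F0(L)) = ui_sp` with `L <= I <= U` — is
reduced to one dimension: given `U`, the sensitivity equation yields
`F1(L)` in closed form, and the remaining specificity residual is a
monotone-bracketed function of `U` solved by `uniroot()` with tolerance
1e-13 on the argument. Both residuals are then verified against 1e-8
(in practice they sit at machine precision); non-convergence is an error
that carries the last iterate. As the targets drop to 0.5 the interval
collapses onto the intersection, which is the coin-flip limit the
definition is built around.

**Distribution-free uncertain interval.** Candidate endpoints are
observed scores bracketing an anchor. Two choices differ from a naive
transcription of the bi-normal recipe:

1. *Anchor.* The raw empirical Youden argmax converges at a cube-root
   rate because the empirical `Se + Sp` curve has a flat, noisy top; its
   error propagates into every within-interval count. The anchor is
   therefore the observed score closest to the centre of the
   near-maximal plateau (all candidates within `1/sqrt(min(n0, n1))` of
   the maximum), which is markedly more stable. The public
   `youden_threshold()` keeps the classical argmax (ties broken toward
   the midpoint of the class medians) for use as a dichotomous
   cut-point.
2. *Selection rule.* Minimizing the squared distance of the
   within-interval (Se, Sp) from the targets is ill-posed on large
   samples: integer-count coincidences (11/20 = 0.55 exactly) produce
   zero-objective pairs at arbitrarily small widths. The interval is
   instead the *widest* bracketing pair whose within-interval Se and Sp
   both stay at or below the targets — the largest region in which
   decisions remain near-chance. At the optimum both constraints bind
   (widening past either target makes the inside scores too
   informative, and a slack constraint always admits a wider feasible
   pair), so the rule converges to the bi-normal equality solution.
   Ties in width are broken by the squared deviation, then by symmetry
   about the anchor; if no pair is feasible at all, the least-squares
   pair is returned. Because the count profiles are monotone in each
   endpoint, the widest feasible pair is found exactly by rank
   arithmetic in `O(n log n)` — no grid thinning, and exhaustive-search
   equivalence holds on small samples by construction.

**Empirical AUC** uses the rank formulation of the concordance
probability with ties counted half, in double precision (the rank sum
overflows integer arithmetic near n = 10^5).

## The synthetic generators

`synth_fixture()` provides two seeded data sets shaped like published
marker studies, for examples and tests; no real data ships with the
package.

* `"iron-deficiency"`: 43 diseased / 167 non-diseased, *lower* scores
  indicating disease, equal class SDs, bi-normal AUC exactly 0.78 via
  the separation `sqrt(2) * qnorm(AUC)`. The scale (non-diseased mean
  28, SD 2) imitates a haemoglobin-content-like marker in pg; only AUC,
  sizes and direction are calibrated quantities.
* `"dmd"`: 75 carriers / 134 non-carriers, *higher* scores indicating
  carriership. Latent scores are bi-normal on a Box–Cox transformed
  scale (`lambda = -0.34`) with AUC exactly 0.87, and are
  back-transformed to a right-skewed raw scale. The carrier class gets
  the wider distribution (SD 0.14 vs 0.10), as real carrier
  creatine-kinase does; this is what makes TG-ROC deselect more
  non-carriers than carriers, the pattern the evaluation module is meant
  to exhibit. The latent location (1.95) keeps the inverse transform
  `(1 + lambda * y)^(1/lambda)` defined more than five latent SDs above
  the carrier mean.

What the generators deliberately do *not* emulate: measurement
truncation and detection limits, discrete reporting grids, non-normal
within-class shapes beyond what one common Box–Cox exponent captures,
covariate structure, or verification bias. Tests passing on these
fixtures therefore show the machinery is correct under the package's own
model, not that any particular real marker satisfies that model.

`estimate_lambda()` maximizes the two-class profile log-likelihood of a
common Box–Cox exponent (class-specific means and variances, Jacobian
term `(lambda - 1) * sum(log x)` included) over `[-3, 3]`. A common
exponent for both classes is the standard choice when a single
transformed scale must carry both distributions. The exponent is only
weakly identified when the score range is narrow relative to its
location, which is why the carrier-like fixture spans roughly a
four-fold score range.

The test–retest simulator uses the classical true-score decomposition
with class-specific variances: true score `T ~ N(mu_k, r sd_k^2)` plus
independent errors of variance `(1 - r) sd_k^2`, so each measurement
marginally follows its class distribution and the within-class
correlation of the two measurements is exactly `r`. Decision
reliability is reported both as raw agreement and chance-corrected
(`2a - 1`), since an agreement of 0.5 means nothing more than a coin
flip.

## Design choices at genuinely open points

* *Outer-zone improvement.* Deselecting the uncertain interval always
  improves the **accuracy** of the remaining decisions (verified over
  model grids), but not necessarily Se and Sp *individually*: for weak
  markers with strongly unequal SDs the asymmetric interval can trade a
  lower outer Se for a much higher outer Sp. Tests assert the accuracy
  improvement generally and the per-component improvement only for
  mirror-symmetric models, where it provably holds.
* *Expected vs observed metrics.* `outer_metrics_binormal()` (normal
  tail masses weighted by the pre-test probability) and
  `outer_metrics()` (counts from a 3x2 table) are separate functions
  with identical output fields, so the gap between model-expected and
  sample-realized performance — including the drift of realized
  post-test probabilities away from the pre-selected targets — stays
  visible instead of being averaged away.
* *"Accuracy" of the outer sections* is `(TP + TN) / decided`, which
  makes `yield = accuracy x proportion` an identity.
* *Collapsed-zone reporting* favours a flagged single cut-point over an
  error, because a test strong enough to need no middle zone is a
  legitimate outcome of every method here.

## Problem sizes

The test suite exercises closed forms exactly and stochastic claims at
fixed seeds: convergence checks use 10^4–10^5 draws per class,
the Monte-Carlo cross-check of the closed-form outer metrics uses 10^6
draws, decision-reliability runs use 2 x 10^4–10^5 subjects per class,
and brute-force oracles (pairwise AUC, threshold sweeps, exhaustive
interval search) run on samples of 12–40 observations where exact
equality is asserted. `scripts/acceptance.R` regenerates the headline
quantities at the same scales from a single `--seed`.

## Known limitations

* The bi-normal assumption is load-bearing for the parametric variants;
  a single Box–Cox exponent may not normalize both classes, and nothing
  here tests goodness of fit.
* The non-parametric uncertain interval needs real overlap (at least 10
  observations per class in the overlap region) and approximates its
  targets only as well as the local counts allow.
* Sampling uncertainty of the thresholds themselves (confidence
  intervals, bootstrap) is out of scope, as are multi-marker
  combinations, ordinal tests, and three-class disease-state methods.
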