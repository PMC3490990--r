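---
title: "Jointly optimizing discrimination and calibration: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Jointly optimizing discrimination and calibration: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(docsvm)
```

This vignette explains the statistical model behind `docsvm`, the
measurement theory it implements, and the choices made where the design
was genuinely open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The two goals and why they are joined

A probabilistic classifier of a binary outcome is judged on
*discrimination* — does it rank positives above negatives? — and
*calibration* — do groups of cases scored `p` experience the event at rate
`p`? The Brier score, the mean of `(p_i - y_i)^2`, couples them. Grouping
observations by their exact score value `s`, with `n_s` cases per group
and `rho_s` the positive fraction in the group, the Brier score splits
exactly into

* dis-calibration `CAL = (1/N) * sum_s n_s (s - rho_s)^2`, which vanishes
  iff every stated score matches its group's event rate, and
* refinement `REF = (1/N) * sum_s n_s rho_s (1 - rho_s)`, the mean
  impurity of the score groups, at most 0.25, zero iff every group is pure.

`brier_decomposition()` computes this split; the identity
`CAL + REF = Brier` is property-tested to 1e-12. Refinement is the bridge
to ranking: impure groups are the only source of tied or discordant
positive–negative pairs when the groups themselves are ranked
concordantly. Quantitatively (see `refinement_auc_bound()`),

```
AUC >= 1 - N^2 / (2 N+ N-) * REF,
```

with equality for the balanced all-0.5 sample. The published statement of
this bound is not machine-readable in our source text, so the constant is
re-derived: for groups ranked concordantly with their event rates, the
rank loss is the between-group discordance plus half the within-group
ties; bounding the discordant count for a score-ordered pair of groups by
`n_g n_h * sqrt(imp_g * imp_h)` (valid because `rho_g (1 - rho_h)` is
dominated by both impurities when `rho_g <= rho_h`) and applying
Cauchy–Schwarz gives rank loss `<= N^2 REF / (2 N+ N-)`. The concordance
premise matters — the test suite constructs its 1000 random check
instances with concordantly ordered realized group fractions — and the
all-0.5 anchor shows the constant cannot be improved in general.

On the hinge side, `hinge_rank_bound()` implements the companion
inequality `1 - AUC <= mean-hinge / (pi (1 - pi))` with `pi` the positive
fraction. It is loose (the right side can exceed 1) but directionally
decisive: driving the mean hinge loss to zero drives the AUC to 1. This
constant is likewise a re-derivation and is verified against brute-force
pair counting on 1000 random instances rather than taken on faith.

Together the bounds justify a single objective that serves both goals.

## The DOC-SVM objective and its optimizer

`train()` minimizes

```
J(w, b) = 1/2 ||w||^2 + C1 * sum_i max(0, 1 - yt_i (w x_i + b))
                      + C2 * sum_i (w x_i + b - y_i)^2
```

* Label codings: the hinge uses `yt in {-1, +1}`, the squared loss targets
  `y in {0, 1}`. The source text's equation symbols are typographically
  lost, but the squared loss is described as a ridge regression loss and
  the raw output must live on the probability scale for calibration to be
  meaningful, which makes the 0/1 coding the coherent reading.
* Regularization is the conventional `1/2 ||w||^2`; the bias is
  unregularized.
* `C1` (hinge penalty) buys discrimination pressure, `C2` (squared
  penalty) buys calibration pressure; both are per-observation sums, so
  their useful ranges scale with `1/N`. Defaults are 1; cross-validation
  grids span `10^-3 .. 10^3` (7 log-spaced points).
* With `C2 = 0` the objective is exactly the soft-margin linear SVM, and
  `model_kind = "svm"` runs the *same* code path — the reduction is tested
  as bit-identical optimization trajectories.

The optimizer is deterministic full-batch subgradient descent from
`w = 0, b = 0`, with the best-objective iterate returned and a warning
(never an error) on non-convergence. The step at iteration `t` is
`eta0 / (L * (1 + decay * t))` with defaults `eta0 = 0.1`,
`decay = 0.01`, `max_iters = 2000`, and stopping when the relative
objective change falls below `tol = 1e-8`. `L` is a gradient-scale
constant, `1 + 2 C2 lmax + C1 sqrt(n lmax)` with `lmax` the top eigenvalue
of the bias-augmented Gram matrix: the smooth part's curvature plus a
bound on the hinge subgradient norm. Without this normalization a fixed
nominal step diverges as soon as `C2 * N` is large, and any workable raw
step size would depend on the penalty magnitudes; with it, one default
works across the full cross-validation grid. At the hinge kink the
subgradient uses the strict-margin convention (`margin < 1` active).
Features are z-scored by default (constant columns pass through
untouched); the parameters are stored in the model and re-applied at
prediction time.

Probability read-outs (`predict_proba()`): DOC-SVM raw scores are clipped
to `[0, 1]` — the squared loss already targets the probability scale, and
clipping is the read-out consistent with evaluating that scale directly; a
`method` flag exposes logistic or Platt read-outs for sensitivity
analyses. Plain SVM scores carry no probability scale, so they are
Platt-scaled: a sigmoid `1 / (1 + exp(A f + B))` fitted by maximum
likelihood against smoothed targets `(N+ + 1)/(N+ + 2)` and
`1/(N- + 2)`. Platt parameters are fitted on the training scores
themselves (in-sample) everywhere, including inside cross-validation:
an internal held-out recalibration split would multiply training cost
k-fold and, at the sample sizes this package targets, trades a small
optimistic bias for a much noisier sigmoid. The logistic baseline
(`logreg_train()`) is fitted by BFGS on the penalized log-likelihood with
an analytic gradient and is checked against `glm()` to 1e-4 in
probabilities.

## Measurement conventions

* **AUC.** Ties count one half (the c-index convention), which makes the
  Mann–Whitney form and the trapezoidal area of `roc_curve()` agree to
  machine precision; both are computed and the equality is
  property-tested. Model evaluation panels compute AUC on *raw* decision
  scores: ranking is scale-free, and clipping would only collapse distinct
  scores into ties.
* **Score grouping.** The Brier decomposition groups by exact score value
  after rounding to 12 decimals. With continuous scores every group is a
  singleton (`REF = 0`, `CAL = Brier`) — still a valid decomposition, just
  an uninformative split; the rounding only stabilizes grouping against
  float noise.
* **Hosmer–Lemeshow.** Statistic
  `sum_g (O_g - E_g)^2 / (E_g (1 - E_g / n_g))` with `O_g` observed
  positives, `n_g` bin size, `E_g` the sum of predicted scores; scheme H
  bins `[0, 0.1), ..., [0.9, 1]`, scheme C cuts the sorted scores into
  `g` near-equal blocks. For order invariance the scheme-C sort breaks
  score ties by label, so tied observations are interchangeable units.
  Degenerate bins (`E_g` equal to 0 or `n_g`) contribute zero and are kept
  when their numerator is also zero, and are otherwise merged toward the
  centre of the bin sequence, preserving all counts. Degrees of freedom
  are retained-bins minus 2; when fewer than three bins remain the
  statistic is still reported with `p = NA` and a warning rather than an
  error, so tiny worked examples (two observations, two bins) remain
  computable. The 0.1-level critical value at ten bins,
  `hl_critical_value(0.1, 10) = 13.36`, is the fit threshold quoted
  throughout; we apply the 0.1 threshold to the p-value (rejecting when
  `p <= 0.1`), the reading consistent with the critical-value arithmetic,
  and reports carry both the statistic and the p-value so either
  convention can be applied.
* **Paired comparisons.** `compare_auc_z()` uses the DeLong
  placement-value covariance for correlated AUCs (the cited methods
  review does not pin a variant; DeLong is the field default and is
  cross-checked against `pROC` and a paired bootstrap). Metric columns
  from repeated splits are compared with `paired_ttest_one_tailed()`,
  with explicit conventions for degenerate differences (all-zero:
  `t = 0, p = 0.5`; constant non-zero: `p` 0 or 1 by sign).
* **Threshold metrics** default to 0.5 — the natural operating point for
  probability-scale outputs; no other operating point is privileged by
  the protocol.

## Model selection protocol

`kfold_cv()` uses label-stratified folds (round-robin within class) and
selects by the cross-fold mean of a criterion. The default criterion is
the Brier score: by the decomposition it prices calibration and
refinement simultaneously, which is the point of the method; `auc` and
`hlc_p` are exposed as alternatives. Ties break toward smaller `C2`, then
smaller `C1` (prefer the less aggressively calibrated, simpler model when
indifferent). `repeated_splits_eval()` implements the
30-random-(stratified)-splits protocol with the standard panel — AUC,
F-score, sensitivity, specificity, Brier, HL-C statistic and p-value —
recording failed splits as annotated missing rows. Tuning is done inside
each training split, never on pooled data. `ttest_feature_rank()`
reproduces the top-k-by-t-test screening step (Welch statistic, variance
floor 1e-12, index tie-break).

## Synthetic data: what it emulates, what it does not

* `gen_triangular_beta()` draws positives from density `2s` and negatives
  from `2(1 - s)` — realized exactly as the max and min of a uniform pair —
  giving `P(y = 1 | s) = s` at equal priors: perfect calibration with the
  AUC capped at `P(S+ > S-) = 5/6`. This is the canonical witness that
  perfect calibration and perfect discrimination are incompatible off the
  dichotomous corner.
* `shrink_scores()` divides scores by a constant (default 10): the
  rank-preserving, calibration-destroying transformation that motivates
  measuring both axes.
* `gen_gaussian_classes()` provides learner fixtures with a known
  logistic posterior and closed-form Bayes AUC `pnorm(delta / sqrt(2))`.
* `gen_grouped_bins()` emits identical one-hot rows per group with
  Bernoulli labels at the group probability: perfectly calibrated,
  imperfectly discriminative, and the fixture for the calibration-pull
  property (with `C1 = 1, C2 = 100` at `N = 2000` the per-group predicted
  probability matches the group's event rate within 0.02).
* `gen_target_auc()` generates scores at a requested AUC via the
  equal-variance binormal model on the probit scale. It is a stand-in for
  "models sampled near a given AUC"; the original sampling recipe is not
  specified, so no numeric reproduction of those figures is claimed.

The tradeoff experiment (`tradeoff_sweep()`) fixes `C1` and sweeps `C2`,
evaluating on a stratified holdout half. The study condition frozen into
the tests is `n = 600`, `d = 4`, `delta = 3`, `C1 = 1`,
`C2 in 10^[-3 .. 2]` (8 log-spaced points), 800 iterations: strong enough
separation that the steep logistic posterior punishes both the
SVM-like extreme (clipped, dichotomous outputs) and the pure
least-squares extreme (an underconfident linear-probability fit), so the
HL-C p-value across the sweep rises to an interior maximum and falls
again — in at least 8 of 10 seeds under the acceptance suite. The sweep's
swept variable is our operationalization of "enforcing discrimination";
the original figure does not name its x-axis. What passing these tests
shows is that the implementation reproduces the *mechanism*; none of the
generators model microarray noise, feature correlation, batch effects or
class imbalance at real-data severity, so they say nothing quantitative
about performance on expression data.

Every generator takes a seed and restores the caller's RNG state; sizes
used in the test suite (hundreds to a few thousand observations, up to
2e6 for the Monte-Carlo AUC check) were chosen so the full suite and the
acceptance script each run in well under a minute on one core while
keeping Monte-Carlo error an order of magnitude below every asserted
tolerance.

## Numerical choices and degenerate inputs

* Calibration metrics refuse scores outside `[0, 1]` rather than
  clipping; ranking metrics accept any real scale.
* Single-class inputs raise explicit "undefined" errors for AUC, ROC and
  both bounds — never `NaN`.
* F-score with neither predicted nor actual positives is reported as 0
  with a warning flag; sensitivity/specificity are `NA` when their class
  is absent.
* Constant score vectors in `platt_fit()` fix `A = 0` and set `B` from
  the smoothed prevalence, flagged.
* Zero-variance features in the t-test screen are floored at variance
  1e-12; constant columns skip z-scoring.
* Cross-validation redraws folds up to 10 times if a training fold loses
  a class, then errors.
* Model JSON uses 17 significant digits, the minimum that round-trips
  IEEE doubles exactly.

## Known limitations

* The learner is linear; no kernels, no mini-batch or dual solvers, no
  multiclass.
* The refinement bound's guarantee needs concordant group ranking;
  adversarially anti-concordant score groups can beat the bound, which is
  inherent to any bound built from group impurities alone.
* The two-component Brier decomposition is uninformative for continuous
  scores (singleton groups); binning-based variants are deliberately out
  of scope.
* The Hosmer–Lemeshow chi-square reference is an approximation whose
  finite-sample rejection rate at a calibrated null runs slightly above
  the nominal level (the suite observes roughly 0.8–0.9 non-rejection at
  the 0.1 level, n = 5000).
* In-sample Platt scaling is mildly optimistic; with abundant data an
  internal recalibration split is preferable.
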