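---
title: "Methods: activity-level scoring, step forecasting and rule-based recommendations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity-level scoring, step forecasting and rule-based recommendations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepcoach)
```

`stepcoach` implements a hybrid activity-coaching engine: a rule-based
layer that turns wearable data into daily activity levels and weekly
recommendations, and a data-driven layer that forecasts steps and
classifies levels. This vignette explains the models, their assumptions,
the tunable parameters, the synthetic-data personas, and the numerical
choices made where the design was genuinely open. It states no empirical
result beyond what the package's tests and acceptance script themselves
compute.

## Daily activity levels and weekly scores

A day is described by its step count and its light/moderate/vigorous
activity minutes (LPA/MPA/VPA). The MET-equivalent weekly minutes implied
by one day are

\[ W = (2\,\mathrm{VPA} + \mathrm{MPA}) \times 7 , \]

one vigorous minute counting as two moderate-equivalent minutes. Each
level 0–4 has two sufficient conditions: a band on \(W\) (all requiring at
least 5000 steps) and a band on steps alone (thresholds 5000, 7500,
10000, 12500). Public-health guidance for adults frames the top of this
scale: 150–300 moderate-equivalent minutes per week corresponds to the
300–360 band of the "medium active" level, and the generic weekly goal of
\(7 \times 3 = 21\) points means medium active every day.

Because both conditions are *sufficient*, a single day can satisfy the
minutes band of one level and the step band of another. `classify_day()`
returns the **maximum** satisfied level: each rule grants its level, and
coaching credits the stronger evidence. A day under 5000 steps is always
sedentary, since every minutes band requires the step threshold. The
footnote-style identity "MPA = 2 VPA" is read as the MET equivalence used
inside \(W\), not as a constraint on the data — real days routinely have
MPA ≠ 2 VPA.

Boundaries are implemented exactly as stated (e.g. `Steps > 4999` is
`Steps >= 5000` on integers). The test suite sweeps 100 000 random
days against an independent brute-force evaluation of the level rules
and checks coverage (some rule always fires) and monotonicity in steps.

## Sensor minutes and the 60-second budget

At sensor resolution each minute carries an activity-intensity count
(IMA) and a split of its 60 seconds across sedentary, weight-bearing,
standing, and LPA/MPA/VPA time:

\[ \text{sedentary} + \text{active} + \text{weight-bearing} +
   \text{standing} = 60 \text{ s.} \]

IMA determines the activity type: 0–400 light, 401–800 moderate, ≥ 801
vigorous. Sedentary time includes sleep — the sensors count non-activity
(leisure and sleep) as sedentary, which is why the synthetic generator
puts nights entirely into sedentary minutes.

## The synthetic-data personas

No real sensor data ships with the package; five personas (one per
activity level) generate it. Each persona fixes a mean and standard
deviation of daily steps centred mid-band for its level, a weekend
multiplier of 1.2 on the step mean (human activity differs between
weekends and weekdays), an optional linear trend, and a per-waking-minute
intensity mix. Design choices:

* **Waking window 06:00–22:59.** Non-sedentary minutes occur only there;
  nights are sedentary with zero steps.
* **Whole-minute intensities.** Each waking minute is assigned one
  dominant category from the mix and its full 60 seconds, which makes the
  budget identity hold by construction; IMA is drawn uniformly inside the
  dominant category's band (only band edges are specified, so uniform is
  the neutral choice).
* **Steps per active minute** are drawn from a normal around
  `daily target / active minutes` (20% relative spread, floored at zero)
  so daily totals match the persona mean in expectation.
* **Activity minutes per class** are drawn so that \(W\) lands inside the
  class's minutes band, making generated days fixed points of the labeler
  — the property the downstream classification tests rely on.
* **Missing data are marked, not dropped** (`inject_missing()`), so the
  forward-then-backward fill (`fill_missing()`) is testable; a
  round-trip on a constant series is the identity.

The personas emulate the *structure* real wearable data exhibits
(weekday/weekend contrast, trend, class imbalance, the budget identity),
not accelerometry physiology: there is no heart rate, no sleep
architecture, no autocorrelated within-day bout structure. Passing tests
therefore demonstrate correctness of the methods on data with known
ground truth, not performance claims about any real cohort.

## Feature selection

Features are pruned by pairwise Spearman correlation at \(|r| \ge 0.72\):
within a violating pair, the member with the larger mean absolute
correlation to all other features is dropped, ties broken alphabetically
(the choice of victim is otherwise arbitrary; this rule is deterministic
and permutation-stable). Shapiro–Wilk normality p-values are reported per
feature at \(\alpha = 0.05\) — they motivate using the rank correlation —
but never gate the selection. Constant features have undefined
correlations; they are reported and retained. When two data sources are
combined, the retained set is intersected with the partner's feature
names, yielding the common space
{sedentary, LPA, MPA, VPA, steps}.

## ADASYN balancing

For each minority class (one-vs-largest), with \(n_{maj}\) and
\(n_{min}\) the majority and minority counts:

* imbalance ratio \(IR = n_{maj}/n_{min}\);
* density weights from the mean Euclidean distance of each minority point
  to its \(k\) nearest neighbours in the full feature space
  (\(rc_i = d_i / \sum d\), \(dd_i = rc_i / \sum rc\));
* per-point synthetic counts \(N_i = dd_i \cdot N\), apportioned by
  largest remainder;
* synthetics \(x_i + \lambda (x_{nn} - x_i)\), \(\lambda \sim U(0,1)\),
  with \(x_{nn}\) among the \(k\) nearest *same-class* neighbours, so
  every synthetic lies on a segment between minority points.

Two sizing modes exist. The formulation that sets
\(N = IR \cdot n_{min}\) equals \(n_{maj}\) added synthetics, which
overshoots: the minority would become the new majority. The default
`mode = "standard"` therefore uses \(G = n_{maj} - n_{min}\), which
balances every class to the majority count (the behaviour the package's
balancing tests assert); `mode = "paper"` retains the literal sizing as a
fidelity switch. Distance-based density weighting is the implemented choice;
canonical ADASYN's difficulty weighting (majority fraction among
neighbours) differs, which is why density estimation uses all-class
neighbours while interpolation uses same-class neighbours. `k = 5` by
default; `k` is truncated with a warning when a class is too small.

## Forecasting with residual-error minimization

The daily step series is split 60/20/20 into train/validation/test in
temporal order — "stratified" shuffling is meaningless for a time series,
so the three named parts are taken as contiguous blocks. The base
forecaster is either an OLS autoregression of order `lag` (default; 14
suits month-scale histories, 50 longer ones) or the persistence model
\(\hat{x}_t = x_{t-1}\), selectable via `base=`. Its one-step in-sample
errors are modeled by an AR(`window`) (default 5) over the error series;
walking forward through the test block, each base forecast is corrected
by the residual model's one-step error estimate and the observed error is
appended:

\[ \text{improved forecast} = \text{forecast} + \text{estimated error}. \]

The correction is exactly additive (a tested invariant), and both
corrected and uncorrected metrics are returned so the improvement can be
observed. The improvement property is demonstrated on replicates of an
AR(1) signal whose innovations are themselves AR(1)-correlated: there the
persistence base (the recipe's own prescribed base) and an under-ordered
AR base leave structure in the residuals that the correction removes. A
well-specified AR base on the same process already absorbs that
structure, and the correction is then neutral — which is the expected
behaviour, not a defect.

Metrics follow the signed convention \(e = \text{actual} -
\text{predicted}\): RMSE \(= \sqrt{\overline{e^2}}\), forecast bias
FB \(= \bar e\) (positive means underprediction; an absolute accessor
`fb_abs()` is provided since summaries sometimes report \(|FB|\)), and
RSD the population standard deviation of \(e\).

Stationarity is checked with an augmented Dickey–Fuller test under both
the constant-only ("C") and constant-plus-trend ("CT") regressions, lag
order by AIC. No unit-root package being available in this stack, the
regressions are run directly by least squares and p-values interpolated
from the standard Dickey–Fuller critical-value tables (clamped to
[0.01, 0.99]); a constant series is reported as trivially stationary.

## Prediction intervals

`naive_interval()` builds \(\hat{Y}_{T+h} \pm c\,\sigma_h\) with
\(c = 1.28\) for the nominal 80% interval under Gaussian errors
(\(2\Phi(1.28) - 1 \approx 0.80\)); \(\sigma_h\) defaults to the standard
deviation of the one-step naive errors \(x_t - x_{t-1}\). Across a 7-day
horizon \(\sigma_h\) is held constant by default — matching the constant
half-width presentation of a weekly forecast table — with the naive
method's \(\sqrt{h}\) inflation available via `inflate = TRUE`. Bounds
are rounded to integer steps for display only.

## Classification and evaluation

`stratified_split()` partitions indices per class by largest remainder,
preserving class proportions within one row in each 60/20/20 part.
Grid-search tuning scores each grid point by k-fold (k ≥ 5)
cross-validated accuracy on the training part; the gradient-boosting
default grid point is `learning_rate = 0.1, max_depth = 3,
n_estimators = 100`. No regularization terms are added. The model roster
maps to: `randomForest` (random forest; bagging via `mtry = p`), `ranger`
with the extra-trees split rule, `xgboost` (gradient boosting), a
multiclass SAMME AdaBoost over shallow `rpart` trees implemented
in-package (no boosting-by-reweighting package is available here), a
majority vote of the tree ensembles, and a most-frequent-class dummy
baseline.

Evaluation reports accuracy, one-vs-rest macro precision, recall,
specificity and F1 (macro rather than weighted: the unweighted average is
the bias-sensitive choice, consistent with preferring MCC), and the
multiclass MCC computed from the full confusion matrix
(\(\mathrm{MCC} = (cs - \sum_k p_k t_k) / \sqrt{(s^2-\sum p_k^2)(s^2-\sum
t_k^2)}\)), all on the 0–100 scale. On binary matrices this reduces to
the familiar \((TP \cdot TN - FP \cdot FN)\) form, which the tests verify
to \(10^{-12}\); a sometimes-seen variant with an extra TP factor in the
numerator and the "specificity = 1 − sensitivity" identity are treated as
errata and not implemented. Classes without test support are skipped in
macro averages with a warning.

The incremental weekly protocol (`incremental_weekly_predict()`) holds
out a participant's final 7 days: each is predicted from a model
retrained on all preceding days, with the true label appended before the
next day. A single-class history short-circuits to that class, which also
covers classifiers that cannot fit a one-class response.

## The rule base and recommendation generation

Fourteen propositional variables `A-2`…`A-17` describe a day and a week:
level indicators (`A-2`–`A-5`), the non-sedentary flag `A-6`, the daily
target flags `A-8`/`A-9` with their pace counterparts `A-10`/`A-11`, the
weekly outcome `A-17` (missed; its false edge fires `A-16`, achieved) and
the forecast advisory `A-13` (next week's forecast, levelled on steps
alone, sums below the goal). Seven activity-level rules and one
satisfiability guard are shipped; rules are evaluated as a binary
decision tree (antecedent node, True/False edges, message leaves), the
guard first — when false, the whole rule set is false and nothing fires.

Two messages are flagged "once a day" (`A-14` keep-it-up, `A-15`
move-more). The guard
`NOT (A-8 AND A-9) AND NOT (A-9 AND NOT A-6)` makes them provably
exclusive: `verify_exclusivity()` enumerates all \(2^{|V|}\) assignments
(refusing beyond 24 variables) and returns a witness assignment whenever
a guard-passing assignment fires two daily messages. The identifiers and
the per-day variable sets follow the reference worked week (a low-active
day carries {A-2, A-6, A-8, A-10, A-15}, a medium-active day
{A-4, A-6, A-9, A-11, A-14}, and so on); the concrete rule formulas and
message texts beyond the two reference weekly messages are this package's
own, and the whole knowledge base is user-replaceable YAML
(`inst/extdata/knowledge_base.yaml`).

Weekly scoring sums the seven daily scores; `difference = goal −
achieved` always. The emoji policy has no externally fixed cut-offs, so the
package fixes a documented, configurable one: deficit ≤ 0 → 😊, deficit
up to ⌈goal/3⌉ → 😐, larger → ☹. Templates are strict: an unresolved or
unknown placeholder is an error, never a silent omission.

## The knowledge graph

Participants, preferences, daily levels, step predictions and
recommendations are minted as IRIs under a single configurable namespace
(pseudonymous ids only) and linked by the object-property schema
(`hasActivityLevel`, `hasIntervalDay`, `hasReceivedRecommendation`,
`hasTimeStamp` → temporal entities, …), each property carrying a
Some/Only/Min/Exact/Max restriction. The class hierarchy is kept a
connected acyclic tree under `owl:Thing`; a cycle is a hard error.

Constraint checking is deliberately **closed-world** over the
materialized triples — the graph validates the package's *own* exports,
so the open-world semantics of description-logic reasoning (and reasoner
benchmarking) is out of scope; the logical payload kept is the
existential/universal property constraints plus the rule layer. No RDF
store is available in this R stack, so the triple store, the Turtle
serialization (round-trip tested for the emitted subset) and a SPARQL
engine covering `SELECT`/`ASK`/`CONSTRUCT` basic graph patterns with
`DISTINCT` and `ORDER BY` are implemented in the package. Persistence is
Turtle files on disk; the versioned schema ships at
`inst/extdata/schema.ttl`.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains the stages, writes every artifact with an MD5
content hash into a manifest, and is reproducible: identical configs give
identical hashes (no timestamps enter any artifact). Every stochastic
stage receives a seed derived from the master seed.

The tests and the acceptance script run at deliberately modest sizes
chosen to exercise each property well inside a desk-scale budget: 10⁵
random days for rule conformance, 50 replicates × 250 points for the
residual-correction property, 5000 draws for interval coverage, 2000 days
for the weekend-multiplier recovery, 100-point five-class toys for
balancing, and 2⁹ assignments for the exclusivity proof. Cohort-level
accuracies and error magnitudes reported for proprietary or external
wearable datasets are not reproduction targets of this package.

## Known limitations

* The personas are fixtures with known ground truth, not generative
  models of any real population; classifier scores on them are near
  ceiling by construction.
* The ADF p-values are table-interpolated (two decimal floor/ceiling at
  0.01/0.99), adequate for a stationarity gate, not for reporting precise
  p-values.
* The SPARQL engine covers basic graph patterns only (no FILTER, OPTIONAL
  or property paths); the Turtle reader targets the subset the writer
  emits.
* Rule evaluation assigns at most one "once a day" message but does not
  rank multiple feasible weekly advisories; selecting an optimal subset
  of feasible recommendations is future work.
* Age, gender and weight adjustment of the level rules is out of scope.
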