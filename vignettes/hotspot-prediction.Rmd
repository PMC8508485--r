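---
title: "Predicting persistent hotspots of preventable hospitalisations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting persistent hotspots of preventable hospitalisations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotcv)
```

## The problem

Health planners placing long-term, place-based interventions need to know
which small areas will have elevated rates of potentially preventable
hospitalisations (PPHs) *after* the intervention could take effect —
typically three years out. Rates are noisy at small-area scale and extreme
areas regress to the mean, so "where is hot today" is a poor guide to
"where will still be hot in three years". `hotspotcv` treats this as a
supervised prediction problem on an area × year × age-sex-stratum panel of
admission counts and populations.

## Hotspot classification

For area $j$, year $l$ and age-sex strata $i$ with counts $O_{ijl}$,
populations $n_{ijl}$ and standard-population weights $w_i$:

$$\mathrm{ASSR}_{jl} = \frac{\sum_i w_i\, O_{ijl}/n_{ijl}}{\sum_i w_i},
\qquad
\mathrm{Var}(\mathrm{ASSR}_{jl}) =
\frac{\sum_i w_i^2\, O_{ijl}/n_{ijl}^2}{(\sum_i w_i)^2}.$$

The all-area count $O_l$ has Poisson variance $\mathrm{Var}(O_l) = O_l$ and
Byar-approximation limits

$$O_{l,\mathrm{lower}} = O_l\Bigl(1 - \tfrac{1}{9O_l} -
\tfrac{z}{3\sqrt{O_l}}\Bigr)^3,\qquad
O_{l,\mathrm{upper}} = (O_l+1)\Bigl(1 - \tfrac{1}{9(O_l+1)} +
\tfrac{z}{3\sqrt{O_l+1}}\Bigr)^3,$$

which the tests verify agree with exact (gamma-quantile) Poisson limits to
within 1% relative error for counts from 10 to 1000. Area-level limits are
carried over by the variance ratio,
$\mathrm{ASSR}_{jl,\mathrm{lower}} = \mathrm{ASSR}_{jl} +
\sqrt{\mathrm{Var}(\mathrm{ASSR}_{jl})/\mathrm{Var}(O_l)}\,
(O_{l,\mathrm{lower}} - O_l)$, and an area is a **hotspot** in year $l$ when
its lower limit exceeds the all-area rate $\mathrm{ASSR}_l$.

Numerical conventions worth stating:

* **Sign of the upper Byar limit.** Both printed forms of the approximation
  are sometimes typeset with a minus in the upper limit; that would place
  the upper limit *below* the count. We use $-z$ in the lower and $+z$ in
  the upper limit, the only sign choice consistent with an interval, and
  validate both tails against exact Poisson limits.
* **Zero counts.** The lower-limit formula is singular at $O=0$; the limit
  is defined as 0 there, and all lower limits are clamped at 0.
* **Confidence level.** $z = 1.959964$ (two-sided 95%) by default,
  configurable; the hotspot set shrinks monotonically as $z$ grows, which
  is asserted as a property test.
* **Small strata.** Cells with population below 30 are replaced by the
  all-area totals for the same stratum and year, computed from the
  *original* panel (not iteratively). This retains each area's age-sex
  structure instead of collapsing age bands. The substitution is idempotent
  on realistic panels, which the tests assert on generated fixtures.
* Rates are kept per person-year internally; `per = 1e5` is display
  scaling only.

## Outcome, predictors and the model space

The outcome at covariate year $l$ and horizon $m$ (default 3) is "hotspot
in **all** of years $l+1,\dots,l+m$". Predictors are defined in year $l$;
some (the number of past consecutive hotspot years) summarise earlier
years. The packaged catalogue mirrors the standard candidate set for this
problem: percentage Aboriginal (signed-log transformed), percentage aged
75+ with a quadratic term, within-year-centred percentage male, rurality
(state-wide catalogue only), signed-log distance to the nearest emergency
department, two mutually exclusive GP-accessibility measures, four mutually
exclusive SEIFA index percentiles, past consecutive hotspot years, and
interactions of past-years and ED distance with each SEIFA percentile.

The signed-log transform $f(x) = x$ for $|x|\le c$ and
$f(x) = \mathrm{sign}(x)\,c\,(1+\log(|x|/c))$ otherwise (default $c=1$)
handles exact zeros in percentage covariates; strictly positive distances
get the same transform by default for uniformity (a plain `log` flag is
available — the two differ only below $c$). Percentile ranks use
$100\,(r-0.5)/n$ with mean ranks for ties; the convention is not forced by
the method, so it is stated here and frozen in tests. The
past-consecutive-years run **includes** the covariate year $l$ itself by
default (the predictor is defined *in* year $l$); `include_current =
FALSE` gives the stricter reading.

`enumerate_candidate_models()` generates every non-empty term subset of
size at most five satisfying marginality (quadratics and interactions
require their parents) and the exclusivity groups. Each term — including
the quadratic — counts as one toward the cap, and the intercept-only model
is excluded; under these conventions the state-wide catalogue yields
exactly 1,146 models and the metropolitan catalogue (rurality dropped) 726,
cross-checked in the tests against a flat power-set filter.

## Firth-penalised fitting

Persistent hotspots are rare (a few percent of areas), so candidate models
routinely separate. Every fit maximises the penalised log-likelihood
$\ell(\beta) + \tfrac12 \log\det I(\beta)$ (Jeffreys-prior penalty), which
keeps coefficients finite under complete separation. Fitting is Fisher
scoring on the modified score $X^\top(y - \pi + h(\tfrac12 - \pi))$, with
$h$ the weighted-hat-matrix diagonal, step-halving (up to 10 halvings) so
the penalised likelihood never decreases, convergence when the largest
score component falls below $10^{-6}$, and a 50-iteration cap with a
flagged (never silent) non-converged result. Standard errors come from the
inverse Fisher information and are reporting-only: selection never uses
p-values. Tests pin the intercept-only closed form
$\log\{(s+\tfrac12)/(n-s+\tfrac12)\}$, agreement with an independent BFGS
maximisation of the same objective to $10^{-6}$, and $O(1/n)$ agreement
with unpenalised ML at $n = 2000$.

## Cross-validation for longitudinal area panels

A rolling forecast window respects time ordering but spends calendar years
on iterations: with training covariates in year $l$, training outcome to
$l+m$, and the test set shifted $m$ years (outcome to $l+2m$), $C$
one-year rolls in a $T$-year series cap the training window at
$w = T - 2m - C + 1$ years (4 years for $T=10$, $m=1$, $C=5$). Predictors
that summarise past years are then truncated.

The package's main engine removes this trade-off: partition **areas** into
$K$ folds once; for each fold $k$, fit on the other $K-1$ folds at
covariate year $l$, select a classification threshold on those same
training rows, then evaluate on fold $k$'s areas with the whole layout
shifted $m$ years forward. The number of comparisons equals $K$ and costs
no calendar years, so $w = T - 2m$ (8 years for $T=10$, $m=1$). Both
widths are found by explicit feasibility scans over the layout's year
indices, not closed forms, and the scan is property-tested against a
brute-force simulation; the area-fold width exceeds the rolling width by
$C-1$ whenever both layouts are feasible.

Threshold selection scans all cut-points (midpoints of adjacent sorted
unique training probabilities plus all-positive and none-positive
sentinels; classification is $\hat p \ge$ threshold) and maximises the
objective metric among cut-points meeting the constraint. Ties prefer the
higher secondary metric (sensitivity when the objective is PPV), then the
largest cut-point — the most conservative prediction set. If the
constraint is unattainable on the training side, the cut-point maximising
the constraint metric is used. The rolling engine re-selects its threshold
every iteration by default (`reselect_threshold = FALSE` reuses the
first).

**Pooling.** With rare outcomes, per-fold sensitivity or PPV is often
undefined (no positives, or no predicted positives, in a fold). All
metrics are therefore computed from confusion counts summed over folds and
repeats; tests assert this equals computing the metric on the
concatenation of all raw per-area predictions. A zero denominator yields
an explicit `NA`, never a silent 0.

**Repeats and folds.** Fold partitioning is stratified on the outcome by
default, since a handful of positive areas would otherwise concentrate in
one fold; repeat $q$ derives its partition seed as `seed + q`, making
every stochastic result reproducible bit-for-bit. When positive areas are
scarcer than $K$, the fold count drops to the number of positives (e.g.
four-fold instead of five-fold with four positive areas).

## Calibration–implementation selection

The calibration step runs a few repeats (default 5) and re-tallies the
cached fits across a grid of minimum sensitivity thresholds
$t \in \{0, 0.1, \dots, 0.9\}$, mapping attainable pooled PPV against
$t$ — fits do not depend on $t$, so one set of fits serves the whole grid.
The minimum sensitivity $t^\*$ is intended to be chosen by the user from
this picture (an intervention's requirement); a convenience rule returning
the largest $t$ whose best attainable PPV meets a floor is provided, with
an explicit warning fallback to 0.

The implementation step runs many repeats (default 250; package examples
use 10–20 for speed) at $t^\*$ and selects the model maximising pooled PPV
among models with pooled sensitivity $\ge t^\*$. Undefined pooled PPV
ranks below any defined value; ties prefer higher pooled sensitivity, then
fewer terms, then the lowest model id, making the ranking invariant to
model-list order. Reported alongside: the ten best models with mean odds
ratios (arithmetic mean of $e^{\beta}$ over all fold-level fits containing
the term), per-repeat metric series for stability plots, 2.5%/97.5%
quantiles of the within-repeat pooled metrics (excluded-undefined counts
reported), and both the pooled point estimate and the median across
repeats, since the two summaries can differ for rare outcomes. If no model
attains $t^\*$ the result is explicitly empty, never a silent fallback.
`refit_and_forecast()` applies the selected structure to the most recent
frame to produce the forward prediction set.

## Baseline rules

`current_hotspots_rule()` predicts the areas hot at year $l$;
`past_persistent_hotspots_rule()` predicts areas hot in all of the last
`run_length` years (default 6; 10 has been used for national analyses but
exhausts persistent hotspots in smaller regions). Both are scored against
either the pipeline's persistent outcome (default, for a fair comparison)
or the single-year outcome at $l+m$; the sensitivity denominator differs
between the two readings, so both are computed and labelled. An empty
prediction set gives PPV `NA` and sensitivity 0.

## The synthetic-data generator

`generate_panel()` draws
$O_{ijl} \sim \mathrm{Poisson}\bigl(n_{ijl}\, r_i\,
e^{u_{jl} + x_j^\top\gamma}\bigr)$ with a stationary area-level AR(1)
effect $u_{j,l+1} = \rho\, u_{jl} + \varepsilon$ (marginal sd $\sigma$)
and effects $\gamma$ on z-scored covariate columns. Defaults emulate a
metropolitan-scale panel: 150 areas over 13 years; 18 five-year age bands
× 2 sexes (the stratum definition is configurable — real analyses rarely
publish theirs); area populations lognormal around 10,000; stratum rates
rising exponentially with age to an overall rate of roughly 4 admissions
per 1,000 person-years (tens of events per area-year, the regime in which
hotspot classification is informative but not trivial); $\sigma = 0.4$,
$\rho = 0.8$; and a covariate signal on a SEIFA score, the Aboriginal
percentage and ED distance. Covariates are shaped like the real candidate
set (correlated index scores sharing an SES factor, zero-inflated skewed
percentages, right-skewed strictly positive distances, pure-noise
columns), constant over time apart from per-year jitter in percentage
male.

What the generator deliberately does **not** emulate: spatial
autocorrelation between neighbouring areas, population drift over time,
coding-practice changes mid-series, and real geography. Passing tests
therefore show the estimator machinery is correct under the stated
generative model, not that the covariates carry the same signal in any
particular health system.

Two test suites use fixed non-default conditions, chosen before running
them and then frozen:

* **Structure recovery** uses a covariate-dominated regime — $\gamma =
  (-0.7, +0.7)$ on two *independent* covariates (a SEIFA score and the
  percentage aged 75+), $\sigma = 0.15$, $\rho = 0.9$ — with 62 candidate
  models, $K=5$, $Q=20$, $t^\*=0.5$, 25 replications. Independence of the
  signal pair matters: correlated signals (e.g. two deprivation-linked
  covariates) let one term substitute for the other, which is a harder and
  different estimand than structure recovery.
* **Baseline contrast** uses $\rho = 0.6$ with the default time-constant
  covariate signal over 200 replications of 100-area panels: the AR(1)
  part regresses to the mean (so current hotspots over-predict) while the
  covariate part sustains the persistent minority (so 6-year persistent
  hotspots exist at all — under a pure AR(1) at $\rho = 0.6$ they
  essentially never do).

Problem sizes throughout the tests (25 recovery replications, 200 contrast
replications, $Q \le 20$) are the package's documented desk-scale
defaults; the method itself is the same at any scale.

## Known limitations

* The hotspot definition tests each area against the all-area rate with no
  multiplicity adjustment; the area-fold CV evaluates *prediction* of that
  operational definition, not the epidemiological truth of "excess risk".
* Areas are assumed closed (no migration between areas within a year) and
  the stratum set fixed over the panel.
* Fold partitioning ignores spatial adjacency; spatially blocked variants
  are out of scope.
* Mean odds ratios are averaged over fits selected for prediction, and
  should be read as descriptions of the selected models, not causal
  effects.
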