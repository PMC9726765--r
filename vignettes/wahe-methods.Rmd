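---
title: "Methods: well-being adjusted health expectancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: well-being adjusted health expectancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wahe)
```

## The indicator

A summary measure of population health compresses a population's mortality
and morbidity into a single number of years. Life expectancy (LE) counts
every year the same; health expectancy (HE) counts only years in a
dichotomously defined "full health"; health-adjusted life expectancies grade
the years between those extremes with state-specific weights. WAHE is the
member of that family in which the weights are derived from the *subjective
well-being of the people who live in each state* — experienced utility rather
than the decision utility of outside raters — so the valuation is internal to
the surveyed population and can differ across contexts (countries, sexes)
where the consequences of ill health genuinely differ.

All expectancies here are Sullivan-method quantities in the stationary
population implied by a period life table. Writing $l_x$ for survivors at
exact age $x$, $L_a$ for person-years lived in the single-year interval
$a$, $h_{k,g(a)}$ for the prevalence of health state $k$ in the age group
containing $a$, and $\theta_k \in [0,1]$ for the state's well-being weight
($\theta_{full} = 1$):

$$WAHE_x = \frac{1}{l_x}\sum_k \sum_{a \ge x} \theta_k\, h_{k,g(a)}\, L_a.$$

Setting every $\theta = 1$ recovers $LE_x$; a $\{1, 0\}$ dichotomy recovers
$HE_x$. These identities are exact in the implementation (compensated
summation over ages in ascending order; the tests assert them to $10^{-9}$
years) and serve as its strongest internal checks, together with the bound
$HE_x \le WAHE_x \le LE_x$ whenever full health carries the largest weight.

The Sullivan prevalence-based construction assumes the cross-sectional
prevalence describes the stationary population of the life table —
adequate when health-transition rates are not changing rapidly, and the
package verifies the equivalence between Sullivan's shortcut and direct
weighted person-year bookkeeping in an exactly stationary synthetic
population.

## Health-state schemes

Health is coded from the three MEHM items, as one of four schemes:
chronic morbidity (full health = "no"), GALI activity limitation (full =
"not limited"), self-rated health (full = "excellent"), or the joint
`chronic:gali:srh` state (full = `no:not_limited:excellent`). For the joint
scheme the state space is the set of combinations actually observed in the
data, not the 2×3×5 cross-product: unobserved combinations carry no
information and would only create empty regressor cells. Missing items are
never imputed; a record missing an item is excluded listwise *for the
schemes that use that item only*, so the same respondent can contribute to
the chronic scheme while being unusable for the joint one.

Prevalence is estimated with cross-sectional survey weights within
country × sex × age group. The default age grouping — 15–29, 30–39, 40–49,
five-year groups to 79, then 80+ — mirrors official health-expectancy
practice for EU survey data, whose respondents start at age 17: ages 15–16
inherit the 15–29 group's prevalence automatically because they fall inside
it. Prevalence is treated as constant across the single years within a
group when matched to life-table ages, and the open 80+ group applies to
every life-table age from 80 upward.

## The valuation model

Per country × sex stratum, life satisfaction $Y \in \{1,\dots,10\}$ is
modelled as an ordered probit on state indicators with age controls:

$$P(Y \le j \mid x) = \Phi\!\big(\tau_j - (\textstyle\sum_{k \ne full}
\beta_k 1[state = k] + \gamma_1 c + \gamma_2 c^2)\big), \qquad
c = (age - 50)/10.$$

No state × age interaction is fitted — weights are age-constant within a
stratum — because the sparse older-age cells of several states cannot
support one; the formula's $\theta_{k}$ is therefore a stratum constant
even though prevalence is age-graded. Age is centred at 50 and scaled by a
decade purely for optimizer conditioning; reported $\gamma$ coefficients
are on that transformed scale.

Standardization to the Well-Year scale divides by the *full threshold
range* of the fitted model:

$$\theta_k = 1 + \frac{\beta_k}{\tau_{J-1} - \tau_1}.$$

The classical standardization of this family divided a chronic-condition
coefficient by the threshold distance between the outcome's extreme
categories; with a 10-point well-being outcome the natural analogue is the
distance between the first and last fitted cut-points, which maps "a latent
displacement spanning the entire outcome scale" to $\theta = 0$. The formula
is isolated in one internal function (`theta_from_beta`), so an alternative
denominator is a one-line change; the synthetic-data generator shares the
same function's inverse, keeping parameter-recovery checks well-posed under
any such change. Standardized weights are clamped to $[0,1]$ — the Sullivan
formula presumes full-health-equivalent fractions — and every clamp is
recorded in the weight table's provenance column. Standardization is
invariant to a common rescaling of the latent scale (all $\beta$ and
$\tau$ by the same positive constant), which the tests assert.

Tunable parameters and defaults:

* `min_cell = 30` observations per state dummy. Below it a stratum's weight
  for that state is replaced by the same-sex, all-country pooled estimate
  and flagged `fallback_pooled`; thirty is the conventional floor below
  which a probit cell coefficient is too noisy to report on its own.
* `weighted = FALSE`: the likelihood is unweighted. Survey weights enter
  prevalence estimation, where they correct known sampling design; for the
  within-stratum regression the design variables (country, sex, age) are
  already conditioned on. A survey-weighted pseudo-likelihood is available
  behind the flag.
* Optimizer: BFGS on the exact analytic gradient from a deterministic
  start — all slopes zero, thresholds at the standard-normal quantiles of
  the empirical cumulative outcome distribution — with thresholds
  parameterised as (first cut-point, log-increments) so their ordering is
  structurally guaranteed at every step. Convergence is declared only when
  the optimizer reports success and the fitted thresholds are strictly
  increasing; relative function tolerance $10^{-12}$. The fit is verified
  in the tests against an independent ordered-probit implementation
  (`MASS::polr`) and against a naive per-record likelihood summation.

## Validation battery

For a countries × measures matrix of SMPH values:

* **Spearman rank concordance** — Pearson correlation of mid-ranks (average
  ranks at ties), two-sided p from the t approximation on $n-2$ degrees of
  freedom; an exact permutation p is available for $n \le 10$.
  Correlations are flagged (not hidden) when $p > 0.1$, the conventional
  shading level for such displays.
* **Bland–Altman agreement** — differences $d = x - y$ (orientation
  documented in the report) against pair means. If the slope of $d$ on the
  mean is significant at $\alpha = 0.05$ two-sided, the limits of agreement
  follow the fitted trend $\pm 1.96\,SD(\text{residuals})$; otherwise the
  classical $\bar d \pm 1.96\,SD(d)$. SDs use the $n-1$ denominator.
* **Consistency ICC** — from the two-way ANOVA without interaction:
  $ICC(C,1) = (MS_{rows} - MS_{err}) / (MS_{rows} + (k-1)MS_{err})$ and
  $ICC(C,k) = (MS_{rows} - MS_{err})/MS_{rows}$, with F-based 95%
  confidence intervals. The average-measures $ICC(C,k)$ is the headline
  number — the question is the reliability of the *group* of indicators —
  but both are always reported, and they satisfy the Spearman–Brown
  relation exactly. Leave-one-out deltas recompute the ICC with each
  measure excluded, isolating indicators that lower group reliability.

A constant measure column (no between-country variation) has no defined
rank correlation; the battery reports `NA` for such pairs rather than
aborting, since degenerate columns are legitimate in synthetic runs.

## The synthetic-data generator

The generator emulates the *structure* of an EU-SILC-like cross-section:
single-year ages 17 up to an open 80+ tail, several countries, both sexes,
the three MEHM items, a 1–10 life-satisfaction item and a positive survey
weight. Its defaults were chosen once, as a plausible European adult
population, and are the study conditions of every large-sample check:

* four observed joint states from full health to severely limited poor
  health, true weights $\theta^* = (1, 0.9, 0.75, 0.5)$ — spanning the
  range typically estimated for MEHM states — with baseline shares
  $(0.35, 0.35, 0.22, 0.08)$ at age 50 and mild positive age slopes on the
  logits of the worse states;
* latent thresholds $\tau^* = \Phi^{-1}(0.01, 0.02, 0.04, 0.08, 0.15,
  0.30, 0.55, 0.80, 0.95)$, i.e. a right-skewed life-satisfaction
  distribution peaking around 7–8 as European surveys show;
  $\gamma_1 = -0.10$, $\gamma_2 = -0.05$;
* Gompertz mortality $\mu(x) = a e^{bx}$ with $(a, b) = (5\times10^{-5},
  0.095)$, giving a remaining life expectancy at 15 of about 58 years
  (verified against Simpson-rule integration of the closed-form survival);
  the life table is built by the standard single-year construction
  $L_a = l_a - d_a/2$ with open interval $L_\omega = l_\omega/\mu(\omega)$
  at $\omega = 110$.

The latent state coefficients are tied to the true weights through the
same standardization the estimator inverts,
$\beta^*_k = -(1-\theta^*_k)(\tau^*_9 - \tau^*_1)$, which is what makes
end-to-end recovery a well-posed check rather than a coincidence of scales.
Missingness, when requested, is completely at random.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: informative missingness, EU-SILC's clustered and
calibrated sampling design, measurement differences in item wording across
countries, reporting heterogeneity in self-rated health, and any state ×
age interaction in well-being. Real-data weights inherit all of those
limitations.

## Problem sizes and numerical choices

Large-sample checks use $n = 50{,}000$ respondents per stratum, the scale
at which the standardized weights are recoverable to about $\pm 0.02$; the
routine test suite uses strata of a few thousand, and the two-way panel
checks use 2,000 rows. Identity checks use $10^{-9}$ absolute tolerance
(years); oracle equivalences $10^{-10}$ or tighter; probability floors of
$10^{-300}$ guard the likelihood against underflow at extreme parameter
values. One caveat is worth stating openly: at $n = 50{,}000$ the
Monte-Carlo dispersion of the end-to-end pipeline-vs-analytic WAHE
comparison is roughly 0.1 year, dominated by the positively correlated
sampling errors of the fitted weights, so a band as tight as a twentieth of
a year on that single comparison is informative about bias but not reliably
attainable at that sample size; the per-weight recovery checks are the
sharper instrument.

## Known limitations

* Single-year life tables are required; abridged tables must be expanded
  upstream, since the Sullivan inner sum runs over single ages.
* Weights are stratum-constant (no age-varying $\theta_{k,a}$), by the
  no-interaction modelling choice above.
* The valuation requires enough well-being variation per stratum: a
  stratum with fewer than two observed life-satisfaction categories is
  rejected.
* Incidence-based alternatives (multistate life tables, Markov chains with
  rewards) are out of scope; under non-stationarity they can diverge from
  the prevalence-based values computed here.
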