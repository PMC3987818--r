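---
title: "Small-area estimation of county smoking prevalence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area estimation of county smoking prevalence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokesae)
```

County-level cigarette smoking prevalence cannot be read directly off a
state-run telephone survey: most counties contribute a handful of
interviews per year, county identifiers are unevenly available, and the
sampling frame itself changed when cell phones entered it. `smokesae`
implements the full model-based pipeline for this problem — a hierarchical
logistic prevalence model with spatial and temporal pooling,
post-stratification and direct age standardization, simulation-based
uncertainty, a linear-ramp correction for the wireless-only coverage bias
of the pre-2011 landline frame, and a sample-down validation framework —
together with a synthetic survey generator whose known ground truth makes
every stage testable.

This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic experiments do and do not
demonstrate about real survey data.

## Outcome definitions

Respondents report whether they have smoked at least 100 cigarettes in
their life and, if so, whether they now smoke every day, some days, or not
at all. `classify_smoking()` maps each valid pattern to nonsmoker /
nondaily / daily and derives two binary outcomes: *current total smoking*
(nondaily or daily) and *current daily smoking*. Inconsistent patterns are
rejected at intake by `validate_microdata()`; "don't know"/refused
responses are treated as missing upstream, so the package only ever sees
complete records. Daily prevalence never exceeds total prevalence at the
microdata level by construction; the separately *fitted* models do not
guarantee the same for estimates, which is why an optional draw-wise cap
(`cap_daily_at_total()`) exists — off by default, since we prefer
reporting what each model says.

## The prevalence model

For each sex and outcome, `sae_fit()` fits a logistic mixed-effects
regression to individual survey responses. For respondent $i$ in county
$c(i)$ nested in state $s(i)$, interviewed in calendar year $t_i$:

$$
\operatorname{logit}\Pr(y_i = 1) =
  \mathbf{x}_i^\top\boldsymbol\beta
  + u^{(0)}_{s(i)} + v^{(0)}_{c(i)}
  + \tilde t_i\,\bigl(u^{(1)}_{s(i)} + v^{(1)}_{c(i)}\bigr),
$$

where $\mathbf{x}_i$ holds the demographic fixed effects (six age groups,
race, marital status, education), a linear term in centered year
$\tilde t_i = t_i - 2004$, and — in the combined-frame variant — phone-usage
category; $u$ and $v$ are state and county-within-state random intercepts
and year slopes,

$$
u^{(k)}_s \sim N(0, \sigma^2_{u,k}), \qquad
v^{(k)}_c \sim N(0, \sigma^2_{v,k}), \qquad k \in \{0, 1\}.
$$

Design choices worth making explicit:

* **Spatial smoothing is hierarchical, not adjacency-based.** Counties
  borrow strength through their state and through the national fixed
  effects; no neighborhood graph is used. A county with no data at all is
  predicted from its state effect and its demographic composition — the
  model's pooling contract, tested explicitly.
* **Temporal smoothing is a linear logit trend with random slopes.**
  Centering the year near the window midpoint (2004) decorrelates
  intercepts and slopes. Random slopes are *uncorrelated* with random
  intercepts (`lme4`'s `||` construction): the correlation is weakly
  identified at these sample sizes and the uncorrelated form is faster and
  more stable. `random_slopes = FALSE` drops the slope terms, which is
  adequate for short fitting windows (the combined-frame model sees only
  two years).
* **Fitting is unweighted.** Design weights do not enter the likelihood;
  composition is handled by covariates and post-stratification. Weights
  are used only for the gold-standard direct estimates, where they belong.
* **Aggregation.** Individual rows are collapsed to binomial counts per
  county × year × demographic cell before fitting — sufficient statistics
  for this model, identical estimates, much faster.
* **Optimization.** The default (`method = "agq0"`) maximizes the joint
  penalized deviance (`glmer` with `nAGQ = 0`); `"laplace"` uses the full
  Laplace approximation. On aggregated binomial data the two agree to well
  within estimation error in our experiments, and the default is about 3x
  faster. Convergence controls (`maxit`, `tol`) are exposed in
  `sae_spec()`; hitting the cap returns `converged = FALSE` with
  diagnostics rather than an error. A constant outcome or a singular
  fixed-effect design is an error naming the offending terms.

## From cell probabilities to published numbers

`predict()` evaluates the inverse-logit linear predictor on every
demographic cell of every county-year. `poststratify()` collapses cells to
age-group prevalence using the county's census cell shares, and
`age_standardize()` takes the fixed-weight average over age groups. The
standard population ships as the US 2000 census adult age distribution
over the six bins (`std_pop_us2000()`, overridable), so estimates are
comparable across counties and years despite different age structures.

### Uncertainty: joint posterior draws

Uncertainty intervals are percentile intervals of simulation draws pushed
through the entire pipeline (standardization, bias correction, trends,
ranks) — *draw-wise*, never summarize-then-transform.

The draws themselves come from the Laplace-approximate **joint** posterior
of the fixed effects and random effects. This matters: the estimation
errors of $\boldsymbol\beta$ and of the conditional modes of $u, v$ are
strongly negatively correlated, and drawing them independently from their
marginal variances overstates the uncertainty of a county prediction — in
our calibration experiments the resulting 95% intervals covered the truth
99.8% of the time, nearly twice as wide as they should be. `sae_fit()`
therefore stores the Cholesky factor of the joint precision

$$
\begin{pmatrix}
X^\top W X & X^\top W Z \\
Z^\top W X & Z^\top W Z + G^{-1}
\end{pmatrix}
$$

evaluated at the fitted values ($W$ the binomial IRLS weights, $G$ the
random-effect covariance), and `simulate()` draws jointly from it.
Counties or states absent from the data draw independently from the
estimated prior, which is exact under the model. With this construction,
measured coverage of the true standardized county prevalence is 95.2% at
nominal 95% (width-to-error ratio ≈ 1.0 across years). Remaining
approximations: variance components are treated as known at their
estimates, and the binomial curvature is evaluated at the modes; both are
standard and small at these sizes. Default draw count is 1000 for
reporting; intervals are the 2.5th/97.5th percentiles.

## Wireless-only frame bias and the ramp correction

Before 2011 the survey frame was landline-only, and wireless-only adults —
a group that grew from essentially zero around 2000 to roughly a third of
adults by 2012, and that smokes more than demographically similar
reachable adults — could not be sampled. Two mechanisms transmit this into
bias: composition (wireless-only adults differ in age, marital status,
education) and a direct residual difference. Covariates and
post-stratification absorb the first; the second requires the two-model
correction:

* **Model A** (landline frame): fit to landline and dual-use respondents,
  all years.
* **Model B** (combined frame): fit to all respondents in 2011-2012, with
  phone-usage category as a fixed effect, post-stratified over a year ×
  age phone-composition table.

`measure_bias()` takes the 2011 overlap difference B − A per county (in
percentage points, draw-wise), and `correct_series()` composes the final
series: model A unchanged through 2000, model A plus the bias scaled by
the linear ramp $(t - 2000)/11$ for 2001-2010, model B from 2011. The
ramp anchors — zero in 2000, the full measured bias in 2011 — follow the
observed wireless-only growth trajectory. Corrections are applied to the
draws, so corrected intervals carry the bias-measurement uncertainty, and
results are clamped to $[0, 100]$.

**Smoothing the bias across counties.** The per-county overlap difference
mixes the real coverage bias with the sampling noise of a model fitted to
two years of data; at realistic county sample sizes that noise (~2 pp) can
rival the bias itself (~1.5 pp), and applying it raw can make the
corrected series *worse*. `measure_bias(smooth = "eb")` — the default
inside `run_pipeline()` — shrinks each county's bias toward the
cross-county mean with an empirical-Bayes factor: the measurement variance
comes from that county's bias draws, the between-county signal variance is
the method-of-moments excess of the observed spread over the average
measurement noise, and the shrinkage is applied draw-wise. When counties
genuinely differ the estimated signal variance keeps the differences; when
they do not, the correction collapses toward the common bias and its
noise contribution almost vanishes. In the recovery experiments below the
smoothed correction reduced the 2001-2010 RMSE against truth on every
realization tried, while the raw correction did not.

## Validation by sampling down

`run_validation()` implements the gold-standard framework used to choose
among candidate models. Counties with at least 900 pooled respondents over
2006-2010 form the validation set; their design-weighted, age-standardized
direct estimates are the gold standard. The microdata are then thinned to
10, 50, and 100 respondents per county-year (simple random sampling
without replacement; pools smaller than the target are kept whole), each
candidate model is refit on each thinned replicate, and its predictions —
averaged over the window — are scored against the gold standard with Lin's
concordance correlation coefficient

$$
\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}
$$

(population moments; penalizes location shifts as well as dispersion,
and never exceeds the Pearson correlation in magnitude) and with RMSE in
percentage points. The selected model maximizes mean CCC with mean RMSE
as the tie-breaker; an `in_sample` row scores each model on the full
data. Fit failures are recorded in the report, not fatal. On synthetic
data the metrics reproduce the expected qualitative structure — CCC
rising and RMSE falling monotonically from 10 to 50 to 100 to in-sample,
and a model stripped of demographic covariates scoring strictly worse
than the generating specification.

## The synthetic study generator

`truth_params()`, `build_registry()`, `true_prevalence_surface()` and
`sample_respondents()` generate a complete survey study from a known
truth: county-clustered respondents within states over 1996-2012 annual
waves, demographic covariates correlated with both smoking and phone
usage, a landline-only frame before 2011 (wireless-only respondents
unsampleable, design weights equal to inverse inclusion probabilities)
and a combined frame from 2011, and daily/nondaily/nonsmoker responses
drawn from the logistic truth with a conditional daily-given-total model
(so daily ≤ total holds in truth by construction).

Default parameters are calibrated once to the published study conditions
and then frozen:

| Parameter | Default | Rationale |
|---|---|---|
| reference-cell intercept | logit(0.32) | male standardized prevalence ≈ 28.6% in 1996 |
| year slope | −0.025 logit/yr | net median county decline ≈ −0.93%/yr *after* phone-composition growth partially offsets it |
| education effects | 0 / −0.35 / −0.90 | strong gradient, the main composition signal |
| wireless-only logit shift | +0.25 | median 2011 frame bias ≈ 1.3-1.6 pp at ~31% wireless share |
| daily conditional slope | −0.035/yr | daily prevalence declines ≈ 1 pp/yr faster than total |
| state / county intercept SD | 0.22 / 0.18 | between-area spread comparable to published county ranges |
| state / county slope SD | 0.012 / 0.008 | some counties flat, some declining > 3%/yr |
| wireless share | 0 until 2000, linear to 34% in 2012, tilted toward young adults | observed wireless-only growth |
| respondents per county-year | Poisson(50) | very uneven county samples; counties above and below the 900-respondent validation threshold |

An income-linked component of the county random effects (−0.10 logit per
SD of log income on levels, −0.004 on slopes) makes richer counties smoke
less and decline faster, so the income-quintile analytics have a real
gradient to find.

Two deliberate simplifications: design weights are simple inverse
inclusion probabilities, not a re-creation of survey raking; and the
phone-usage composition is a national year × age table rather than
county-specific. Passing tests on this generator therefore demonstrate
that the *estimators* recover a truth of the assumed structure — they do
not certify behavior under real-survey features the generator omits
(raking, within-county phone-composition differences, item nonresponse,
self-report bias).

## Experimental design of the checks

The test suite runs three seeded experiments, sized to finish in a few
minutes on one CPU:

* **Parameter recovery and calibration** — 20 states × 10 counties,
  ~120 respondents per county-year (≥1,000 per county), frame effects and
  income links switched off so the generative model coincides exactly with
  the fitted family. All fixed effects must land within 3 standard errors
  of truth for ≥90% of coefficients, and 95% intervals must cover the true
  standardized county prevalence between 90% and 99% of the time across
  200 counties × 3 years.
* **Bias-correction recovery** — 120 counties at full defaults (frame
  exclusion active), ~150 respondents per county-year. The smoothed
  ramp-corrected 2001-2010 series must beat the uncorrected series on
  RMSE against truth; ramp endpoints are checked exactly.
* **Validation structure** — 30 counties, 2006-2010, ~500 respondents per
  county-year so every county clears the 900-respondent threshold; 5
  thinning replicates per size. Mean CCC must be nondecreasing and mean
  RMSE nonincreasing across 10 → 50 → 100 → in-sample, and the
  no-covariate model must score strictly worse than the generating one.

Trend analytics are checked against worked arithmetic (the geometric
annualized rate $100\,[(p_{end}/p_{start})^{1/(y_{end}-y_{start})} - 1]$
reproduces the published national endpoint declines; within-state gaps
reproduce published county pairs) and against construction (rank
intervals from per-draw re-ranking, significance as the 95% rate-draw
interval excluding zero, with no multiple-testing adjustment — matching
the published usage).

## Numerical and degenerate-input choices

* Income quintile cut points are the 20/40/60/80 sample percentiles of
  1996 county income; ties take the lower quintile, making assignment
  deterministic and order-invariant (all-equal incomes collapse to
  quintile 1).
* `sample_down()` keeps whole pools smaller than the target size.
* Gold-standard age groups with no respondents inherit the county's
  overall weighted prevalence (rare at the 900-respondent threshold).
* Rank intervals are widened, if necessary, to contain the point rank;
  point ranks break ties by first occurrence.
* The joint-precision Cholesky adds a 1e-8 relative ridge only if the
  factorization fails; variance components below 1e-6 are treated as
  pinned at zero (precision 1e8) so their draws are effectively exact
  zeros.
* CCC is undefined when both vectors are constant — an error, not a
  value.
* Geometric annualization requires positive endpoints; zero or negative
  prevalence is an error rather than a silent NaN.

## Known limitations

* The hierarchical pooling has no adjacency structure; two neighboring
  counties in different states share only national information.
* Variance-component uncertainty is not propagated into the draws;
  coverage is measured slightly below nominal at small state counts.
* The combined-frame model, fitted to two years, is the noisiest stage;
  the empirical-Bayes bias smoothing manages but does not eliminate this.
* The linear bias ramp is an assumption, not an estimate — only its
  endpoints are data-driven, and nothing in the 2001-2010 data can test
  linearity in between.
* Separately fitted total and daily models can produce daily > total for
  individual counties unless the optional cap is enabled.
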