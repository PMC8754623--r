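---
title: "Decomposing change in child underweight between surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing change in child underweight between surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(nutridecomp)
```

## The question the package answers

Repeated cross-sectional household surveys — the Demographic and Health
Survey (DHS) series is the canonical example — show child underweight
prevalence falling over a decade. Two very different mechanisms can produce
the same headline decline: the *composition* of the population can improve
(more educated mothers, wealthier households, more institutional
deliveries), or the *relationship* between those characteristics and
underweight can change (the same kind of household now produces
better-nourished children). A nonlinear Blinder–Oaxaca ("multivariate")
decomposition separates the two, and allocates each part across individual
covariates. nutridecomp implements that analysis end to end for
child-level survey records: outcome classification, survey-weighted
logistic regression, the decomposition with detailed contributions and
delta-method uncertainty, stratified trend tables, and a synthetic-data
generator with exact population ground truth for validation.

## Outcome definition

A child is *underweight* when the weight-for-age Z-score (WAZ) is below
−2 SD of the reference-population median, and *severely underweight* below
−3 SD. `classify_waz()` applies both cut-offs; the binary modelling outcome
is `waz < -2`, so "severe" implies underweight. The boundaries are strict:
a child at exactly −2.0 SD is classified as normal. Survey reports phrase
the definition as "below minus two standard deviations", which pins the
open interval; ties at the boundary are vanishingly rare in continuous
anthropometry, but the convention is fixed and tested so results cannot
drift with implementation detail.

Missing-data handling is complete-case per model: rows missing the
outcome, the sampling weight, or any modelled covariate are dropped and
counted (`survey_dataset()$n_dropped`, echoed in the pipeline run log).
Trend tables and the decomposition for a survey pair are computed on the
same filtered rows, so the accounting identity between them (below) is
exactly testable.

## Estimation

Each survey's outcome model is a logistic regression estimated by
maximising the probability-weighted log-likelihood

$$\ell(\beta) = \sum_i w_i \left[ y_i \log p_i + (1 - y_i)\log(1 - p_i)
\right], \qquad p_i = \operatorname{logit}^{-1}(x_i^\top \beta),$$

with $w_i$ the sampling weight ("pweights": inverse selection probability
adjusted for nonresponse). `fit_wlogit()` uses Newton–Raphson with
step-halving (at most 10 halvings per step), starting from the logit of
the weighted prevalence with zero slopes, and declares convergence when
the largest weighted score component falls below 1e-8 (at most 100
iterations). The default covariance is the sandwich
$H^{-1}\left(\sum_i w_i^2 s_i s_i^\top\right) H^{-1}$; a model-based
$H^{-1}$ and a cluster-robust variant (scores summed within cluster) are
options. Two properties worth knowing:

* rescaling all weights by a positive constant changes neither the
  coefficients nor the sandwich covariance (no finite-population factor is
  applied);
* integer weights reproduce the fit obtained by replicating rows.

Separation (a coefficient passing ±30 on the logit scale while the
likelihood still improves) and collinearity (singular weighted Hessian)
are hard errors, not warnings; penalised likelihood is out of scope. The
estimator is cross-checked in the test suite against `glm` and against a
generic BFGS maximisation of the same likelihood.

## The decomposition

Let $B$ be the baseline (earlier) survey and $A$ the comparison (later)
survey, $\bar F_S(\beta)$ the weighted mean of
$\operatorname{logit}^{-1}(x^\top\beta)$ over survey $S$'s rows. The
change in prevalence splits as

$$\underbrace{\bar F_A(\beta_A) - \bar F_B(\beta_A)}_{E\ \text{(endowments)}}
\;+\;
\underbrace{\bar F_B(\beta_A) - \bar F_B(\beta_B)}_{C\ \text{(coefficients)}}
\;=\; \bar F_A(\beta_A) - \bar F_B(\beta_B).$$

$E$ is the part explained by compositional change, evaluated at the later
survey's coefficients; $C$ is the part due to changed covariate effects
(including the intercept), evaluated at the baseline composition. Because
each fitted model carries an intercept, $\bar F_S(\hat\beta_S)$ equals the
weighted observed prevalence (the intercept score equation), so the total
equals the raw prevalence difference — this "path identity" is asserted to
1e-8 in the tests.

Two deliberate scale/reference choices:

* **Probability scale.** Although the decomposition is often written in
  logit notation, components here are differences of weighted mean
  *probabilities*. Only on that scale do the totals add up to the observed
  percentage-point drop in prevalence, which is how published
  decomposition tables in this literature present them (and how the
  widely-used Stata implementation behaves).
* **Counterfactual reference.** $E$ at $\beta_A$, $C$ at $X_B$ — the
  standard asymmetric weighting. Reversing the roles of the surveys
  negates the total but does not map $(E, C)$ onto $(-E, -C)$; only the
  total's antisymmetry is a theorem, and only it is asserted.

### Detailed contributions

Per-category contributions use first-order linearisation shares:

$$E_k = E \cdot \frac{(\bar x^A_k - \bar x^B_k)\,\beta_{A,k}}
{(\bar x^A - \bar x^B)^\top \beta_A}, \qquad
C_k = C \cdot \frac{\bar x^B_k\,(\beta_{A,k} - \beta_{B,k})}
{\bar x^{B\top}(\beta_A - \beta_B)},$$

with $\bar x$ the weighted column means including the intercept column
(the intercept has equal means in both surveys, so it contributes to $C$
only — the "Constant" row of a report table). The shares sum to one by
construction, so detail rows recombine exactly to $E$ and $C$. If a
linearisation denominator is ~0 (below 1e-12) while its component is not
(above 1e-10), the allocation is degenerate and the package raises an
error rather than reporting arbitrary splits; when the *total* itself is
~0, absolute contributions are still reported but percentage shares are
undefined (`NA`).

### Reference-category normalisation

Raw dummy-coded detail rows depend on which category was chosen as each
variable's baseline. Before computing detail, the package therefore
re-expresses every categorical variable in deviation-from-mean form: the
within-variable effects (reference = 0) are centred on their unweighted
mean over all $L$ categories, the removed means are absorbed into the
intercept, and the design is expanded to one indicator column per
category. The linear predictor of every observation is unchanged (checked
to 1e-12), and every category — including the former reference — gets a
row whose value is invariant to the original baseline choice (checked to
1e-8 over all reference permutations of a three-variable schema).
Normalisation is ON by default for reports; `normalize = FALSE` is
available for debugging and for textbook examples keyed to a specific
baseline.

### Uncertainty

Standard errors are delta-method: the gradient of each quantity with
respect to the stacked coefficient vector $(\beta_A, \beta_B)$ is combined
with the block-diagonal covariance of the two independent fits,
$\mathrm{SE} = \sqrt{g^\top V g}$. Gradients of $E$ and $C$ are analytic;
gradients of the detail terms use central finite differences with step
1e-6 (cross-checked against the analytic totals in the tests). Intervals
are normal: estimate ± 1.959964·SE at the default 95% level.

**Known limitation.** This variance treats the realised covariate
composition (the $\bar x$'s, and more generally the empirical
distribution of $X$ and $w$) as fixed and propagates only coefficient
uncertainty — the convention of the established decomposition software.
A nonparametric bootstrap that resamples whole records also varies the
composition. In the package's own bootstrap check (500 replicates at
5 000 records per survey on the bundled scenario) the delta-method SE for
$C$ matches the bootstrap closely, while the SE for $E$ — a composition
contrast — runs on the order of 10–20% below it. Where composition
uncertainty matters, bootstrap the full pipeline rather than relying on
the reported $E$ interval.

## Trend tables

`trend_table()` reports weighted prevalence (percent) per subgroup and
survey plus phase differences, later minus earlier, for each requested
pair (declines are negative; consecutive pairs plus the full span by
default). Phase differences are exactly additive: Phase I + Phase II =
Phase III at full precision. The overall prevalence recombines from any
stratifier's rows with stratum weight shares (asserted to 1e-10), and the
decomposition total for a pair equals that pair's overall trend difference
on the same complete-case rows.

## The synthetic generator and what it does (not) emulate

No public microdata ship with the package; `generator_config()` defines
seeded synthetic surveys that make every downstream stage testable:

* covariates are drawn *independently across variables* from per-survey
  category probabilities — deliberately, so `ground_truth()` can compute
  the exact population $E$ and $C$ by enumerating the full category space
  (capped at 1e6 cells) rather than by Monte Carlo;
* the outcome follows each survey's logistic model, either directly
  (`binary-direct`) or through a latent Z-score
  $\mathrm{waz} = \mu(x) + \mathcal N(0, \sigma)$ with
  $\mu(x) = -2 - \sigma\,\Phi^{-1}(\operatorname{logit}^{-1}(x^\top\beta))$,
  which makes $P(\mathrm{waz} < -2 \mid x)$ exactly the logistic model and
  exercises the classification path;
* weights are log-normal (meanlog 0, sdlog 0.5 by default), drawn
  independently of covariates and outcome, so weighted and unweighted
  population targets coincide and weight-invariance properties are
  testable.

The bundled scenario (`default_generator_config()`) has three surveys
labelled 2005/2011/2016 over six covariates, with composition shifts
patterned on the Ethiopian DHS series (maternal education "None" falling
0.79 → 0.655, wealth "Poor" rising 0.49 → 0.54, institutional delivery
rising 5% → 27%), different coefficient vectors in 2005 and 2016 (2011
midway), and intercepts calibrated by enumeration so the expected weighted
prevalences are exactly 38%, 29% and 24% — the published trend anchors for
that setting. The default sample size, 8 000 children per survey, matches
the order of a DHS child file.

What the generator does **not** emulate: the two-stage cluster sample (no
strata or enumeration-area labels, so the cluster-robust covariance is
exercised only on synthetic cluster labels in tests), correlation between
covariates, informative weights, and item missingness. Passing tests on
this generator therefore validate the estimators and the decomposition
algebra, not robustness to design effects or covariate dependence in real
DHS data.

```{r ground-truth}
cfg <- default_generator_config(seed = 1, n_per_survey = 2000)
ground_truth(cfg, "2005", "2016")
```

## Problem sizes used in validation

The shipped test suite runs, among smaller cases: the additivity and
path-identity suite on 100 random two-survey configs of 500 records each;
parameter recovery against enumerated ground truth at 50 000 records per
survey over 20 seeds (each estimate within 3 delta-method SEs of truth in
at least 18); and the bootstrap variance comparison at 5 000 records per
survey with 500 replicates. These sizes give Monte-Carlo error comfortably
below the tolerances being asserted while keeping a full run in the tens
of seconds on a single core.

## Numerical choices, collected

| Quantity | Value |
|---|---|
| Newton score tolerance / max iterations | 1e-8 / 100 |
| Step halvings per Newton step | ≤ 10 |
| Separation threshold | abs(beta) > 30, likelihood improving |
| Detail-term FD step | 1e-6 (central) |
| Degenerate-allocation guard | denominator < 1e-12 with component > 1e-10 |
| Percentage shares undefined | abs(total) ≤ 1e-10 |
| Enumeration cap | 1e6 cells |
| CI quantile | 1.959964 (95%) |
| WAZ boundaries | strict: underweight iff waz < −2; severe iff waz < −3 |

Report tables round estimates to 5 decimals and percentage shares to 2–3
in the print methods; CSV and JSON outputs keep full precision.

## Limitations

* Two-survey decomposition only; a third survey enters trend tables, not
  the decomposition (no sequential three-way split).
* No interaction ("three-fold") decomposition separating intercept shifts
  from slope shifts.
* Probability weights only; no strata/linearisation beyond the optional
  cluster-robust covariance.
* The $E$ interval understates composition uncertainty (see above).
* WAZ is taken as supplied; the package does not re-derive Z-scores from
  raw weight/age/sex via growth-standard LMS tables.
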