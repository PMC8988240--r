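---
title: "Abridging a nutritional empowerment index: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abridging a nutritional empowerment index: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weni)
```

## The problem

Comprehensive empowerment indices are expensive to field.  The Women's
Empowerment in Nutrition Index (WENI) aggregates 33 binary indicators
spanning seven domain-dimensions (DDs) — the domains food, health and
institutions crossed with the dimensions knowledge, resources and agency,
with institutions kept undivided — and classifies a respondent as
nutritionally empowered when her composite score reaches 0.5.  Its
abridgement, A-WENI, keeps 20 of the 33 indicators chosen so that the
shorter index reproduces the full index's scores and status while still
representing at least half of the themes in every DD.

This package implements that entire workflow as reusable, testable
machinery: schema handling, the scoring engine, a penalized-regression
(lasso) engine with three penalty-selection families and exact-cardinality
subset search, the abbreviation pipeline with its theme-coverage constraint,
a validation battery, and a synthetic multi-site survey generator so every
stage can be exercised without access to the original (undeposited) surveys.

## The scoring model

Each indicator is binary, 1 meaning empowered on that item.  For respondent
$i$ and domain-dimension $d$ the DD score is the headcount ratio

$$s_{id} = \frac{\#\{j \in d : x_{ij} = 1\}}{\#\{j \in d\ \text{observed}\}},$$

the composite is the unweighted mean over the DDs present in the schema,
and status is $\mathbf{1}\{\text{composite} \ge \tau\}$ with $\tau = 0.5$
(inclusive: a score of exactly 0.5 is empowered).  On complete data the
composite is exactly linear in the indicators with weights
$w_j = 1/(D\, n_{d(j)})$; `linear_weights()` exposes this and the equality
is tested to $10^{-12}$.

Missing indicators are handled by one of two policies: `"renormalize"`
(default) drops the missing item from its DD denominator — our reading of
the guidance that missing items "need to be dropped from the analysis" — and
`"complete"` drops the respondent.  A respondent with an entire DD missing
cannot be renormalized and is excluded with a logged count.  DD-level
empowerment (used by `dd_comparison()`) applies the same cutoff to the DD
score; the source material never defines this, so the choice is recorded in
the output's `threshold` attribute.

## The penalized regression engine

Abbreviation regresses the full-schema composite score $y_i$ on all $p$
indicators with an L1 penalty:

$$\hat\beta(\lambda) = \arg\min_\beta\;
  \frac{1}{n}\sum_i \left(y_i - \beta_0 - x_i'\beta\right)^2
  + \frac{\lambda}{n}\sum_j \varphi_j\,|\beta_j|.$$

Solver choices:

* **Cyclic coordinate descent with soft-thresholding**, tolerance $10^{-8}$
  on the maximum coefficient change, at most 10,000 sweeps
  (non-convergence is an error carrying the last objective and sweep
  count).  Correctness is audited three ways: KKT residuals stored on every
  fit, a brute-force grid minimizer at $n=6, p=2$, and glmnet as an
  independent oracle.
* **Standardization**: predictors are centred and scaled to unit population
  variance (binary indicators have unequal variances); the intercept is
  unpenalized; coefficients are reported on the original scale; loadings
  $\varphi_j$ default to 1.
* **Parametrization**: under the objective above the smallest all-zero
  penalty is $\lambda_{\text{null}} = 2\max_j |\tilde x_j'y|/\varphi_j$.
  This is the lassopack-style convention; glmnet's
  $\tfrac{1}{2n}$-convention relates by
  $\lambda_{\text{here}} = 2n\,\lambda_{\text{glmnet}}$, which the test
  suite uses when cross-checking.  The path grid is 100 log-spaced points
  from $\lambda_{\text{null}}$ down to $10^{-4}\lambda_{\text{null}}$
  (configurable), its top nudged infinitesimally above the threshold so the
  first fit is the empty model even under floating-point rounding.

Penalty selection (`select_lambda()`):

* **Cross-validation** (`"cv"`): plain $k$-fold (default 10), respondent-level
  random assignment from a stated seed, mean held-out squared error,
  $\lambda$ at the minimum — no one-standard-error rule.
* **Information criteria** (`"aic"`, `"aicc"`, `"bic"`, `"ebic"`): computed
  along the path with $\mathrm{df}$ = active-set size and
  $\mathrm{AIC} = n\log(\mathrm{RSS}/n) + 2\,\mathrm{df}$, AICC adding
  $2\,\mathrm{df}(\mathrm{df}+1)/(n-\mathrm{df}-1)$, BIC using
  $\mathrm{df}\log n$, and EBIC adding $2\xi\,\mathrm{df}\log p$ with
  $\xi = 0.5$.  The RSS entering the criteria comes from a least-squares
  refit on each active set.  This is a deliberate numerical choice: with
  the penalized RSS the criteria conflate support quality with shrinkage
  bias and demonstrably over-select when the noise is small (a planted
  3-of-10 support at $\sigma = 0.01$, $n = 2000$ is then missed); with the
  refit RSS the planted support is recovered exactly, which the tests
  assert.
* **Rigorous plug-in** (`"rigorous"`): no grid search;
  $\lambda = 2c\,\hat\sigma\sqrt{n}\,\Phi^{-1}(1 - \gamma/2p)$ with
  $c = 1.1$, $\gamma = 0.1/\log(\max(p, n))$, heteroskedasticity-aware
  loadings $\varphi_j = \sqrt{\overline{\tilde x_j^2 \hat\varepsilon^2}}/\hat\sigma$,
  and $\hat\sigma$ iterated from residuals (at most 15 iterations).  All
  constants are configurable and echoed in results.

**Exact-cardinality selection** (`exact_k_select()`) searches the path for
a support of exactly $k$: grid first, then up to 60 log-scale bisection
steps between the two grid points where the support size jumps past $k$.
If the path simply never visits size $k$, the smallest support above $k$
is taken and its weakest standardized coefficients are dropped, ties broken
by schema order; this fallback is deterministic and announced.  The binary
status can replace the score as the response (`response = "status"`)
through the same linear machinery (a linear probability fit, not a
logistic variant), mirroring the robustness variant in the source design.

## The abbreviation pipeline

`run_abbreviation()` trains on a named set of sites and validates on the
complement.  Every approach is tuned to exactly $k$ indicators and audited
with the in-sample (training) and out-of-sample (validation) RMSE of its
penalized linear predictor; a post-selection OLS refit RMSE is reported
alongside, clearly labelled, because the source tables are silent on which
of the two they print (the refit values resemble them more closely in our
synthetic world).  Theme coverage of each subset is computed against the
full schema; the chosen subset minimizes out-of-sample RMSE among
approaches that pass the 50% coverage rule, with ties broken in favour of
cross-validation and then by schema order.  When nothing passes, the report
carries an explicit failure flag instead of a subset.

The abbreviated index itself is *not* the lasso predictor: following the
source methodology, A-WENI-style scores re-apply the headcount scoring to
the retained indicators (DD denominators shrink to the retained counts).

`sensitivity_sweep()` re-runs the pipeline over a grid of thresholds
(0.05 steps), subset sizes ($k \in \{10, 15, 20, 25\}$ style sweeps), or
alternative training-site partitions, reporting for site swaps the
symmetric difference against the baseline subset.

## Validation battery

* `kendall_tau()`: Kendall score $S$, tau-a, tie-corrected tau-b, the null
  standard error of $S$ with the standard tie terms, and a two-sided
  continuity-corrected normal p-value.  Tie counts use exact numeric
  equality (a subtlety: `table()`-based counting rounds values through
  their character representation and can disagree with the pairwise signs,
  pushing |tau-b| above 1 on scores that differ by one ulp).
* `roc_auc()`: Mann-Whitney concordance probability with ties counting one
  half, Hanley-McNeil standard error, bounds $\pm 1.96\,\mathrm{SE}$
  clipped to $[0,1]$.
* `outcome_regression()`: OLS for BMI and log BMI with HC1 robust errors;
  probit with a score-based sandwich covariance for normal-BMI and minimum
  dietary diversity (MDD).  BMI-family models are fit on the subsample with
  BMI < 25 — the overweight/obese exclusion — and pregnant respondents are
  excluded there, while pregnancy enters the MDD model as a control (the
  source states physiological status is controlled without giving the
  mechanism; this is our documented mechanism).  MDD is food-group count
  $\ge 5$ of 10, the MDD-W convention, configurable.  Reference levels of
  factor controls are reported explicitly rather than matched to unknown
  omitted categories.
* `group_tests()`: Welch two-sample means test and pooled two-sample
  proportion $z$ test per demographic group and pooled; one-class strata
  are flagged, not fatal.
* `dd_comparison()`: per-DD percent empowered under the full and
  abbreviated index side by side.

## The synthetic world

`generate_survey()` draws a latent empowerment factor
$\theta_i \sim N(\mu_{\text{site}}, 1)$, one shared perturbation per DD per
respondent $u_{id} \sim N(0, 0.5)$ on the logit scale, and indicators
$x_{ij} \sim \text{Bernoulli}(\text{logit}^{-1}(a_j + b_j\theta_i + u_{id(j)}))$.
BMI is $20 + 0.8\cdot\mathbf{1}\{\text{composite} \ge 0.5\} +$ group
effects $+ N(0, 2^2)$; the food-group count is
$\text{Binomial}(10, \text{logit}^{-1}(-0.2 + 0.5\,\theta_i))$.  Defaults
were fixed once:

* **Sites**: five sites of (486, 485, 476, 476, 475) respondents — total
  2398 with a 971/1427 train/validation split when training on the first
  two — with latent shifts $(-0.45, -0.45, +0.25, +0.25, +0.25)$, so the
  training-like sites are genuinely less empowered than the validation
  sites.
* **Difficulties** $a_j$: an even spread over $[-1.1, 0.9]$, calibrated
  once so that overall empowerment prevalence is about 45% at the 0.5
  cutoff (observed 45.3% at $n = 5000$); the target is recorded in the
  configuration.
* **Discriminations** $b_j$: a fixed 7-value cycle
  $(1.5, 0.7, 1.1, 1.6, 0.8, 1.3, 0.6)$.  Heterogeneous discriminations
  matter qualitatively: with homogeneous slopes every indicator is an
  exchangeable proxy of $\theta$, and since food-resources indicators carry
  the smallest composite weights ($1/56$ each), an unconstrained
  exact-20 selection then drops that entire block — unlike the surveyed
  world, where even unconstrained selections spanned all DDs.  The cycle
  length being coprime to the DD block sizes puts strong and weak items in
  every DD.
* **BMI truncation**: none at generation; the BMI < 25 analysis restriction
  is what creates the analysed subsample.  Because that restriction
  truncates on the outcome, the truncated-regression estimand is a mildly
  attenuated version of the configured effect (about 0.73 versus 0.8); the
  replicate-coverage test therefore checks interval coverage of the
  estimand (a large-sample pseudo-truth), while single-run recovery of the
  configured 0.8 within a robust 95% interval is tested directly.

What a green test does **not** establish: the generator makes no attempt to
reproduce the real surveys' joint indicator distributions, regional
composition, anthropometric measurement error, or the particular 20
indicators of the published abridgement — the packaged `aweni20` fixture is
the published list, while abbreviation runs on synthetic data legitimately
select different subsets of the same size and coverage behaviour.

## Worked example

```{r pipeline}
full <- weni_schema("weni33")
survey <- generate_survey(default_config(seed = 101))
scores <- compute_scores(survey, full)
prevalence(scores)

report <- run_abbreviation(survey, full, k = 20,
                           train_sites = c("site1", "site2"),
                           approaches = c("cv", "bic", "rigorous"),
                           config = lasso_config(cv_folds = 5))
report

abbrev <- new_schema(full$indicators[
  full$indicators$name %in% report$chosen$names, ])
ab_scores <- compute_scores(survey, abbrev)
kendall_tau(scores$composite, ab_scores$composite)
roc_auc(ab_scores$composite, scores$status)
```

```{r regression}
status <- scores$status[match(survey$respondent_id, scores$respondent_id)]
outcome_regression(survey, status, "bmi")
```

## Known limitations

* The lasso engine is dense and single-threaded; it is built for
  survey-scale problems (hundreds to thousands of rows, tens of
  indicators), not genomic scale.
* Kendall's tau is computed by an $O(n^2)$ pairwise pass — exact and
  auditable, adequate to tens of thousands of observations, slow beyond.
* The probit sandwich uses the expected-information bread from the fitted
  model; with heavy misspecification it differs from an observed-Hessian
  sandwich in finite samples.
* Conversion of raw questionnaire answers into binary indicators is out of
  scope: inputs are assumed already binarized.
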