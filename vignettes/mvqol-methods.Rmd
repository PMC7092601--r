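---
title: "Joint growth-curve modelling of WHOQOL-HIV domain scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint growth-curve modelling of WHOQOL-HIV domain scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Longitudinal HIV cohorts typically record quality of life with the
WHOQOL-HIV BREF instrument at every clinic visit. Four domain scores —
physical health (`ph`), psychological (`psy`), level of independence
(`ind`) and social relationships (`soc`) — are each the mean of a
domain's 5-point Likert items multiplied by 4, so every score lives on
the 4–20 scale of the longer WHOQOL-100. The four trajectories of one
woman are not independent: pain and fatigue move with depression and
anxiety, and a subject who starts low on one domain tends to change
differently on the others. Fitting four separate linear mixed models
ignores exactly this, biasing standard errors and making it impossible
to ask whether a covariate acts differently on different domains.

`mvqol` fits the four growth curves **jointly**. For outcome
$k = 1,\dots,4$, subject $j$ and visit time $t$ (months since
enrolment),

$$y_{kjt} = \mathbf{x}'_{tj}\,\boldsymbol\beta_k + u_{kj} + v_{kj}\,t + e_{kjt},$$

where the eight subject effects (four random intercepts $u_{kj}$, four
random time slopes $v_{kj}$) are drawn from a single
$\mathrm{MVN}(0, \Omega_G)$ with $\Omega_G$ an unstructured
$8\times 8$ covariance, and the four occasion residuals
$(e_{1jt},\dots,e_{4jt})$ from $\mathrm{MVN}(0, \Omega_R)$ with
$\Omega_R$ unstructured $4\times 4$, independent across visits. The
*independent-outcome* restriction zeroes every cross-outcome covariance
($\Omega_G$ block-diagonal in four $2\times2$ intercept/slope blocks,
$\Omega_R$ diagonal) and is exactly equivalent to four separate
univariate linear mixed models — the package verifies this equivalence
against `lme4` in its test suite.

## Estimation

Stacking a subject's outcomes visit-major (all four outcomes of visit
1, then visit 2, …) gives the marginal law
$Y_j \sim \mathrm{MVN}(X_j\beta,\; V_j)$ with
$V_j = Z_j \Omega_G Z_j' + I_{n_j} \otimes \Omega_R$. The fit maximises
the marginal likelihood (ML by default, so deviances and AICs are
directly comparable across the related and independent variants; REML
is available via `mvml_spec(estimation = "REML")`):

* **Log-Cholesky parameterisation.** Each covariance is represented by
  its lower Cholesky factor with log-transformed diagonal, so any real
  parameter vector decodes to a positive-definite matrix and the
  optimisation is unconstrained — 46 covariance parameters for the
  related model, 16 for the independent restriction.
* **Profiling.** At each candidate covariance, $\beta$ is solved by
  GLS, so the optimiser only searches the covariance space. Subjects
  sharing a visit schedule share one Cholesky factorisation of $V_j$
  (the kernel is compiled C++), and the exact gradient of the profiled
  deviance is available in closed form via
  $\partial(-2\ell)/\partial V_j = V_j^{-1} - w_j w_j'$,
  $w_j = V_j^{-1}(y_j - X_j\hat\beta)$ — the GLS $\hat\beta$
  contributes nothing by the envelope theorem.
* **Warm starts.** The related fit starts from the independent fit
  (itself started from per-outcome least-squares moments), mirroring
  the usual independent-then-joint workflow and stabilising the
  46-parameter search.
* **Numerical safeguards.** A Cholesky failure triggers a diagonal
  jitter of `1e-8` times the mean diagonal, escalating tenfold at most
  three times; a still-indefinite point evaluates to a large finite
  deviance so BFGS can retreat. Cholesky log-diagonals are clamped at
  $\pm 20$ against line-search overflow. Convergence is declared when
  BFGS meets its relative-change criterion (`reltol = 1e-10`) and the
  exact gradient max-norm is small relative to the deviance scale
  (`grad_tol = 0.05` per unit deviance); on optimiser failure one
  restart from a deterministically perturbed point is attempted and
  the best fit is returned flagged rather than erroring.

Wald inference for $\beta$ uses the normal reference (the study-scale
datasets have thousands of visits, where a degrees-of-freedom
correction is immaterial); no multiple-testing correction is applied
by default, matching common practice for these effect tables.

## Downstream summaries

* `random_effect_correlations()` rescales $\hat\Omega_G$ to the
  baseline/slope correlation matrix; zero-variance components are
  reported as `NA` rows rather than propagating `NaN`.
* `fit_statistics()` / `compare_models()` compute $-2\ell$, AIC,
  AICC and BIC with the mixed-model conventions `AICC` using the
  number of *visits* and `BIC` the number of *subjects* — the pair of
  conventions under which published multivariate multilevel fit tables
  are internally consistent (the test suite checks this arithmetic on
  printed values: 238 parameters, 219 subjects, ≈8,700 visits).
  The related-vs-independent comparison has 30 degrees of freedom (24
  cross-outcome constraints in $\Omega_G$, 6 in $\Omega_R$).
* `contrast_effects()` tests $\beta_{a,\text{term}} -
  \beta_{b,\text{term}}$ across outcomes with the joint fixed-effect
  covariance — the question separate univariate fits cannot answer.
* `transformed_residuals()` returns $L_j^{-1}(y_j - X_j\hat\beta)$
  (lower Cholesky of $\hat V_j$), approximately i.i.d. standard normal
  under a correct model, with matched normal quantiles for Q-Q checks.
* `predict_blups()` returns the empirical Bayes subject effects
  $\hat\Omega_G Z_j' \hat V_j^{-1}(y_j - X_j\hat\beta)$.

## Clinical-panel compression

Routine laboratory panels carry two dozen correlated variables.
`fit_factor_model()` standardises each variable group (white blood
cell, red blood cell, blood chemistry, protein — factored separately),
extracts factors from the correlation matrix by maximum likelihood
(`stats::factanal`; an iterative principal-axis fallback handles
non-convergence, and a PCA mode is provided because eigenvalue-based
retention is often described in principal-component language), retains
factors with eigenvalues strictly above 1 (Kaiser; a floor of one
factor with a warning), applies raw varimax rotation with a
sign-and-order convention, labels loadings (strong $>0.6$, moderate in
the closed interval $[0.4, 0.6]$, weak $<0.4$, on absolute values —
published tables bold negative loadings such as $-0.592$), and scores
observations by the regression (Thomson) method, with Bartlett as an
option. Scores are standardised against the fitting sample, so they
have mean zero there by construction.

## The synthetic cohort generator

The study data behind this model class (an acute-HIV-infection cohort
of 219 women followed from seroconversion through cART in
KwaZulu-Natal) is not public, so the package ships a generator that
emulates its structure and makes every stage testable:

* **Visit schedule.** Weekly visits to month 3, monthly to month 12,
  quarterly thereafter to month 69 (41 scheduled visits); a subject
  completes the schedule with probability 0.95, otherwise follow-up
  truncates uniformly, giving a mean of ≈40 visits and a minimum of 2.
* **Covariates.** Categorical frequencies mirror the published
  enrolment table (e.g. 174/219 stable partners, 18/219 TB
  co-infected — the table's printed 9.2% for TB is inconsistent with
  its own counts, so counts are used); age is drawn to match a median
  near 25 with reference group ≤20; weight and log viral load vary
  between visits around subject baselines, since they enter the model
  as time-varying covariates.
* **Random effects.** $\Omega_G$ defaults to the published 8×8
  correlation pattern. As printed, that matrix is slightly indefinite
  (minimum eigenvalue $-0.026$), so the generator uses the nearest
  positive semi-definite correlation matrix (maximum entrywise change
  0.0094; the anchor entries 0.94 and 0.90 become 0.944 and 0.909).
  Variances are not published. Score points run 4–20 and time is in
  months, so unit slope variances would drive trajectories far out of
  range within a year; the defaults are intercept SD 1.5 points and
  slope SD 0.05 points/month, with unit residual variances and 0.3
  cross-domain residual correlation — values that keep simulated
  scores on-scale over six years of follow-up.
* **Likert emission.** Item counts default to the instrument's
  (4, 5, 4, 4); items are chosen so that with zero emission noise
  re-scoring returns the nearest attainable score, then perturbed with
  Gaussian noise (SD 0.5) before rounding and clipping to 1..5.
  Latent scores are clamped to the 4–20 instrument range before
  emission (floor/ceiling effects, as in the real instrument).
* **Clinical panel.** $x = \Lambda f + \varepsilon$ per visit with the
  published block loading matrix and uniquenesses
  $1 - \text{communality}$, so columns have unit variance.
* **Reproducibility.** Each subject draws from a sub-stream derived
  from the master seed and the subject id, so a cohort can be extended
  without perturbing existing subjects; the same configuration and
  seed reproduce a cohort byte-for-byte.

What the generator does **not** emulate: informative dropout,
measurement-occasion irregularity beyond schedule truncation,
covariate–random-effect dependence, ordinal floor/ceiling beyond
simple clamping, and any genuine causal structure. Passing tests
therefore demonstrate that the estimator recovers the model it states,
not that the model is correct for any particular real cohort.

## Validation scale and design choices

The test suite exercises the estimator at sizes chosen to finish in
minutes while leaving the statistical checks well powered: likelihood
values are verified to `1e-8` against a dense brute-force Gaussian
density on tiny instances; nesting ($-2\ell_{\text{related}} \le
-2\ell_{\text{independent}}$) on 20 simulated datasets of 100 subjects
× 6 visits; correlation and fixed-effect recovery on 20 replicates of
219-like scale (200 subjects × 10 visits, slope SD raised to 0.15 so
slope correlations are identifiable over an 18-month window); AIC
model selection on the same scale with strongly correlated versus
zero cross-covariance truths; Kaiser/varimax structure recovery on 50
panels of 2,000 observations (the assignment check excludes the one
variable whose generating loadings are nearly tied, 0.360 vs 0.341,
where "its" factor is not well defined); and contrast type-I error on
200 null replicates of 100 subjects × 5 visits, a scale at which the
normal-reference Wald test is close to nominal.

Open choices resolved here: maximum likelihood extraction is the
default for the factor stage (the stated method) even though retention
is computed on correlation-matrix eigenvalues as in PCA-style
descriptions — both extractions are available; factor scores use the
regression method (no method is conventionally reported); the
completeness filter runs before the minimum-visit filter, since
dropping incomplete visits can push a subject below two visits; a
domain is scorable when at least 80% of its items are present (common
WHOQOL practice, configurable); and the moderate-loading interval is
closed at both 0.4 and 0.6.

## Limitations

The estimator assumes complete four-outcome visits (incomplete visits
are filtered, not modelled); missingness is treated as ignorable after
filtering. Likelihood evaluation factorises by visit schedule, so
cohorts where every subject has a unique schedule lose that sharing
(they still fit, one Cholesky per subject). The normal-reference Wald
tests are asymptotic; for very small cohorts a parametric bootstrap
would be preferable. Satterthwaite/Kenward-Roger degrees of freedom
and oblique factor rotations are out of scope.
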