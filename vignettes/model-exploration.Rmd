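---
title: "Exhaustive exploration of linear mixed-effects models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive exploration of linear mixed-effects models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlmexplore)
```

## The model family

`mlmexplore` works with Gaussian linear mixed-effects models for
observations nested in groups (participants in countries, students in
schools):

$$y_{ig} = x_{ig}^\top \beta + z_{ig}^\top b_g + \varepsilon_{ig}, \qquad
  b_g \sim N(0, \Psi), \quad \varepsilon_{ig} \sim N(0, \sigma^2),$$

with fixed effects $\beta$ shared across groups, group-specific deviations
$b_g$ (a random intercept and optionally random slopes, jointly Gaussian
with unstructured covariance $\Psi$), and independent residual noise. The
marginal likelihood of group $g$ after integrating out $b_g$ is Gaussian
with covariance $V_g = Z_g \Psi Z_g^\top + \sigma^2 I$, and the model
log-likelihood is the sum of the per-group terms
$-\tfrac12\{n_g\log 2\pi + \log|V_g| + r_g^\top V_g^{-1} r_g\}$.

Assumptions worth keeping in view: responses are continuous and
conditionally Gaussian; random effects enter through a *single* grouping
factor (no crossed or nested designs); all terms are additive — interaction
and transformation terms are rejected at parse time rather than silently
accepted.

## The candidate space

A full model is declared by four ingredients: the free fixed effects the
search may drop, the forced covariates every candidate keeps (typically a
demographics block), the grouping factor, and the subset of free fixed
effects eligible as random slopes. Admissibility imposes two structural
rules, stated as hard constraints:

* a random slope requires its fixed effect in the same model — a
  group-varying effect with a zero population mean is rarely the hypothesis
  of interest, and allowing it would double-count structures;
* a random slope requires a random intercept — slope-only random parts
  force every group's regression line through a common intercept, an
  artifact rather than a plausible data-generating process.

Forced covariates are never slope candidates. Under these rules each of the
$s$ slope candidates is in one of three states (absent, fixed-only,
fixed-plus-slope) and each of the remaining $f - s$ free predictors in one
of two, giving $2^f + 2^{f-s}3^s$ candidates with a grouping factor
(`countCandidates()`), verified in the tests against a brute-force
enumeration that filters all raw subset pairs.

Candidates are emitted in a fixed stratified order — all fixed-effects-only
models, then all random-intercept models, then the random-slope models —
with subsets ordered by increasing size and ties by declaration order, and
in the slope stratum the fixed subset varying slowest. Within-stratum order
beyond "smaller first" is a documented convention of this package; it is
chosen once so that result files and golden tests are byte-stable.

Because the space grows exponentially, `enumerateCandidates()` refuses past
a ceiling (default 10,000 candidates) unless explicitly overridden; at that
size users should force in more covariates or drop slope candidates rather
than brute-force the space.

## Fitting and scoring

All candidates are fit by **maximum likelihood**, not REML: REML
log-likelihoods are not comparable across models with different fixed
effects, which is precisely the comparison an exploration makes. A `reml`
flag exists for completeness and warns when used for ranking.

Fixed-effects-only candidates are fit by OLS (the ML solution), with
$\hat\sigma^2 = \mathrm{RSS}/N$ and the closed-form log-likelihood.
Mixed candidates are fit with `lme4::lmer(REML = FALSE)`, which profiles
$\beta$ and $\sigma^2$ out of the deviance and optimizes over the Cholesky
factor of the relative covariance $\Psi/\sigma^2$; the test suite
cross-checks the resulting maxima against an independent direct
maximization of the marginal likelihood written from the formula above.
A fit whose relative-covariance factor has a diagonal entry below $10^{-4}$
is flagged `singular` (a variance component estimated at the boundary);
boundary fits are legitimate maxima and are kept, flagged, in the table.
Non-convergence is likewise flag-and-keep: a sweep is exploratory by
design, and one pathological candidate should not abort the other
thousands. Such rows carry missing criteria and sort last.

The criteria are the standard Akaike and Schwarz forms
$\mathrm{AIC} = -2LL + 2k$ and $\mathrm{BIC} = -2LL + k\ln N$, with $N$ the
number of observations (not the number of groups) and

$$k = p + q(q+1)/2 + 1,$$

i.e. fixed coefficients after categorical expansion (treatment coding,
reference = first sorted level; a categorical term counts as one term for
enumeration but `levels - 1` coefficients here), the free elements of the
$q \times q$ random-effect covariance, and the residual variance. This is
the usual mixed-model likelihood degrees-of-freedom convention (it matches
`logLik()` on an ML `lmer` fit exactly, which the tests assert); "number of
parameters" is genuinely convention-dependent in mixed models, so the
choice is documented rather than configurable.

**Missing data.** Rows with missingness in *any* variable of the full model
are dropped once, before exploration, so every candidate is fit to
identical observations. Criteria computed on different row sets are not
comparable; per-candidate deletion would silently reward models that omit
the gappiest predictors.

## From BIC to Bayes factors

The ranking can be restated as evidence: under unit-information priors,
$\ln \mathrm{BF}(A\,\mathrm{vs}\,B) \approx (\mathrm{BIC}_B -
\mathrm{BIC}_A)/2$ (`approxLogBFfromBIC()`), so BIC order and approximate
Bayes-factor order are the same monotone ranking. Differences are reported
on the conventional $2\log\mathrm{BF}$ scale with Kass–Raftery bands
(below 2 weak, 2–6 positive, 6–10 strong, above 10 very strong;
`interpret2LogBF()` uses the magnitude, the sign gives the direction).
The approximation is a screening device: it assumes a unit prior that a
careful analysis might not accept, and a fully Bayesian comparison with
problem-specific priors (e.g. bridge sampling over posterior draws) remains
the confirmatory step for the handful of nominated models. That
computation is hours-scale and prior-dependent and is deliberately outside
this package's scope.

## The synthetic-data generator

`simSpec()`/`simulateDataset()` draw data exactly from the model family
above: per-group effects $b_g \sim N(0, \Psi)$ (via an eigendecomposition,
so positive *semi*-definite $\Psi$, including exact zeros, is supported),
standard-normal predictors by default (mirroring the common practice of
standardizing survey scales), optional categorical predictors, Gaussian
noise, all deterministic given a seed. `studyShapedSpec()` provides three
ready shapes mirroring published multi-country survey designs with 2, 4
and 7 free predictors (6, 2 and 3 forced covariates; 43, 43 and 62
countries), whose candidate spaces are 13, 97 and 2315 models. Their group
sizes default to 100 rows per group so a full test run takes minutes; the
studies' real sample sizes (~15–20k participants) are carried only as
metadata.

What the generator does **not** emulate: bounded Likert-type item scales
(responses are unbounded Gaussians), empirical predictor correlations,
unbalanced group sizes, or structured missingness. A green recovery test
therefore establishes that the machinery identifies a true model under its
own assumptions at realistic effect sizes — not that any particular field
dataset satisfies those assumptions.

Default generative values used by the recovery simulations were fixed up
front: 40 groups of 100 observations, unit residual SD, unit
random-intercept SD, random-slope SD equal to the residual SD (the boundary
of the "strong slope" regime, taken at equality), slope–intercept
correlation 0.3, fixed effects of 1 for true predictors, 0.5 for the
forced covariate and 0 for noise predictors. Under that world the best-BIC
nomination recovers the generating model and its approximate Bayes factor
beats the full model's in at least 18 of 20 seeded replicates (asserted in
the acceptance tests).

## Numerical and interface choices

* Determinism: exploration partitions work by candidate index and
  reassembles in enumeration order, so results are identical for any
  worker count (asserted to $10^{-10}$; in practice bitwise). Workers use
  fork-based parallelism and fall back to serial on platforms without it.
* Ties in ranking break by fewer parameters, then by formula string —
  favouring the simpler model, and making sorts reproducible.
* Result CSVs print criteria with six decimals (byte-stable golden files);
  a JSON sidecar records the run metadata (N after deletion, group and
  candidate counts, workers, elapsed time, version).
* Elapsed time is recorded but never tested: it is hardware-bound.
* The CLI (`exec/mlmexplore`) exits 0 on success, 2 on usage or
  specification errors, 3 on data errors; flat `key: value` config files
  supply defaults that command-line flags override.

## Known limitations

Single grouping factor; Gaussian responses only; no interactions; no AICc
or other small-sample corrections; the Schwarz approximation inherits its
unit-prior assumption; and exhaustive search is exponential — the ceiling
guard is a feature, not a bug.
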