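---
title: "Twin models for longitudinal wellbeing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin models for longitudinal wellbeing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinpanel)
```

## The scientific problem

Adolescent wellbeing, measured here on the 1-10 Cantril ladder across
three questionnaire waves roughly two years apart, is moderately stable.
Twin data let us ask *why*: monozygotic (MZ) co-twins share all of their
segregating genes, dizygotic (DZ) co-twins on average half, so the
contrast between MZ and DZ similarity separates additive genetic
variance (A) from shared-environmental (C) and nonshared-environmental
(E) variance, the last of which also absorbs measurement error. The
package implements the two model families needed for this analysis and
for the companion question of whether counted life events (negative
dependent, negative independent, positive dependent clusters) predict
subsequent change in wellbeing:

1. a **trivariate Cholesky decomposition** of the three wellbeing waves
   into A, C, E (or A, E) components, giving per-wave standardized
   shares (heritability $a^2_w$, etc.);
2. a **genetically informative random-intercept cross-lagged panel
   model (RI-CLPM)** for wellbeing and one life-event cluster, in which
   both the stable between-person random intercepts and the
   wave-specific within-person factors are decomposed into biometric
   components, and within-person deviations are linked across waves by
   autoregressive and cross-lagged paths.

Because the source cohort's raw data are access-restricted, everything
is exercised against a synthetic twin-pair generator whose defaults
reproduce the cohort's structure (sample sizes, the seven
wave-participation patterns, the published generating estimates).

## The estimation engine

Both model families are expressed as a `SourceLoadingModel`: per twin,
component loading matrices $\Lambda_A(\theta), \Lambda_C(\theta),
\Lambda_E(\theta)$ map independent standard-normal sources to the
observed vector, plus a mean map $\mu(\theta)$ shared by co-twins and
zygosity groups (standard twin-model practice). The pair-level implied
covariance is built from the biometric sharing rules: within-twin
$\Sigma_W = \sum_k \Lambda_k \Lambda_k^\top$, cross-twin $\Sigma_X =
\bar r \Lambda_A \Lambda_A^\top + \Lambda_C \Lambda_C^\top$ with $\bar r
= 1$ (MZ) and $0.5$ (DZ). The DZ genetic correlation is realized by
*source splitting* — each twin's genetic source is $\sqrt{\bar r}\,z_c +
\sqrt{1-\bar r}\,z_t$ with independent standard-normal pieces — which
reproduces the cross-twin covariance $\bar r\,\Lambda_A\Lambda_A^\top$
exactly while keeping every source independent and standard normal.
This construction makes the implied covariance positive semi-definite
for *every* admissible parameter vector, so the optimizer never needs a
positivity repair step.

**Likelihood.** Raw-data (full-information) maximum likelihood: each
pair-row contributes the multivariate-normal $-2\log$ density of its
observed sub-vector; rows with nothing observed are dropped. Rows are
grouped by missingness pattern and reduced to count, mean, and ML
scatter per pattern, which is algebraically identical to row-by-row
evaluation (a unit test holds the two paths to within $10^{-8}$) and
makes an objective evaluation essentially independent of the sample
size. Under missing-completely-at-random participation (what the
generator implements) FIML point estimates are unbiased.

**Optimization.** Bounded quasi-Newton (PORT, `nlminb`) on raw path
coefficients — not variances — so that off-diagonal paths may be
negative while implied variance components stay non-negative by
construction. Cholesky diagonal entries are bounded at zero, which
resolves the sign indeterminacy of the parameterization without
restricting the implied covariance. Defaults: five starts (the
data-driven heuristic plus four jittered copies, jitter scale 0.2 of
each start value), convergence tolerance $10^{-8}$ on the relative
objective change, and a relative gradient-norm check at the optimum
that warns at $10^{-4}\times\max(1, |-2\ln L|)$ for interior solutions.
Start heuristic: sample variance split equally over the included
components (per-component path $\sqrt{v/k}$), zero off-diagonals and
lagged paths at 0.2/0; means at sample means. Replicated recovery runs
use a single start for throughput — with complete simulated data and
the variance-splitting start the objective has not shown multimodality
in any converged replicate.

**Uncertainty.** Standard errors come from the inverse numerical
Hessian of $\tfrac12(-2\ln L)$ (central differences); a non-PD Hessian
flags them unreliable. Standardized quantities (variance shares,
standardized paths) get delta-method intervals by numerically
differentiating the standardization map; `profileCI()` offers
profile-likelihood intervals (bisection on the $\chi^2_1$ boundary,
3.84 at 95%) as the likelihood-based alternative, and the two agree
within 20% in our checks at moderate sample sizes. Published twin
tables do not always state which convention produced their brackets, so
both are exposed and Fisher-z is the default for plain twin
correlations.

**Fit statistics.** The saturated reference model frees per-group means
and covariances (closed form at the ML sample moments for complete
data; numerically optimized over a Cholesky parameterization
otherwise); the independence model (free means, diagonal covariance)
factorizes per variable, so its FIML optimum is closed-form under any
missingness pattern. CFI, TLI, RMSEA and AIC follow the usual
likelihood-ratio definitions; for RMSEA we adopt the multi-group
convention with the number of groups $G$ under the root,
$\sqrt{G\,\max(T-df,0)/(df\,(N-G))}$ — other software differs by
$\sqrt G$, so the convention is recorded in the output metadata.
Likelihood-ratio tests clamp negative $\Delta\chi^2$ at zero and warn,
since a better-fitting nested model indicates an optimizer failure.

## The Cholesky decomposition

Three waves of one phenotype, lower-triangular $3\times3$ path matrices
per component: AE has $6+6+3=15$ free parameters, ACE $21$. Shares are
$a^2_w = (aa^\top)_{ww}/\Sigma_{ww}$ and sum to one per wave exactly.
AE-vs-ACE selection is by AIC with ties going to the simpler AE model.
For an AE model the implied twin correlations obey $r_{MZ,w} = a^2_w$
and $r_{DZ,w} = a^2_w/2$, an algebraic identity the tests use as an
internal consistency check.

## The genetic RI-CLPM

Per twin the observed 6-vector (wellbeing and one event cluster at
three waves) is $\mu + RI + w$ with unit loadings throughout, so the
implied observed variance is exactly $var(RI) + var(w_w)$. The
within-person recursion is $w_1 = s_1$, $w_2 = T_1 s_1 + s_2$,
$w_3 = T_2 T_1 s_1 + T_2 s_2 + s_3$: transmission is *phenotypic* — the
lagged matrix acts on the total within-person factors, while the new
wave-specific sources $s_w$ (and the intercepts) are decomposed into
components through $2\times2$ lower-Cholesky blocks per component.
Design choices where the specification was genuinely open:

* **Innovation blocks free per wave** (not equated across waves), and
  **lagged paths free per transition**, matching wave-specific reported
  estimates; an equated variant can be expressed through the constraint
  mechanism.
* **Cross-trait covariance at component level**: each $2\times2$ block
  carries an off-diagonal, so traits may covary through A and through E
  separately. When one trait excludes a component (wellbeing and
  negative dependent events are AE; negative independent events add C
  on the event side only), that block degenerates to a single variance
  touching the other trait, with no cross path — four extra parameters,
  $38 \to 42$.
* **Continuous treatment** of the 1-10 ladder and the event counts (no
  threshold model), matching the linear treatment in the source
  analyses.
* Identification at three waves is checked empirically: the recovery
  harness requires a non-degenerate Hessian at the generating values
  (the delta-method SEs in the coverage check would otherwise fail).

Standardized paths are raw paths scaled by the ratio of model-implied
within-person factor SDs, $std(\gamma_{xy}) = \gamma_{xy}
SD(y_w)/SD(x_{w+1})$.

Nested tests (`testLaggedPaths()`) refit with named paths fixed at
zero, warm-started from the full solution, and compare by
likelihood-ratio $\chi^2$.

## The synthetic generator and its defaults

`simulatePairs()` draws sources per the loading model (deterministic
given a seed); `applyMissingness()` assigns each twin one of the seven
participation patterns $\{123, 12, 13, 23, 1, 2, 3\}$ with weights
defaulting to the published counts (1132, 613, 179, 78, 710, 97, 70 of
2,879 twins), blanking non-participating waves — an MCAR mechanism by
construction. `discretizeTwinData()` optionally maps continuous scores
onto the instrument scales (affine rescale, round half-up, clamp);
round-half-up is used, not banker's rounding, because the tie behaviour
matters for the attenuation checks. Recovery runs keep discretization
off by default so estimator bias is isolated from coarsening bias; a
realism preset turns it on together with the participation weights.

Generating truths are fixed once from the published estimates:

* **Cholesky** (`choleskyTruth()`): $a^2 = (0.48, 0.46, 0.26)$, the
  remainder E. Cross-wave correlation structure is not published, so we
  chose genetic correlations $(0.8, 0.8, 0.7)$ and environmental
  $(0.25, 0.25, 0.15)$ between waves — values implying phenotypic
  adjacent-wave stability near 0.5, the level reported for adolescent
  wellbeing. Latent scale: total variance 1, mean 0 per wave.
* **RI-CLPM** (`riclpmTruth()`): wellbeing intercept shares 40/40/36%
  by wave with an 81/19 A/E split; standardized lagged paths set to the
  published standardized estimates (cross-lags $-0.11$, $-0.08$,
  $-0.02$, $-0.10$ for the negative dependent cluster). Quantities no
  table determines were fixed once at field-plausible values: event-side
  intercept variance 0.35 with a 60/40 A/E split (negative dependent
  events are reported ~50% heritable), within-person wellbeing A share
  0.26 (so total wave-1 heritability is ~0.48 after adding the
  intercept's contribution), event-side within A share 0.45,
  autoregressive standardized paths 0.25 (wellbeing) and 0.30 (events),
  cross-trait correlations $-0.3$ (intercepts) and $-0.2$
  (within-person), with cross-covariances split across components
  proportionally to the geometric mean of the component shares. The
  negative independent variant uses the reported ACE split (~0.2/0.4/0.4
  on the event side), weaker cross-lags, lower stability. All of these
  are *generating* conditions, not estimates; the recovery studies then
  refit the model and compare.

The construction is exact by algebra: `riVarianceShares()` and
`standardizePaths()` applied to the generating parameters reproduce the
target shares and paths to machine precision, which the tests assert.

## What the simulations do and do not show

The generator emulates the covariance structure, sample composition and
participation mix the models assume — multivariate-normal sources,
linear phenotypes, MCAR missingness. Real data differ in ways the
recovery studies deliberately do not capture: bounded ordinal scales
(the discretization preset probes the resulting attenuation, which is
mild), skewed event counts, possibly informative dropout, age
heterogeneity within waves (the age-residualization tool addresses the
analysis side of this), and gene-environment correlation or
interaction. Passing recovery therefore shows the estimator is correct
and essentially unbiased *under the stated conditions*; it does not
validate the substantive assumptions against a real cohort.

## Problem sizes used in testing

Recovery studies run at the study scale: 550 MZ + 890 DZ pairs
(matching the cohort's 1,094 MZ and 1,785 DZ twins) for the RI-CLPM
with 50 replicates, and 1,000 MZ + 1,500 DZ pairs for the Cholesky
recovery. Calibration-style checks use smaller per-replicate samples
with more replicates (200 for the likelihood-ratio type-I rate, 100 for
CI coverage at 300 + 450 pairs), and the large Monte-Carlo
moment-agreement checks use 20,000-100,000 pairs. These sizes were
chosen so each check's Monte-Carlo error is small relative to the
tolerance it asserts.

## Event-category screening

The screening step mirrors the pre-modelling decision to drop the
positive dependent cluster: a category enters the twin models only if
at least one same-wave correlation with wellbeing is both
non-negligible (|r| > 0.10 by default) and significant at the 0.05
level. We require magnitude *and* significance jointly: a significant
but negligible correlation — routine at thousands of observations — is
not evidence worth a model term, and a large but non-significant one is
not established. Phenotypic p-values treat twins as individuals without
a family-clustering correction; they are anti-conservative and the
report flags them as descriptive. Twin correlations are single-entry
Pearson by default with a double-entry option (exactly swap-invariant);
confidence intervals are Fisher-z by default.

## Known limitations

Ordinal/threshold liability models, sex-limitation, moderation by
definition variables, non-MCAR dropout and Bayesian estimation are out
of scope. The saturated reference model under heavy missingness is
numerically optimized over ~90 parameters per group and is the slowest
path in the package; fit indices on complete simulated data use its
closed form. RMSEA's multi-group convention differs across software by
$\sqrt G$; comparisons across packages should check the recorded
convention first.
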