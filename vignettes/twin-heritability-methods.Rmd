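---
title: "Methods: variance-component twin models for serum biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variance-component twin models for serum biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinherit)
```

## The biometric model

`twinherit` implements the classical MZ/DZ twin decomposition of a
quantitative phenotype's variance, `V = A + D + C + E`. Each intact pair is
an independent draw from a bivariate normal with common member variance `V`
and within-pair covariance `A + C + D` (MZ) or `0.5 A + C + 0.25 D` (DZ):
MZ co-twins share all their genes, DZ co-twins on average half of the
additive effects and a quarter of the dominance interactions. The DZ
dominance coefficient of 0.25 is the standard biometrical-genetics value
and is fixed, not estimated. Shared environment C and dominance D are never
free together — with only two group covariances the ACDE model is not
identified — which leaves the five admissible models ACE, ADE, AE, CE, E.

The standard simplifying constraints apply throughout: equal means and
variances across co-twin 1/2 and across zygosity groups. Covariates (age in
years, a male indicator) enter the mean of the joint likelihood in one
stage, `mu_i = beta0 + beta_age * (age_i - mean age) + beta_sex * I(male)`;
we deliberately avoid pre-residualization, which leaks degrees of freedom
and changes what "adjusted ICC / adjusted heritability" means. Broad-sense
heritability is `h2 = (A + D) / V`.

### Assumptions worth stating

* Equal environments: the shared-environment variance is assumed the same
  for MZ and DZ pairs.
* Same-sex pairs only; no opposite-sex DZ pairs, no sex-limitation models,
  and no zygosity-specific variances in this version.
* Phenotypes are modelled as (conditionally) Gaussian. Right-skewed
  analytes violate this; the sensitivity machinery (below) quantifies how
  much that matters for the variance shares.

## Numerical strategy

Component variances are optimized as log standard deviations, which
enforces non-negativity smoothly and keeps the delta method well behaved
away from boundaries. Each fit runs a fixed three-start schedule (equal
shares; a genetic-heavy allocation; an E-heavy allocation), so refitting
identical data is bit-reproducible. Two safeguards deal with boundaries:

1. The log-SD scale can approach but never reach a zero variance. After
   optimization every admissible nested model (one component dropped) is
   fitted — recursively, so AE also checks the closed-form E solution — and
   adopted whenever it attains a higher likelihood. Likelihood nesting
   (`loglik(ACE) >= loglik(AE) >= loglik(E)`, etc.) therefore holds exactly,
   not just up to optimizer tolerance.
2. The E-only model with an intercept mean has a closed-form ML solution
   (grand mean, mean squared deviation) and is computed analytically.

`converged` requires optimizer success plus either a replicated optimum
across starts or a small gradient norm. The heritability CI uses the delta
method on the log-SD parameterization, truncated to `[0, 1]`; at a boundary
the curvature matrix can be singular, in which case the CI is reported as
missing rather than fabricated. A parametric-bootstrap check in the test
suite confirms the delta CI endpoints to within ±0.03 at 500 pairs per
zygosity.

The test oracle for the fitter is `grid_oracle_fit()`: an exhaustive lattice
search over variance proportions and a total-variance grid, with the GLS
mean profiled in closed form at each lattice point. It shares no optimizer
code with the ML path, and the total-variance grid is anchored so it always
contains the closed-form E solution exactly.

Likelihood-ratio tests between nested models report the naive chi-square
p-value with a `boundary` flag: when the null pins a variance at zero the
statistic follows a chi-square mixture and the naive p is conservative. The
50:50 mixture correction is available (`mixture = TRUE`) but not the
default, since the conservative direction is the safe one for claiming
heritability. AIC (`2k - 2 loglik`) compares non-nested models; exact ties
break toward fewer parameters, then the fixed order AE, ACE, ADE, CE, E.

## Similarity estimators

`within_pair_pearson()` offers two orderings. `file_order` correlates
(y1, y2) as delivered; because twins carry no natural order this estimate
depends on an arbitrary labelling, so `double_entry` (augmenting with
member-swapped copies, an ICC-type estimator) is provided and the output
records which was used. Fisher-z CIs always use the pair count — double
entry does not double the information. The default is `file_order`; the two
agree under exchangeability, which the tests check in simulation.

`icc_ml()` estimates the ICC as the correlation parameter of an
exchangeable bivariate-normal ML fit, unadjusted or with covariates in the
mean. The default CI inverts the profile likelihood, which behaves at the
`rho -> 1` boundary; a Fisher-z CI (`ci_method = "fisher"`) is the fast
fallback and is what the pipeline uses for bulk tables when speed matters.
Negative ICCs are admissible (the pair-likelihood lower bound is -1) and
reported as estimated.

## Cluster-robust descriptives

Co-twins are not independent, so descriptive inference treats the pair as
the sampling unit. `cluster_robust_correlation()` keeps the ordinary
Pearson r as the point estimate and derives its SE from a
standardized-regression slope with a cluster sandwich variance
(`sandwich::vcovCL`), normal-approximation CI and p. The sex contrast is
the percent difference of medians, with a p-value from a seeded cluster
bootstrap (whole pairs resampled, 10,000 replicates by default): since
co-twins share sex, a naive rank test would be anti-conservative. The
normality flag uses Shapiro–Wilk up to n = 5000 and the D'Agostino–Pearson
K2 omnibus beyond (Shapiro–Wilk's supported range ends there); the original
analyses named neither a normality nor a sex-difference test, so these are
documented conventions, and the run log says so.

Quantiles use linear interpolation between order statistics (type 7) — the
P25/P75 columns depend on this rule, hence it is fixed. Age groups are
left-open/right-closed: <=75, (75,80], (80,85], >85 years.

## The synthetic cohort generator

Subject-level twin registry data of this kind are not shareable, so every
downstream stage is exercised against `generate_cohort()`. The default
design (`default_study_config()`) emulates the study cohort the package was
built around: 125 MZ + 173 DZ intact same-sex pairs (596 subjects), 33%
male pairs, ages on [73.2, 94.3] years with mean 78.8, and four log-normal
analytes. Per pair, one sex and one shared age are drawn; per protein and
member, a latent log-scale value

    mu + beta_sex * I(male) + beta_age * (age - 78.8) + a A_i + c C + d D_i + e E_i

with standard-normal factors correlated across co-twins at the biometrical
values (A: 1 / 0.5; D: 1 / 0.25; C shared; E independent), loadings
`a = sqrt(a2 * total_var)` etc., exponentiated last. Calibration choices,
each fixed once from published summaries:

* `a2` = the published unadjusted AE heritabilities (0.67, 0.71, 0.62,
  0.59), `c2 = d2 = 0`;
* `mu` = log of the published medians (1.14, 29.3, 88, 406 ng/mL);
* `beta_sex` = log of the published male/female median ratios (+29%, +18%,
  +19%, -28%) — an additive latent effect is a multiplicative median ratio
  after exponentiation;
* `beta_age` chosen as `r * sigma_latent / sd(age)` to reproduce the
  published age correlations (0.19 for PAPP-A, -0.12 for IGF-I, none for
  STC2/IGF-II); these are calibrated approximations because the published
  correlations are on the observed scale;
* `total_var` = the latent variance implied by the published CVs via
  `log(1 + CV^2)`, minus the variance contributed by the sex and age terms,
  so marginal dispersion roughly matches;
* ages follow a truncated exponential on the published range solved to the
  published mean (rate 0.1558, SD 4.82 years) — elderly cohorts are
  bottom-heavy in age and only range and mean were published.

What the generator does **not** emulate: assay noise as a separate
component (it is absorbed into E), cross-protein correlation by default
(available via an optional correlation matrix on the A and E factors, but
the published cross-twin cross-trait structure is unknown, so any default
would be a stand-in), longitudinal waves, and mortality/attrition. Passing
tests on synthetic data therefore demonstrate correctness of the estimators
under the stated model, not robustness to every feature of real serum data.
Note one deliberate consequence of the design: because co-twins share age
and sex, the unadjusted resemblance absorbs those effects and adjusted
ICC/heritability run lower — the same ordering the real tables show.

## Sensitivity analyses

`sensitivity_analysis()` refits the AE model (unadjusted and adjusted)
after (i) excluding whole pairs with a member above the analyte threshold,
(ii) truncating values at the threshold, or (iii) a rank-based
inverse-normal transform (Blom offsets) of the pooled subject-level values
before pair formation. Default thresholds are 3 (PAPP-A), 55 (STC2), 200
(IGF-I) and 800 ng/mL; the source material lists the 800 threshold under a
second "IGF-I" label that is inconsistent with the IGF-I range but sits
just below the IGF-II maximum, so it is mapped to IGF-II here — a
documented interpretation, not a silent fix. Which normalizing
transformation the original analysis used is unstated; rank-inverse-normal
is the documented stand-in.

## Problem sizes used in the checks

Simulation-based checks use sizes chosen to balance statistical resolution
against runtime on a single core: parameter-recovery experiments at 10^5
pairs per zygosity (±0.01 resolution), Falconer consistency
(`h2 ≈ 2 (r_MZ - r_DZ)`) at 10^5, boundary-LRT conservativeness at 1,000
replicates of 100 pairs per zygosity, CI coverage at 400 replicates of 500
clusters, the parametric-bootstrap CI check at 400 replicates of 500 pairs
per zygosity, and bias checks at 4,000 pairs per zygosity across
`h2 in {0.2, 0.5, 0.8}`.

## Known limitations

* No bivariate/multivariate (Cholesky) twin models, so cross-trait genetic
  correlations are out of scope.
* The delta-method CI is symmetric and can be anti-conservative near
  `h2 -> 1`; the bootstrap path exists for verification.
* The exchangeable ICC assumes a common variance across co-twins; gross
  heteroscedasticity within pairs would bias it.
* `grid_oracle_fit()` is deliberately restricted to small, unadjusted
  problems; it is a test oracle, not an estimator.
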