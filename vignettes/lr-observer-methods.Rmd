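---
title: "Methods: the likelihood-ratio ideal observer for MTL volumetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the likelihood-ratio ideal observer for MTL volumetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrobserver)
```

## The model

The decision variable is a scalar volume $x$ in mm³ — a single
medial-temporal-lobe (MTL) subregion (hippocampus, amygdala,
entorhinal, parahippocampal), one hemisphere or both, or the bilateral
MTL total (eight summed volumes). Each diagnostic class is given a
class-conditional density: $f_n$ for normal controls (NC), $f_d$ for
Alzheimer's disease (AD). The ideal observer scores a subject by the
natural-log likelihood ratio

$$y(x) = \log f_d(x) - \log f_n(x)$$

and classifies $y > 0$ as diseased. Under equal priors and symmetric
costs this rule minimises error probability; sweeping the threshold
over $y$ instead of fixing it at 0 traces the optimal ROC curve.

With the primary Gaussian backend, $f_n = N(\mu_n, \sigma_n^2)$ and
$f_d = N(\mu_d, \sigma_d^2)$, the score is the quadratic

$$y(x) = \log\frac{\sigma_n}{\sigma_d}
  - \tfrac12\Big(\frac{x-\mu_d}{\sigma_d}\Big)^2
  + \tfrac12\Big(\frac{x-\mu_n}{\sigma_n}\Big)^2 ,$$

so the $y = 0$ decision boundary has one root when
$\sigma_n = \sigma_d$ (the equal-likelihood point between the means)
and up to two otherwise; with AD variance above NC variance, a second
root appears far in the upper tail, where extreme volumes again favour
the wider density. `decision_boundaries()` returns the real roots of
this quadratic; every returned root satisfies $|y| < 10^{-9}$.

Ranking by any *monotone* transform of $x$ gives the binormal area
under the ROC curve, the detectability index

$$A_z = \Phi\!\left(\frac{|\mu_n - \mu_d|}
  {\sqrt{\sigma_n^2 + \sigma_d^2}}\right),$$

which equals the probability that an independent AD/NC pair is ranked
correctly. The quadratic $y$-ranking is not monotone in $x$, but at
the parameter scales involved the non-monotone branch carries
negligible mass, so empirical AUCs of $y$-scores and the binormal
$A_z$ agree closely (tested to within 0.005 at 20,000 draws per
class).

### Assumptions

* **Normality per class.** Cohort volumes are treated as Gaussian;
  the kernel-density backend (`backend = "kde"`, Gaussian kernel,
  Silverman bandwidth — the defaults of R's `density()`) exists to
  check this assumption nonparametrically, not to replace the
  parametric analysis.
* **Untruncated densities.** Volumes are positive but the Gaussians
  are not truncated at zero: at the reference parameters
  (coefficients of variation ≤ 0.27) the sub-zero mass is below
  $10^{-8}$ and truncation would change nothing at double precision.
* **One measure at a time.** The observer is univariate. Multivariate
  likelihood ratios over several regions jointly are out of scope; the
  MTL *total* is still univariate — the regions are summed before
  scoring.
* **No covariate correction.** Volumes enter raw, without age, sex or
  intracranial-volume normalisation; the method is deliberately a
  single-number tool.

## Estimation and numerical choices

* `fit_gaussian()` uses the arithmetic mean and the $n-1$ sample SD;
  at $n = 263$ the difference from the ML estimator is negligible, and
  the unbiased form is the field convention. Fewer than two values, or
  zero variance, is an error rather than a degenerate density.
* All likelihood evaluation is in the log domain
  (`density_logpdf()`), so scores stay finite hundreds of SDs from the
  means. For the kernel backend the log-density uses a
  max-stabilised log-mean-exp; a measurement so far outside the
  fitted sample that the kernel mixture underflows to zero in the
  linear domain raises an undefined-ratio error (the Gaussian backend
  cannot trigger this).
* A score of exactly $y = 0$ — equal likelihood — classifies as
  *normal*: ties go to the null class, the conservative clinical
  convention. The sign of $y$, hence every decision, is invariant to
  the logarithm base.
* The empirical ROC (`empirical_roc()`) sweeps thresholds over the
  distinct score values, collapses ties into single vertices, and
  integrates by the trapezoidal rule; this makes the AUC identical to
  the Mann–Whitney statistic
  $P(s_D > s_N) + \tfrac12 P(s_D = s_N)$, which the tests verify by
  exhaustive pairwise enumeration and against `pROC`.
* AUC confidence intervals use the Hanley–McNeil standard error with
  the exponential approximations $Q_1 = A/(2-A)$,
  $Q_2 = 2A^2/(1+A)$, normal quantiles, and clipping to $[0,1]$;
  a 10,000-resample bootstrap in the test suite agrees with the upper
  bound to within 0.02 at the study's 46/23 test size.

## Morphometry conventions

Percent differences — hemispheric asymmetry and AD-vs-NC reduction —
are computed relative to the **midpoint mean**:
$100\,|a-b| / \{(a+b)/2\}$. This symmetric convention is the one under
which the reference hippocampal figures cohere: AD asymmetry 3.26%,
left and right AD-vs-NC reductions 19.4% and 19.3%, bilateral
reduction 19.3% (dividing by the larger value would give 17.7% for
the left reduction instead). Signed left–right differences are stored
as left minus right (negative when the left is smaller, as in both
groups here); the percentage reports the magnitude. The
"average asymmetry" across groups is the arithmetic mean of the
per-group percentages as reported, so already-rounded figures
(3.26, 3.20) average to 3.23. P-values display to three decimals,
flooring at "< 0.001".

## The synthetic-cohort generator

`generate_cohort()` emulates the study conditions so the full
construction → held-out evaluation can run with no data access:

* **Cohort sizes.** `default_recipe("adni_like")` generates 263 AD +
  263 NC (density construction); `"miriad_like"` generates 46 AD +
  23 NC (held-out test). The default seed is 42.
* **Per-region structure.** For each subject and region, (left,
  right) volumes are bivariate normal. Hippocampal per-hemisphere
  means, SDs and left–right correlations (0.798 AD, 0.841 NC) are the
  published reference values; the other regions are reported only as
  bilateral totals, so their hemispheric means are split 50/50 and the
  per-hemisphere SD is $\sigma_{bil}/\sqrt{2(1+\rho)}$ with
  $\rho = 0.8$, inverting exactly to the published bilateral SD.
* **Between-region correlation.** Regional volumes of one subject
  co-vary (global atrophy): summing *independent* region totals would
  give an MTL SD of ≈1550 mm³ (AD) where the published value is
  2511.1, inflating the MTL $A_z$ from ≈0.84 to ≈0.94. The generator
  therefore ties region totals to a subject-level common factor with
  one correlation per group, calibrated
  (`calibrate_region_correlation()`: $\rho_r$ ≈ 0.59 AD, 0.47 NC) so
  the simulated MTL bilateral SD reproduces the published one. The
  bilateral sum is then split into hemispheres conditionally, which
  preserves every per-region marginal and left–right correlation
  exactly.
* **Positivity.** Draws with a non-positive volume are rejected and
  redrawn (keeping the subject's common factor). At reference scale
  the rejected mass is < $10^{-7}$, so moments are untouched; a
  parameter set that concentrates mass below zero errors out after a
  bounded number of attempts instead of looping.
* **Determinism.** Generation depends only on the recipe (its seed
  included); the caller's RNG stream is restored afterwards, and two
  runs serialize byte-identically.

What the generator does **not** emulate: the test-cohort shift (the
real held-out AD cohort is more atrophic than the construction cohort
— its test AUC of ≈0.93 exceeds the construction $A_z$ of 0.84, and
its 89.1%/87.0% operating point is correspondingly better than the
construction-parameter prediction of ≈72%/81%); non-Gaussian tails;
age, sex and head-size structure; and any region-pair correlation
pattern beyond the single common factor. Passing tests therefore show
the pipeline's internal consistency at the published parameters, not
performance on real patients.

## Problem sizes in the test suite

Deterministic identities are tested exactly. Stochastic checks use
fixed seeds with sampling-theory tolerances: parameter recovery at the
construction size $n = 263$ (3 standard errors on means, 15% on SDs);
left–right correlation at $n$ = 10,000 (±0.03); empirical-vs-binormal
AUC at 20,000 draws per class (±0.005); the Monte-Carlo $A_z$ oracle
at $10^6$–$10^7$ pair draws (±0.001–0.002); the held-out operating
point at the study's own 46/23 split, judged by the exact binomial
test at $\alpha = 0.05$ (with 23 controls the specificity moves in
steps of 0.043, so a normal-approximation band would misstate the
check); monotonicity of AUC in class separation over a five-point
grid at 1,500 subjects per class per point.

## Known limitations

* Univariate only; combining measures requires refitting on a derived
  sum, not a joint density.
* The binormal $A_z$ is exact only under per-class normality; for
  clearly non-Gaussian data use the KDE backend and the empirical
  AUC.
* Hanley–McNeil intervals are asymptotic and degrade near
  $A_z = 1$ or with very few subjects; the bootstrap is the fallback.
* FreeSurfer parsing expects the standard `aseg.stats` /
  `?h.aparc.stats` layouts (`# ColHeaders` line, Desikan–Killiany
  names); other atlases need a tidy CSV prepared by the user.
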