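---
title: "Two-sample Mendelian randomization with mrlong: models, assumptions, and numerical choices"
author: "mrlong authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrlong}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrlong)
```

## The causal model

Mendelian randomization (MR) treats genetic variants as instrumental
variables for a modifiable exposure. For SNP $j$, let $\beta_{Xj}$ be its
per-allele effect on the exposure (here: a circulating antioxidant or
antioxidant metabolite) and $\beta_{Yj}$ its effect on the outcome (here:
the log odds of surviving to the 90th vs. the 60th percentile age, or
parental lifespan in years). Under the three instrumental-variable
assumptions — relevance, independence from confounders, and exclusion
restriction — a linear causal model implies

$$\beta_{Yj} = \theta\,\beta_{Xj},$$

so every valid instrument estimates the same causal effect $\theta$
through its Wald ratio $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$. The
two-sample design takes $\hat\beta_{Xj}$ and $\hat\beta_{Yj}$ from
non-overlapping GWAS samples, which makes their errors independent and
permits inference from published summary statistics alone.

Violations enter as a pleiotropic term $\alpha_j$:
$\beta_{Yj} = \theta\beta_{Xj} + \alpha_j$. The estimator battery spans
the standard responses to it:

* **IVW (multiplicative random effects)** — `mrIVW()`. Pools the ratios
  with first-order weights $w_j = \beta_{Xj}^2/\sigma_{Yj}^2$, i.e. the
  zero-intercept weighted regression of $\hat\beta_{Yj}$ on
  $\hat\beta_{Xj}$. Cochran's $Q = \sum_j w_j(\hat\theta_j-\hat\theta)^2$
  measures heterogeneity; the fixed-effect standard error
  $(\sum_j w_j)^{-1/2}$ is multiplied by $\max(1, \sqrt{Q/(J-1)})$.
  Flooring the factor at 1 means underdispersion never narrows the
  interval, the usual multiplicative random-effects convention.
* **Weighted median** — `mrWeightedMedian()`. Sorts the ratio estimates
  and interpolates the order statistics at standardized midpoint
  cumulative weight $s_j = (\sum_{i\le j} w_i - w_j/2)/\sum_i w_i = 0.5$;
  consistent while instruments carrying over half the weight are valid.
  Its standard error comes from a seeded parametric bootstrap (default
  1,000 replicates) resampling both effect sides from normals.
* **MR-Egger** — `mrEgger()`. Weighted regression with a free intercept,
  after orienting every instrument to a nonnegative exposure effect. The
  intercept estimates average directional pleiotropy; the slope is a
  pleiotropy-corrected effect under the InSIDE assumption. Standard
  errors carry the same multiplicative residual inflation, floored at 1.
* **MR-PRESSO** — `mrPresso()`. A Monte-Carlo residual-sum-of-squares
  framework: a global heterogeneity test, a per-SNP outlier test
  (Bonferroni-corrected across instruments), an outlier-corrected IVW
  estimate, and a distortion test comparing corrected and uncorrected
  estimates against random same-sized inlier removals. The distortion
  result is surfaced but never used to pick which estimate to report.
* **Leave-one-out** — `mrLeaveOneOut()`, recomputing the IVW estimate
  with each SNP omitted.

All p-values are two-sided normal ($z = \hat\theta/\widehat{se}$) except
heterogeneity, which is upper-tail $\chi^2$. Confidence intervals are
normal-theory 95% intervals throughout.

## Wald-ratio standard errors

The default is the first-order delta method, $\sigma_{Yj}/|\beta_{Xj}|$,
which ignores exposure-side uncertainty. This matches the weighting
implied by the IVW formulation above and is what summary-statistics MR
conventionally reports; `waldRatio(..., secondOrder = TRUE)` exposes the
second-order form
$\sqrt{\sigma_Y^2/\beta_X^2 + \beta_Y^2\sigma_X^2/\beta_X^4}$ for strength
sensitivity checks. With instruments at $F > 30$ the two differ
negligibly; the first-order choice matters only near the weak-instrument
regime, where no SE formula rescues the ratio anyway.

## Harmonization

`harmonize()` aligns each outcome record onto the exposure's effect
allele. Non-palindromic mismatches resolve deterministically by strand
complementation and/or allele swap (a swap negates the outcome beta and
reflects its allele frequency). Palindromic SNPs (A/T, C/G) cannot be
resolved from letters; the default policy `infer_by_eaf` uses allele
frequencies, dropping the SNP when either frequency is missing or within
0.08 of 0.5 (i.e. in [0.42, 0.58]) — the window standard two-sample MR
practice uses, trading a few instruments for protection against silent
sign errors. `keep` trusts reported strands, appropriate when ingesting
tables already harmonized at source, and `drop` refuses palindromes
outright. Every exposure SNP appears in the audit table with an action
(`aligned`, `flipped`, `dropped_palindromic`, `dropped_missing`,
`dropped_incompatible`); nothing is dropped silently. SNPs absent from
the outcome are dropped rather than proxied — LD-proxy lookup would
require an external reference panel and is deliberately out of scope.

## Instrument strength and power

With the exposure standardized to unit variance, a SNP with standardized
per-allele effect $\beta$ and minor-allele frequency $m$ explains
$R^2 = 2\beta^2 m(1-m)$ of the exposure variance (`snpR2()`); set-level
values sum per-SNP contributions under the assumption of LD-pruned
(uncorrelated) instruments. Instrument strength is summarized by

$$F = \frac{R^2 (n-k-1)}{k\,(1-R^2)},$$

with $n$ the exposure-GWAS sample size and $k$ the instrument count
(`fStatistic()`); sets below $F = 10$ trigger a warning. Statistical
power for the IVW test (`powerIVW()`) uses the noncentrality
approximation behind the standard online calculators: the IVW $z$
statistic is approximately $N(\sqrt{nR^2}\,\theta, 1)$, with $\theta$
replaced by $\log\mathrm{OR}\cdot\sqrt{cf(1-cf)}$ for a binary outcome
with case fraction $cf$. Because this models the fixed-effect $z$, the
multiplicative random-effects floor makes realized rejection run a few
percentage points below the formula for small instrument counts in
mid-power regimes; the approximation is validated against simulation at
an instrument count large enough (60) that the floor perturbs the
comparison by under 3 percentage points.

## The synthetic-data generator

`simulationScenario()` + `simulateSummaryStats()` generate two-sample
summary statistics with known truth. Per SNP: MAF uniform on
[0.1, 0.5] by default (common variants, as GWAS instruments are);
$\beta_{Xj}$ drawn half-normal with random sign, so harmonization and
Egger orientation logic face both orientations; standard errors from the
large-sample per-allele approximation
$\sigma = 1/\sqrt{2m(1-m)n}$, divided by $\sqrt{cf(1-cf)}$ on the
log-odds scale — which keeps realized per-SNP $F$ statistics consistent
with `fStatistic()`. Observed effects are drawn independently on the two
sides (the two-sample property). Each SNP has its own deterministic RNG
sub-stream derived from the scenario seed, so enlarging a scenario never
reshuffles earlier SNPs and identical seeds are bit-reproducible.

Pleiotropy regimes: `none`; `balanced` ($\alpha_j \sim N(0,\tau^2)$);
`directional` ($\alpha_j \sim N(\mu_\alpha,\tau^2)$); and `outliers`
(a subset receives an offset of `offset_scale` outcome standard errors).
One modelling choice deserves emphasis: **pleiotropy is defined on the
exposure-increasing allele**. The generator multiplies the drawn
$\alpha_j$ by $\mathrm{sign}(\beta_{Xj})$ before forming
$\beta_{Yj} = \theta\beta_{Xj} + \alpha_j^{\mathrm{eff}}$. Without this,
a "directional" mean $\mu_\alpha$ attached to randomly signed reported
alleles averages to zero after the orientation step every estimator
applies, and no directional regime would exist at all; with it, the
Egger intercept recovers $\mu_\alpha$ and directional contamination
genuinely biases IVW, as the regime names promise. Balanced pleiotropy
is unaffected (the distribution is symmetric).

`scenarioFromSource()` calibrates scenarios to the nine antioxidant
source GWASs (instrument counts 2–24, exposure samples 441–15,087,
reported $R^2$ 1.87%–30.1%): `betaXScale` is solved so the expected
realized $R^2$, $k \cdot \mathrm{betaXScale}^2 \cdot E[2m(1-m)]$, equals
the reported value. The outcome defaults to the binary longevity
contrast (11,262 cases / 25,483 controls, log-odds) or the continuous
parental-lifespan trait ($n$ = 1,012,240).

What the generator does *not* emulate: LD between instruments,
individual-level genotypes, winner's-curse selection of instruments,
sample overlap, or population stratification. Passing tests therefore
demonstrate correctness of the estimators under the stated model, not
robustness of any real-data conclusion to those additional artefacts.

## Numerical and design choices

* **Ties and interpolation.** The weighted median interpolates midpoint
  cumulative weights; with equal weights and odd $J$ it reduces to the
  ordinary sample median. Order-of-input never matters.
* **Egger identifiability.** Zero spread in oriented exposure effects is
  a hard error (the slope is unidentifiable), as is $\beta_X = 0$ for a
  Wald ratio.
* **Degeneracies.** One instrument degrades IVW to the Wald ratio with a
  logged notice; the weighted median and Egger require 3 instruments,
  MR-PRESSO 4 (it holds leave-one-out fits inside). The pipeline emits
  `NA` rows with machine-readable reasons instead of skipping silently.
* **Monte-Carlo floors.** PRESSO p-values use the add-one estimator
  $(1+\#\{\cdot\})/(n_{\mathrm{sim}}+1)$, bounded away from zero;
  defaults $n_{\mathrm{sim}} = 5{,}000$, outlier threshold 0.05 after
  Bonferroni correction across instruments. The global test is known to
  run conservative for small instrument sets (measured ≈2% rejection at
  $\alpha = 0.05$ with $J = 10$, nominal by $J \approx 16$–24); its
  calibration check therefore runs at $J = 24$, the largest instrument
  count among the nine exposures.
* **Seeds.** Every stochastic component takes a mandatory seed; the
  pipeline derives per-pair, per-method sub-seeds from its master seed so
  toggling one method never perturbs another and whole result tables are
  byte-reproducible.
* **Presentation scales.** Binary-outcome estimates exponentiate to odds
  ratios; parental-lifespan estimates may be scaled by ten to read as
  lifespan years per 10-fold (decadic) exposure increase. Transforms act
  on the estimate and CI bounds only — p-values are computed on the
  estimation scale and never recomputed after transformation (the
  transforms are monotone, so this is exact for symmetric normal-theory
  intervals).
* **No multiplicity correction across exposures.** The exposure panel is
  reported at per-test $\alpha = 0.05$, matching the study design this
  package operationalizes; users wanting family-wise control can apply
  `p.adjust` to the result table.

## Problem sizes used in validation

The shipped checks use desk-scale simulation sizes chosen to keep
Monte-Carlo error well inside each assertion's tolerance: 50 random
instances for the weighted-least-squares oracle equivalence; 1,000
replicates for bias/coverage recovery on the lycopene-calibrated
scenario; 2,000 and 500 replicates for Cochran's Q and PRESSO global
null calibration; 500 replicates for the contamination-robustness
ordering; 200 runs for outlier detection; $10^5$–$10^6$ draws for the
delta-method and $R^2$ oracles.

## Known limitations

* First-order weights understate ratio uncertainty for weak instruments;
  the $F$-statistic screen (warn below 10) is the guard rail.
* Egger orientation relies on the sign of the *observed* exposure
  effect: instruments indistinguishable from zero can be mis-oriented,
  which drags the intercept — one more reason instruments must be
  significance-selected before analysis.
* The distortion test needs more inliers than outliers to resample; with
  nearly half the set flagged it returns `NA`.
* No LD-aware IVW, no multivariable MR, no mode-based estimators, no
  Steiger filtering; instrument lists are taken as given (pre-selected
  and LD-pruned at source).
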