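---
title: "Adding mammographic density to case-control breast cancer risk models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adding mammographic density to case-control breast cancer risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(densrisk)
```

## The problem

Mammographic density — whether graded visually into the four BI-RADS
categories or measured as volumetric percent density (VPD) by automated
software — is one of the strongest risk factors for breast cancer that is
routinely available at screening. It is also strongly negatively
correlated with age and BMI, which are themselves in every risk model.
Adding raw density to a model such as Tyrer-Cuzick would double-count the
age and BMI information. `densrisk` therefore works with the **density
residual**: the part of (transformed) density not explained by age and
BMI among healthy controls. This vignette records the statistical model,
the tunable parameters, the numerical conventions, and the design
decisions that were genuinely open.

## The expected-density model and its residual

`fit_expected_density()` fits, to controls only,

$$ t(d_i) = \beta_0 + s_1(\mathrm{age}_i) + s_2(\mathrm{bmi}_i) + \varepsilon_i $$

where $t$ is the natural log for VPD and the fibroglandular/fat volumes
and the identity for BI-RADS grade codes 1–4, and $s_1, s_2$ are cubic
B-spline expansions. Choices:

* **Basis and smoothness.** Cubic B-splines with `df = 4` per covariate
  (interior knots at equally spaced quantiles), fitted by unpenalized
  least squares. With two covariates and nine coefficients against
  hundreds or thousands of controls, the variance cost of skipping the
  penalty is negligible, the fit is a plain linear solve, and the model
  serializes exactly (knots + coefficients) to JSON. The test suite
  cross-checks the fitted surface against an independently fitted
  penalized GAM (`mgcv::gam` with thin-plate smooths); the two agree to
  an RMSE well below the residual spread.
* **No log transform for BI-RADS.** Density grade codes are ordinal
  labels; the log of a category code has no scale meaning. Grades enter
  as integers 1–4, and predictions are clamped to [1, 4].
* **Quartiles.** Control residual quartiles use linear interpolation of
  order statistics (R's type 7), stated here so that the interquartile
  width — the denominator of every IQ-OR — is bit-reproducible.
* **Out-of-range prediction.** Ages or BMIs outside the training range
  are clamped to the boundary with a warning rather than extrapolated:
  cubic spline extrapolation is wild, and the analysis never needs values
  outside the control hull.

A residual of $r$ means the woman's density is $e^r$ times her age/BMI
expectation (VPD scale); the control residuals have median ≈ 0 by
construction.

## Adjusted logistic modelling

`fit_adjusted_logistic()` is maximum likelihood via IRLS (`stats::glm`)
with convergence tolerance $10^{-10}$ and explicit failure modes:
non-convergence, degenerate outcome, constant (collinear) terms, and
suspected separation (|coefficient| > 15) all raise errors naming the
term. The standard adjustment set is the matching variable (5-year age
group, indicator-coded) plus region, insurance, financial screening,
education, ethnicity, BMI, and the natural log of the baseline 10-year
risk. Missing categorical values become an explicit `"Unknown"` level;
rows with missing continuous covariates are dropped with a logged count.

* **IQ-OR.** `exp(coef × IQR)` with Wald CIs on the log-odds scale —
  symmetric on the log scale, matching epidemiological convention. The
  IQ-OR is invariant to affine rescaling of the residual.
* **Quantile-group ORs.** Group boundaries sit at the control order
  statistics `round(i·n/k)`, so 2,243 controls split into quintiles of
  449/448/449/448/449; controls are assigned by rank (ties broken by
  position) and cases by comparison with the boundary values.
* **Bootstrap comparison of two measures.** The comparison statistic is
  the difference in added LR-χ² (each measure against the covariates-only
  model). Participants are resampled within case/control strata; the
  two-sided p comes from the bootstrap distribution centred at the
  observed difference. Replicates whose refits fail are dropped and
  counted, with a warning above 5%.
* **Calibration coefficient.** The slope (×100) of case status on
  ln(predicted risk). This is the standard relative-risk calibration
  available in case-control data, where absolute observed/expected ratios
  are not identified: 100% means the model's relative risks are fully
  expressed.
* **Linearity and interaction checks.** Both are LR tests: a spline
  expansion of the residual against the linear term (the spline span
  contains the line, so the models are nested even though the design
  matrices differ), and a product term for effect modification.

## Matched concordance

`matched_concordance()` first residualizes the predictor on the
adjustment factors by OLS (`adjust_predictor()`), then compares every
case with every control within a matching stratum:

$$ mC = \frac{\#(\text{case} > \text{control}) + \tfrac12\,\#\text{ties}}{\#\text{pairs}} $$

computed via the midrank identity with the Wilcoxon statistic. Strata
default to the 5-year age groups used for frequency matching; strata
without both outcomes are skipped and counted. The CI is a stratified
nonparametric bootstrap (cases and controls resampled separately within
each stratum), consistent with the bootstrap used elsewhere in the
package; 1,000 replicates by default. mC is invariant to strictly
increasing transforms of the score, and swapping the outcome labels maps
mC to 1 − mC — both are tested properties.

## Agreement and crude association

`weighted_kappa()` uses disagreement weights $w_{ij}=|i-j|/(k-1)$
(linear) by default. The choice was fixed by verification: on the shipped
reference cross-tabulation of BI-RADS against volumetric grades (2,717
women), linear weights give κ = 0.640 while quadratic weights give 0.78,
and 0.64 is the documented agreement for such tables. The CI is a seeded
multinomial bootstrap of the count table. `crude_odds_ratio()` is
`ad/bc` with the Woolf (log-scale normal) interval and a 0.5 continuity
correction for zero cells. `spearman_rho()` is the Pearson correlation
of midranks.

## Combining density with the absolute 10-year risk

The fitted residual coefficient $\beta$ converts to a relative risk
$rr = e^{\beta r} / \bar{E}$, normalized by
$\bar E = \mathrm{mean}(e^{\beta r})$ over controls so that the mean rr
among controls is exactly 1 and adding density leaves the
population-average risk approximately unchanged — without this the
before/after risk histograms would not be comparable. Combination is on
the hazard scale, $100(1-(1-p/100)^{rr})$, which stays a valid
probability for any positive rr and is numerically close to $p \cdot rr$
in the 0–10% range where screening risks live. Strata boundaries follow
clinical usage: *low* is < 2%, *high* is ≥ 8%, the middle takes the rest,
so the three proportions always sum to one.

## The synthetic-data generator

No participant-level data ship with the package; `generate_population()`
emulates the data structure the analysis assumes, and its defaults are
the study conditions every simulation-based test uses:

* 2,243 controls and 474 cases, ages 40–79 (truncated normal, median
  ≈ 59); cases frequency-matched to the control 5-year age distribution
  by largest-remainder apportionment, so bin shares match to rounding.
* BMI log-normal (median 25.6 kg/m², log-SD 0.2075).
* ln VPD linear in age and BMI (slopes −0.034/yr and −0.12 per kg/m²)
  with Gaussian residual SD 0.9. The slopes were chosen once to hit
  control Spearman correlations of about −0.25 (age) and −0.56 (BMI);
  the residual SD puts the control residual IQR near 1.2 natural-log
  units, matching the adjusted-density spread such studies report.
  A consequence of reproducing that residual spread with a log-normal is
  that the marginal VPD-grade distribution is wider than real Volpara
  grade margins — one of several deliberate simplifications (below).
* BI-RADS from latent ln VPD plus Gaussian reader noise (SD 0.70 on the
  log scale) thresholded at the manufacturer cutoffs 4.6/7.6/15.4%. The
  noise SD was calibrated by a sweep so that generated BI-RADS × VPD
  grade cross-tabs give linear weighted κ ≈ 0.64, the agreement observed
  between clinical and volumetric gradings.
* Baseline 10-year risk log-normal with control median 3.17% and IQR
  2.35–4.56%; its case-status coefficient defaults to 1 per ln(risk)
  (a perfectly calibrated baseline model).
* Five demographic covariates with control prevalences and case odds
  ratios (1.90, 1.78/2.05, 3.16, 1.93, 2.00) acting as independent
  multiplicative odds factors.
* Case status: cases are drawn by exact exponential tilting of the
  factorized control distribution — tilted categorical prevalences,
  ln-risk mean shifted by `tc_coef·σ²`, VPD residual mean shifted by
  `beta_vpd·σ²` — plus a rejection step for the BI-RADS-residual effect,
  whose acceptance weight is bounded because the grade residual lies in
  (−3, 3). This preserves all logistic coefficients under case-control
  sampling without simulating a huge source population.
* Total breast volume is log-normal in BMI, and fat volume is defined as
  total minus fibroglandular volume, so
  `vpd = 100·fibro/(fibro + fat)` holds exactly for every record.
* Reproducibility: one master seed; every variable draws from a named
  substream, so adding a variable never perturbs existing draws, and the
  same seed reproduces the same table byte for byte.

**What the generator does not emulate.** Covariates are mutually
independent in controls (real insurance status correlates with region and
education); BMI has no direct case effect (its real crude OR arises
through pathways the generator routes only through density and risk);
baseline risk is independent of age (real Tyrer-Cuzick risk rises with
age); density is log-normal with linear trends (real density surfaces
flatten at the extremes, and the real residual distribution is heavier
tailed than its grade margins imply). Passing tests therefore show the
*estimators* are correct under the assumed structure — recovery of known
IQ-ORs, nominal test size, exact bookkeeping — not that real data meet
the assumptions.

## Problem sizes and numerical conventions

Simulation-based checks use study-scale datasets (2,243/474) for test
size (200 replicates) and n = 20,000 with a 5,000-control pilot for
effect-size recovery — sizes at which the recovery tolerance of ±0.1 on
an IQ-OR of 1.40 corresponds to roughly two standard errors. Convergence
tolerances: IRLS $10^{-10}$ (relative deviance); residual-fit mean-zero
to $10^{-8}$; rr normalization exact to $10^{-10}$. Bootstrap defaults:
2,000 (kappa), 1,000 (mC), 499 (measure comparison); all seeded through
the substream mechanism. Ties: midranks everywhere (Spearman, mC);
quantiles type 7; `findInterval` conventions put a value exactly on a
grade cutoff into the upper grade and a risk exactly on a stratum
threshold into the upper stratum.

## Known limitations

* The expected-density surface is additive in age and BMI; a strong
  age×BMI interaction in density would leak into the residual.
* The calibration coefficient and the bootstrap comparison statistic are
  reasonable conventions for under-specified quantities; other defensible
  definitions exist (e.g. resampling schemes that refit the expected-
  density model inside each replicate).
* The within-stratum all-pairs definition of mC is one of several
  matched-concordance constructions in the literature.
* No Firth correction or exact logistic regression: very sparse strata
  or quasi-separated covariates raise errors rather than being shrunk.
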