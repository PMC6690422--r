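# densrisk

Mammographic density improves breast cancer risk assessment, but the two
measures practical for clinics — the visually read BI-RADS density category
(1 = fatty … 4 = dense) and automated volumetric percent density (VPD) —
are strongly confounded with age and body mass index. `densrisk`
implements a case-control workflow that isolates the density signal
independent of age and BMI and folds it into a questionnaire-based
absolute 10-year risk (such as a Tyrer-Cuzick assessment), for
biostatisticians working with screening case-control data.

## The model

For controls, expected transformed density is an additive spline surface

```
E[ln VPD | age, bmi] = s1(age) + s2(bmi)        (BI-RADS: grade codes 1..4 untransformed)
```

and each woman's **density residual** is `observed − expected`. Case status
is then modelled by adjusted logistic regression

```
logit P(case) = β·residual + age-group + demographic factors + bmi + ln(TC10)
```

and the density effect is reported as an **interquartile odds ratio**,
`IQ-OR = exp(β·(q75 − q25))`, for a move across the control residual IQR.
Supporting statistics: likelihood-ratio χ², quantile-group ORs, a matched
concordance index `mC` (probability a case out-scores a control within a
5-year age stratum), weighted-kappa agreement between the two gradings,
a calibration slope for the baseline risk, and the combined absolute risk
`100·(1 − (1 − TC10/100)^rr)` with `rr = exp(β·residual)` normalized to
mean 1 over controls, tabulated into the clinical <2% / ≥8% 10-year
strata.

A synthetic case-control generator (`generate_population()`) reproduces
the joint structure this analysis assumes — log-normal density with
age/BMI trends, latent-threshold BI-RADS, frequency matching, log-normal
baseline risk, multiplicative demographic odds — so the entire pipeline is
testable end to end, including recovery of known generative effect sizes.

## Worked example

```r
library(densrisk)

pop   <- generate_population(generator_config(seed = 7))   # 2,243 controls / 474 cases
model <- fit_expected_density(subset(pop, status == "control"), "vpd_log")
model
#> Expected-density model
#>   measure: vpd_log
#>   basis: cubic B-splines, df 4 (age) + 4 (bmi)
#>   trained on 2243 controls; age 40.1-80.0, bmi 13.9-51.6
#>   control residual quartiles: -0.613 / 0.004 / 0.624

pop <- add_residual(pop, model)          # adds vpd_residual
pop <- prepare_analysis_data(pop)        # adds age_group, log_tc10, case
fit <- fit_adjusted_logistic(pop, "vpd_residual", standard_adjustments())
q   <- residual_iqr(model)
iq_or(fit, q[["q25"]], q[["q75"]])
#> IQ-OR 1.31 (95% CI 1.13-1.53); IQR width 1.237
```

The fitted IQ-OR of 1.31 is this dataset's estimate of the generator's
true effect (IQ-OR 1.40 by default); at n = 20,000 the estimate lands
within ±0.1 of the target. Discrimination and agreement:

```r
pop$score <- adjust_predictor(pop, "vpd_residual",
                              setdiff(standard_adjustments(), "age_group"))
matched_concordance(pop, "score", "age_group", n_boot = 500, seed = 7)
#> Matched concordance mC = 0.546 (95% CI 0.516-0.575), 166737 pairs in 8 strata

tab <- read_crosstab(system.file("extdata", "birads_vpd_crosstab_controls.csv",
                                 package = "densrisk")) +
       read_crosstab(system.file("extdata", "birads_vpd_crosstab_cases.csv",
                                 package = "densrisk"))
weighted_kappa(tab, "linear", seed = 7)
#> weighted kappa 0.64 (95% CI 0.62-0.66)
```

mC = 0.546 says a case out-scores an age-matched control 54.6% of the
time (0.5 = no discrimination). The kappa of 0.64 is the agreement
between clinical BI-RADS and volumetric grades on the shipped reference
cross-tabulation. Finally, combining density with the baseline risk
shifts women out of the middle stratum:

```r
ctrl <- subset(pop, status == "control" & region == "primary")
rr   <- density_relative_risk(ctrl$vpd_residual, fit$coefficients["vpd_residual"],
                              control_residuals = pop$vpd_residual[pop$status == "control"])
round(100 * rbind(baseline     = risk_strata_proportions(ctrl$tc10),
                  with_density = risk_strata_proportions(combine_risk(ctrl$tc10, rr))), 1)
#>               low average high
#> baseline     16.6    79.5  3.9   (percent of primary-area controls)
#> with_density 19.7    76.2  4.1
```

`run_pipeline(pipeline_config(...))` chains all of the above into one
report (JSON + TSV tables).

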