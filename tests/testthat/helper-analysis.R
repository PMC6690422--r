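# Shared helpers: small deterministic populations and the standard
# residual -> adjusted-fit -> IQ-OR chain used across test files.

make_pop <- function(n_controls = 1500, n_cases = 300, seed = 42, ...) {
  generate_population(generator_config(n_controls = n_controls,
                                       n_cases = n_cases, seed = seed, ...))
}

# Fit the expected-density surface on controls, residualize everyone and
# return the adjusted IQ-OR for the residual.
recover_iq_or <- function(pop, measure = "vpd_log",
                          adjustments = standard_adjustments()) {
  model <- fit_expected_density(pop[pop$status == "control", ], measure)
  rescol <- "res"
  pop <- suppressWarnings(add_residual(pop, model, rescol))
  pop <- prepare_analysis_data(pop)
  fit <- fit_adjusted_logistic(pop, rescol, adjustments)
  q <- residual_iqr(model)
  list(iq_or = iq_or(fit, q[["q25"]], q[["q75"]], term = rescol),
       fit = fit, model = model, data = pop)
}

# Small hand-made participant table for IO tests.
tiny_participants <- function(n = 12, seed = 7) {
  set.seed(seed)
  data.frame(
    id = sprintf("p%02d", seq_len(n)),
    status = rep(c("control", "case"), length.out = n),
    age_mammogram = round(runif(n, 41, 78), 1),
    bmi = round(runif(n, 19, 38), 1),
    region = rep(c("primary", "outlying"), length.out = n),
    insurance = rep(c("insured", "medicaid", "none"), length.out = n),
    financial_screen = rep(c("never", "ever"), length.out = n),
    education = rep(c("more", "less"), length.out = n),
    ethnicity = rep(c("white", "other"), length.out = n),
    tc10 = round(runif(n, 1.2, 8), 2),
    vpd = round(runif(n, 2, 30), 2),
    fibro_volume = round(runif(n, 20, 120), 1),
    fat_volume = round(runif(n, 200, 900), 1),
    birads = sample(1:4, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "densrisk", mustWork = TRUE)
}

reference_crosstab <- function(which = c("combined", "controls", "cases")) {
  which <- match.arg(which)
  ctrl <- read_crosstab(fixture_path("birads_vpd_crosstab_controls.csv"))
  case <- read_crosstab(fixture_path("birads_vpd_crosstab_cases.csv"))
  switch(which, controls = ctrl, cases = case, combined = ctrl + case)
}
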