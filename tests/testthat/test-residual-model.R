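synthetic_controls <- function(n = 150, seed = 2, vpd = NULL) {
  set.seed(seed)
  d <- data.frame(
    status = rep("control", n),
    age_mammogram = runif(n, 40, 79),
    bmi = runif(n, 18, 40)
  )
  d$vpd <- if (is.null(vpd)) exp(rnorm(n, 2, 0.5)) else vpd
  d
}

test_that("constant density gives a flat surface with zero residuals", {
  d <- synthetic_controls(n = 120, vpd = rep(10, 120))
  m <- fit_expected_density(d, "vpd_log")
  r <- residualize(m, d$age_mammogram, d$bmi, d$vpd)
  expect_equal(max(abs(r)), 0, tolerance = 1e-8)
  expect_equal(unname(residual_iqr(m)), c(0, 0), tolerance = 1e-10)
})

test_that("a log-linear age trend is reproduced exactly at training points", {
  d <- synthetic_controls(n = 150)
  d$vpd <- exp(0.5 + 0.02 * d$age_mammogram)
  m <- fit_expected_density(d, "vpd_log")
  r <- residualize(m, d$age_mammogram, d$bmi, d$vpd)
  expect_lt(max(abs(r)), 1e-6)
})

test_that("residuals are invariant to scale shifts and to row order", {
  pop <- make_pop(n_controls = 600, n_cases = 0, seed = 12)
  m1 <- fit_expected_density(pop, "vpd_log")
  r1 <- residualize(m1, pop$age_mammogram, pop$bmi, pop$vpd)
  # multiplying density by a constant shifts only the intercept
  pop2 <- pop
  pop2$vpd <- pop2$vpd * 3
  m2 <- fit_expected_density(pop2, "vpd_log")
  r2 <- residualize(m2, pop2$age_mammogram, pop2$bmi, pop2$vpd)
  expect_equal(r1, r2, tolerance = 1e-8)
  # permuting rows permutes residuals
  perm <- sample(nrow(pop))
  m3 <- fit_expected_density(pop[perm, ], "vpd_log")
  r3 <- residualize(m3, pop$age_mammogram[perm], pop$bmi[perm], pop$vpd[perm])
  expect_equal(r3, r1[perm], tolerance = 1e-8)
})

test_that("stored quartiles equal the sort-and-interpolate oracle", {
  # independent type-7 oracle: h = (n-1)p + 1, linear interpolation
  q_oracle <- function(x, p) {
    s <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[pmin(lo + 1, length(x))] - s[lo])
  }
  pop <- make_pop(n_controls = 95, n_cases = 0, seed = 8)
  m <- fit_expected_density(pop, "vpd_log")
  r <- residualize(m, pop$age_mammogram, pop$bmi, pop$vpd)
  q <- residual_iqr(m)
  expect_equal(unname(q["q25"]), q_oracle(r, 0.25), tolerance = 1e-10)
  expect_equal(unname(q["q75"]), q_oracle(r, 0.75), tolerance = 1e-10)
  # symmetric hand-listed residual set: q25 = -q75
  expect_equal(q_oracle(c(-1, 0, 1), 0.25), -q_oracle(c(-1, 0, 1), 0.75))
  # length-5 hand case against the same oracle
  x5 <- c(3, -2, 7, 0, 5)
  expect_equal(q_oracle(x5, 0.25), 0)
  expect_equal(q_oracle(x5, 0.75), 5)
})

test_that("default synthetic controls give centred residuals, reference IQR and a falling age trend", {
  pop <- make_pop(n_controls = 2243, n_cases = 0, seed = 19)
  m <- fit_expected_density(pop, "vpd_log")
  r <- residualize(m, pop$age_mammogram, pop$bmi, pop$vpd)
  expect_lt(abs(median(r)), 0.05)
  q <- residual_iqr(m)
  w <- unname(q["q75"] - q["q25"])
  expect_gt(w, 1.0)
  expect_lt(w, 1.8)
  # expected density decreases across the screening age range at median BMI
  bmi_med <- median(pop$bmi)
  pred <- function(age) -residualize(m, age, bmi_med, 10) # -resid = E - log(10)
  expect_gt(pred(45), pred(75))
})

test_that("out-of-range inputs are clamped and BI-RADS predictions stay in 1..4", {
  pop <- make_pop(n_controls = 500, n_cases = 0, seed = 14)
  m <- fit_expected_density(pop, "vpd_log")
  expect_warning(r_out <- residualize(m, 20, 25, 10), "clamped")
  r_edge <- residualize(m, min(pop$age_mammogram), 25, 10)
  expect_equal(r_out, r_edge, tolerance = 1e-12)

  mb <- fit_expected_density(pop, "birads_integer")
  grid <- expand.grid(age = seq(40, 79, 5), bmi = seq(18, 40, 4))
  # parts of the grid lie outside the training hull and are clamped
  pred <- 3 - suppressWarnings(residualize(mb, grid$age, grid$bmi, 3))
  expect_true(all(pred >= 1 & pred <= 4))
})

test_that("JSON serialization round-trips to identical predictions", {
  pop <- make_pop(n_controls = 400, n_cases = 0, seed = 16)
  m <- fit_expected_density(pop, "vpd_log")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path), add = TRUE)
  write_density_model(m, path)
  m2 <- read_density_model(path)
  r1 <- residualize(m, pop$age_mammogram, pop$bmi, pop$vpd)
  # boundary values may round by one ulp through JSON, clamping one point
  r2 <- suppressWarnings(residualize(m2, pop$age_mammogram, pop$bmi, pop$vpd))
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_equal(residual_iqr(m), residual_iqr(m2), tolerance = 1e-12)
})

test_that("the spline surface agrees with an independent penalized GAM", {
  pop <- make_pop(n_controls = 2000, n_cases = 0, seed = 23)
  m <- fit_expected_density(pop, "vpd_log")
  ours <- log(pop$vpd) - residualize(m, pop$age_mammogram, pop$bmi, pop$vpd)
  gam_fit <- mgcv::gam(log(vpd) ~ s(age_mammogram) + s(bmi), data = pop)
  theirs <- as.numeric(predict(gam_fit))
  expect_lt(sqrt(mean((ours - theirs)^2)), 0.1)
})

test_that("invalid inputs to fitting and residualization error clearly", {
  pop <- make_pop(n_controls = 300, n_cases = 60, seed = 4)
  expect_error(fit_expected_density(pop, "vpd_log"), "controls only")
  ctrl <- pop[pop$status == "control", ]
  expect_error(fit_expected_density(ctrl[1:5, ], "vpd_log"), "underdetermined")
  m <- fit_expected_density(ctrl, "vpd_log")
  expect_error(residualize(m, 50, 25, -2), "> 0")
  expect_error(residual_iqr(structure(list(), class = "expected_density_model")),
               "not been fitted")
})
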