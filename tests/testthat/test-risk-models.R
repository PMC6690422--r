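expand_2x2 <- function(a, b, c, d) {
  # a: exposed cases, b: exposed controls, c: unexposed cases, d: unexposed controls
  data.frame(
    case = rep(c(1, 0, 1, 0), c(a, b, c, d)),
    exposed = rep(c(1, 1, 0, 0), c(a, b, c, d))
  )
}

test_that("logistic coefficient on a binary predictor equals the closed-form crude OR", {
  for (cell in list(c(30, 70, 45, 55), c(12, 88, 60, 40), c(198, 660, 257, 1528))) {
    d <- expand_2x2(cell[1], cell[2], cell[3], cell[4])
    fit <- fit_adjusted_logistic(d, "exposed")
    or_glm <- exp(unname(fit$coefficients["exposed"]))
    or_crude <- (cell[1] * cell[4]) / (cell[2] * cell[3])
    expect_equal(or_glm, or_crude, tolerance = 1e-8)
  }
})

test_that("iq_or is analytic on the log-odds scale and scale invariant", {
  fake_fit <- function(b, se) {
    structure(list(coefficients = c(x = b),
                   vcov = matrix(se^2, 1, 1, dimnames = list("x", "x")),
                   terms = "x"),
              class = "logistic_fit")
  }
  expect_equal(iq_or(fake_fit(log(2), 0.1), 0, 1)$or, 2)
  expect_equal(iq_or(fake_fit(log(1.55) / 1.5, 0.1), -0.8, 0.7)$or, 1.55)
  r0 <- iq_or(fake_fit(0, 0.2), -1, 1)
  expect_equal(r0$or, 1)
  expect_true(r0$lo < 1 && r0$hi > 1)
  expect_error(iq_or(fake_fit(1, 0.1), 1, 1), "q75 > q25")

  # rescaling the residual column leaves the IQ-OR unchanged
  pop <- make_pop(n_controls = 800, n_cases = 400, seed = 6)
  res <- recover_iq_or(pop)
  d <- res$data
  d$res_scaled <- d$res * 3.7
  fit2 <- fit_adjusted_logistic(d, "res_scaled", standard_adjustments())
  q <- residual_iqr(res$model)
  or2 <- iq_or(fit2, 3.7 * q[["q25"]], 3.7 * q[["q75"]], term = "res_scaled")
  expect_equal(or2$or, res$iq_or$or, tolerance = 1e-6)
  expect_equal(or2$lo, res$iq_or$lo, tolerance = 1e-6)
})

test_that("lr_test compares nested fits and rejects non-nested ones", {
  pop <- prepare_analysis_data(make_pop(n_controls = 700, n_cases = 300, seed = 13))
  f0 <- fit_adjusted_logistic(pop, NULL, c("region", "education"))
  f1 <- fit_adjusted_logistic(pop, "bmi", c("region", "education"))
  same <- lr_test(f0, f0)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  out <- lr_test(f1, f0)
  expect_gte(out$chi2, 0)
  expect_equal(out$df, 1)
  f_other <- fit_adjusted_logistic(pop, "bmi", c("ethnicity"))
  expect_error(lr_test(f1, f_other), "not nested")
  # a predictor unrelated to status stays near zero
  pop$noise <- rnorm(nrow(pop))
  fn <- fit_adjusted_logistic(pop, "noise", standard_adjustments())
  z <- fn$coefficients["noise"] / sqrt(fn$vcov["noise", "noise"])
  expect_lt(abs(z), 3)
})

test_that("quantile grouping gives equal control groups and monotone ORs under a strong effect", {
  pop <- make_pop(n_controls = 2243, n_cases = 474, seed = 17,
                  beta_vpd = log(2.5) / 1.2)
  res <- recover_iq_or(pop)
  qg <- quantile_group_ors(res$data, "res", 5, standard_adjustments())
  expect_equal(qg$groups$n_controls, c(449L, 448L, 449L, 448L, 449L))
  expect_equal(sum(qg$groups$n_cases), 474L)
  expect_equal(qg$groups$or[1], 1)
  expect_gt(qg$groups$or[5], qg$groups$or[1])
  expect_gt(cor(qg$groups$or, 1:5), 0)
  expect_error(quantile_group_ors(res$data[1:30, ], "res", 5), "10 controls")
})

test_that("interaction_test detects a product term and rejects a constant modifier", {
  set.seed(71)
  n <- 4000
  d <- data.frame(x = rnorm(n), m = rbinom(n, 1, 0.5))
  eta <- -0.5 + 0.2 * d$x + 0.2 * d$m + log(2) * d$x * d$m
  d$case <- rbinom(n, 1, plogis(eta))
  strong <- interaction_test(d, "x", "m")
  expect_lt(strong$p, 0.05)
  expect_equal(strong$df, 1)

  d$eta_null <- NULL
  d2 <- d
  d2$case <- rbinom(n, 1, plogis(-0.5 + 0.2 * d2$x + 0.2 * d2$m))
  null <- interaction_test(d2, "x", "m")
  expect_gt(null$p, 0.001)

  d2$const <- 1
  expect_error(interaction_test(d2, "x", "const"), "constant")
})

test_that("bootstrap_compare is seeded, null at identity and sensitive to information", {
  pop <- make_pop(n_controls = 900, n_cases = 450, seed = 25)
  res <- recover_iq_or(pop)
  d <- res$data
  d$res_copy <- d$res
  same <- bootstrap_compare(d, "res", "res_copy",
                            adjustments = c("region", "bmi"),
                            n_boot = 199, seed = 2)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)

  set.seed(33)
  d$pure_noise <- rnorm(nrow(d))
  cmp1 <- bootstrap_compare(d, "res", "pure_noise",
                            adjustments = c("region", "bmi"),
                            n_boot = 199, seed = 7)
  cmp2 <- bootstrap_compare(d, "res", "pure_noise",
                            adjustments = c("region", "bmi"),
                            n_boot = 199, seed = 7)
  expect_identical(cmp1$p, cmp2$p)
  expect_gt(cmp1$delta, 0)
  expect_lt(cmp1$p, 0.05)
  expect_error(bootstrap_compare(d, "res", "pure_noise", n_boot = 50),
               ">= 199")
})

test_that("calibration coefficient recovers the generative risk slope", {
  pop <- prepare_analysis_data(make_pop(4000, 2000, seed = 41))
  cal <- calibration_coefficient(pop, "tc10")
  expect_gt(cal$slope_pct, 75)
  expect_lt(cal$slope_pct, 125)

  pop2 <- prepare_analysis_data(make_pop(4000, 2000, seed = 43, tc_coef = 2))
  cal2 <- calibration_coefficient(pop2, "tc10")
  expect_gt(cal2$slope_pct, 170)
  expect_lt(cal2$slope_pct, 230)

  # shuffling the risk column destroys the association
  pop$tc_shuffled <- sample(pop$tc10)
  cal0 <- calibration_coefficient(pop, "tc_shuffled")
  expect_lt(abs(cal0$slope_pct / cal0$se_pct), 3)

  pop$tc_const <- 5
  expect_error(calibration_coefficient(pop, "tc_const"), "variance")
})

test_that("nonlinearity_check keeps a linear effect and flags curvature", {
  set.seed(55)
  n <- 3000
  lin <- data.frame(x = rnorm(n))
  lin$case <- rbinom(n, 1, plogis(-0.3 + 0.5 * lin$x))
  out_lin <- nonlinearity_check(lin, "x")
  expect_gt(out_lin$p, 0.001)
  expect_equal(out_lin$df, 3)

  quad <- data.frame(x = rnorm(n))
  quad$case <- rbinom(n, 1, plogis(-1 + 0.6 * quad$x^2))
  out_quad <- nonlinearity_check(quad, "x")
  expect_lt(out_quad$p, 0.01)
})

test_that("degenerate designs are rejected with clear errors", {
  pop <- prepare_analysis_data(make_pop(200, 0, seed = 3))
  expect_error(fit_adjusted_logistic(pop, "bmi"), "degenerate outcome")
  pop2 <- prepare_analysis_data(make_pop(200, 50, seed = 3))
  expect_error(fit_adjusted_logistic(pop2, "missing_col"), "not found")
})
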