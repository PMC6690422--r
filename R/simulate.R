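#' Configuration for the synthetic case-control generator
#'
#' Builds and validates the parameter set used by [generate_population()].
#' Defaults emulate a screening-age case-control study of mammographic
#' density: 2,243 controls and 474 cases aged 40--79, control 10-year
#' baseline risk with median 3.17% (IQR 2.35--4.56), volumetric percent
#' density (VPD) log-normal with negative age and BMI trends (Spearman
#' targets about -0.25 and -0.56 in controls), manufacturer VPD grade
#' cutoffs 4.6 / 7.6 / 15.4 percent, and a default density effect equal to
#' an interquartile odds ratio of 1.40 on the control residual scale.
#'
#' @param n_controls,n_cases number of control / case records.
#' @param seed master seed; all draws flow through named substreams so that
#'   adding a variable to the generator does not perturb existing streams.
#' @param age_range inclusive age range (years) at mammogram.
#' @param age_mean,age_sd location/scale of the (truncated normal) control
#'   age distribution.
#' @param bmi_log_mean,bmi_log_sd log-scale location/scale of the
#'   (log-normal) BMI distribution, kg/m^2.
#' @param beta_vpd log-odds of case status per unit ln-VPD residual.
#' @param beta_birads log-odds of case status per unit BI-RADS integer
#'   residual (deviation of the noisy grade from its age/BMI expectation).
#' @param density_intercept mean ln VPD at the age/BMI centring point.
#' @param density_age_slope,density_bmi_slope change in mean ln VPD per year
#'   of age / per kg/m^2 of BMI.
#' @param density_sd SD of ln VPD about its age/BMI expectation (the control
#'   residual SD; the implied residual IQR is 1.349 * density_sd).
#' @param birads_cutoffs three increasing VPD percent thresholds mapping the
#'   volumetric scale onto the four density grades.
#' @param birads_noise_sd SD (ln-VPD scale) of the latent reader noise added
#'   before thresholding to produce the clinical BI-RADS grade. The default
#'   is calibrated so that generated BI-RADS x VPD-grade cross-tabs have a
#'   linear weighted kappa near 0.64.
#' @param demographic_prevalences named list; each element has `levels`
#'   (first level is the reference), `control_prob` (control prevalences,
#'   summing to 1) and `case_or` (odds ratio vs reference, first element 1).
#' @param tc_risk_median_pct,tc_risk_iqr_pct control median and IQR of the
#'   baseline 10-year risk, in percent.
#' @param tc_coef log-odds of case status per unit ln baseline risk; 1 means
#'   the baseline model's relative risks are fully expressed (calibration
#'   slope 100%).
#' @param volume_median_cm3,volume_bmi_slope,volume_sd total breast volume
#'   model: log-normal with median `volume_median_cm3`, log-volume slope on
#'   ln BMI, and residual SD on the log scale.
#' @param vpd_bounds admissible open interval for generated VPD (percent);
#'   residuals are redrawn on the rare occasions the bound is exceeded.
#'
#' @return An object of class `generator_config` (a validated list).
#' @seealso [generate_population()], [assign_birads()]
#' @export
generator_config <- function(n_controls = 2243,
                             n_cases = 474,
                             seed = 1,
                             age_range = c(40, 79),
                             age_mean = 59,
                             age_sd = 9.5,
                             bmi_log_mean = log(25.6),
                             bmi_log_sd = 0.2075,
                             beta_vpd = log(1.40) / (2 * qnorm(0.75) * 0.9),
                             beta_birads = 0,
                             density_intercept = log(7),
                             density_age_slope = -0.034,
                             density_bmi_slope = -0.12,
                             density_sd = 0.9,
                             birads_cutoffs = c(4.6, 7.6, 15.4),
                             birads_noise_sd = 0.70,
                             demographic_prevalences = default_demographics(),
                             tc_risk_median_pct = 3.17,
                             tc_risk_iqr_pct = c(2.35, 4.56),
                             tc_coef = 1,
                             volume_median_cm3 = 700,
                             volume_bmi_slope = 1.6,
                             volume_sd = 0.25,
                             vpd_bounds = c(0.2, 97)) {
  cfg <- list(
    n_controls = n_controls, n_cases = n_cases, seed = seed,
    age_range = age_range, age_mean = age_mean, age_sd = age_sd,
    bmi_log_mean = bmi_log_mean, bmi_log_sd = bmi_log_sd,
    beta_vpd = beta_vpd, beta_birads = beta_birads,
    density_intercept = density_intercept,
    density_age_slope = density_age_slope,
    density_bmi_slope = density_bmi_slope,
    density_sd = density_sd,
    birads_cutoffs = birads_cutoffs,
    birads_noise_sd = birads_noise_sd,
    demographic_prevalences = demographic_prevalences,
    tc_risk_median_pct = tc_risk_median_pct,
    tc_risk_iqr_pct = tc_risk_iqr_pct,
    tc_coef = tc_coef,
    volume_median_cm3 = volume_median_cm3,
    volume_bmi_slope = volume_bmi_slope,
    volume_sd = volume_sd,
    vpd_bounds = vpd_bounds
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

#' Default demographic covariates of the generator
#'
#' Five binary/ternary covariates with control prevalences and crude case
#' odds ratios matching a public-institution screening case-control setting
#' (reference level first). Case effects act as independent multiplicative
#' odds factors.
#'
#' @return Named list usable as `demographic_prevalences` in
#'   [generator_config()].
#' @export
default_demographics <- function() {
  list(
    region = list(levels = c("primary", "outlying"),
                  control_prob = c(1028, 1215) / 2243,
                  case_or = c(1, 1.90)),
    insurance = list(levels = c("insured", "medicaid", "none"),
                     control_prob = c(1528, 660, 55) / 2243,
                     case_or = c(1, 1.78, 2.05)),
    financial_screen = list(levels = c("never", "ever"),
                            control_prob = c(2121, 122) / 2243,
                            case_or = c(1, 3.16)),
    education = list(levels = c("more", "less"),
                     control_prob = c(1503, 740) / 2243,
                     case_or = c(1, 1.93)),
    ethnicity = list(levels = c("white", "other"),
                     control_prob = c(2036, 207) / 2243,
                     case_or = c(1, 2.00))
  )
}

validate_generator_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid generator configuration: field '%s' %s",
                 field, why), call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(cfg$n_controls) || cfg$n_controls <= 0 ||
      cfg$n_controls != round(cfg$n_controls)) {
    fail("n_controls", "must be a positive integer")
  }
  if (!num1(cfg$n_cases) || cfg$n_cases < 0 ||
      cfg$n_cases != round(cfg$n_cases)) {
    fail("n_cases", "must be a non-negative integer")
  }
  if (!num1(cfg$seed)) fail("seed", "must be a single number")
  if (!is.numeric(cfg$age_range) || length(cfg$age_range) != 2L ||
      cfg$age_range[1] >= cfg$age_range[2]) {
    fail("age_range", "must be an increasing pair of ages")
  }
  if (!num1(cfg$density_sd) || cfg$density_sd <= 0) {
    fail("density_sd", "must be > 0")
  }
  if (!is.numeric(cfg$birads_cutoffs) || length(cfg$birads_cutoffs) != 3L ||
      any(diff(cfg$birads_cutoffs) <= 0) || any(cfg$birads_cutoffs <= 0)) {
    fail("birads_cutoffs", "must be three strictly increasing positive values")
  }
  if (!num1(cfg$birads_noise_sd) || cfg$birads_noise_sd < 0) {
    fail("birads_noise_sd", "must be >= 0")
  }
  if (!num1(cfg$tc_risk_median_pct) || cfg$tc_risk_median_pct <= 0) {
    fail("tc_risk_median_pct", "must be > 0")
  }
  if (!is.numeric(cfg$tc_risk_iqr_pct) || length(cfg$tc_risk_iqr_pct) != 2L ||
      cfg$tc_risk_iqr_pct[1] <= 0 ||
      cfg$tc_risk_iqr_pct[1] >= cfg$tc_risk_iqr_pct[2]) {
    fail("tc_risk_iqr_pct", "must be an increasing positive pair")
  }
  if (!is.list(cfg$demographic_prevalences)) {
    fail("demographic_prevalences", "must be a named list of covariates")
  }
  for (nm in names(cfg$demographic_prevalences)) {
    d <- cfg$demographic_prevalences[[nm]]
    if (!all(c("levels", "control_prob", "case_or") %in% names(d)) ||
        length(d$levels) != length(d$control_prob) ||
        length(d$levels) != length(d$case_or)) {
      fail(paste0("demographic_prevalences$", nm),
           "must have matching levels/control_prob/case_or")
    }
    if (any(d$control_prob <= 0) || any(d$control_prob >= 1) ||
        abs(sum(d$control_prob) - 1) > 1e-8) {
      fail(paste0("demographic_prevalences$", nm),
           "control_prob must lie in (0,1) and sum to 1")
    }
    if (any(d$case_or <= 0) || d$case_or[1] != 1) {
      fail(paste0("demographic_prevalences$", nm),
           "case_or must be positive with reference level 1")
    }
  }
  if (!is.numeric(cfg$vpd_bounds) || length(cfg$vpd_bounds) != 2L ||
      cfg$vpd_bounds[1] <= 0 || cfg$vpd_bounds[2] >= 100 ||
      cfg$vpd_bounds[1] >= cfg$vpd_bounds[2]) {
    fail("vpd_bounds", "must be increasing and inside (0, 100)")
  }
  invisible(cfg)
}

#' Map volumetric percent density to a four-level density grade
#'
#' Thresholds ln(VPD) (plus optional latent reader noise) against the log of
#' three increasing percent cutoffs, yielding grades 1 (fatty) to 4 (dense).
#' A value exactly on a cutoff falls in the upper grade, so the grade bands
#' are `<c1`, `c1-<c2`, `c2-<c3`, `c3+`. With `noise_sd = 0` (and no
#' supplied noise) the binning is deterministic.
#'
#' @param vpd volumetric percent density, > 0.
#' @param cutoffs three strictly increasing percent thresholds.
#' @param noise_sd SD of latent Gaussian noise on the ln-VPD scale.
#' @param noise optional explicit noise vector (recycled); when `NULL` and
#'   `noise_sd > 0`, noise is drawn from the current RNG stream.
#' @return Integer vector of grades in 1..4.
#' @export
assign_birads <- function(vpd, cutoffs = c(4.6, 7.6, 15.4),
                          noise_sd = 0, noise = NULL) {
  if (any(!is.finite(vpd)) || any(vpd <= 0)) {
    stop("assign_birads: 'vpd' must be positive and finite", call. = FALSE)
  }
  if (length(cutoffs) != 3L || any(diff(cutoffs) <= 0) || any(cutoffs <= 0)) {
    stop("assign_birads: 'cutoffs' must be three strictly increasing positive values",
         call. = FALSE)
  }
  if (is.null(noise)) {
    noise <- if (noise_sd > 0) rnorm(length(vpd), 0, noise_sd) else 0
  }
  findInterval(log(vpd) + noise, log(cutoffs)) + 1L
}

# E[grade | latent mean mu, latent sd]: used to define the BI-RADS integer
# residual at generation time without reference to any fitted model.
expected_grade <- function(mu, log_cutoffs, latent_sd) {
  p_le <- vapply(log_cutoffs,
                 function(ct) pnorm((ct - mu) / latent_sd),
                 numeric(length(mu)))
  p_le <- matrix(p_le, nrow = length(mu))
  # P(grade > k) summed over k = 0..3 gives E[grade] - 1 + 1
  1 + rowSums(1 - p_le)
}

age_bin_breaks <- function(age_range) {
  lo <- 5 * floor(age_range[1] / 5)
  hi <- 5 * ceiling((age_range[2] + 1) / 5)
  seq(lo, hi, by = 5)
}

#' Five-year age group labels
#'
#' @param age numeric ages.
#' @param age_range inclusive range used to define the bins.
#' @return Factor of labels such as `"55-59"`.
#' @export
age_group_5y <- function(age, age_range = c(40, 79)) {
  br <- age_bin_breaks(age_range)
  labs <- paste0(head(br, -1), "-", br[-1] - 1)
  cut(age, breaks = br, labels = labs, right = FALSE)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Largest-remainder apportionment of n into shares proportional to w.
apportion <- function(n, w) {
  q <- n * w / sum(w)
  k <- floor(q)
  r <- n - sum(k)
  if (r > 0) {
    idx <- order(q - k, decreasing = TRUE)[seq_len(r)]
    k[idx] <- k[idx] + 1
  }
  as.integer(k)
}

# Draw (vpd residual, reader noise, grade) for `mu` = expected ln VPD.
# For cases the residual proposal is the exact exponential tilt of the
# control law by beta_vpd, and a rejection step applies the BI-RADS
# residual effect beta_birads; VPD bound violations are redrawn.
draw_density <- function(mu, cfg, tilted) {
  n <- length(mu)
  sd_e <- cfg$density_sd
  lct <- log(cfg$birads_cutoffs)
  latent_sd <- sqrt(sd_e^2 + cfg$birads_noise_sd^2)
  prop_mean <- if (tilted) cfg$beta_vpd * sd_e^2 else 0
  bb <- if (tilted) cfg$beta_birads else 0
  eg <- if (bb != 0) expected_grade(mu, lct, latent_sd) else NULL
  cb <- abs(bb) * 3  # |grade - E[grade]| <= 3
  lb <- log(cfg$vpd_bounds)

  resid <- numeric(n)
  noise <- numeric(n)
  grade <- integer(n)
  need <- seq_len(n)
  for (iter in 1:1000) {
    if (!length(need)) break
    m <- length(need)
    r <- rnorm(m, prop_mean, sd_e)
    u <- rnorm(m, 0, cfg$birads_noise_sd)
    lv <- mu[need] + r
    g <- findInterval(lv + u, lct) + 1L
    acc <- lv > lb[1] & lv < lb[2]
    if (bb != 0) {
      acc <- acc & (log(runif(m)) < bb * (g - eg[need]) - cb)
    }
    idx <- need[acc]
    resid[idx] <- r[acc]
    noise[idx] <- u[acc]
    grade[idx] <- g[acc]
    need <- need[!acc]
  }
  if (length(need)) {
    stop("density rejection sampler failed to converge", call. = FALSE)
  }
  list(resid = resid, noise = noise, grade = grade)
}

sample_categorical <- function(n, levels, prob) {
  factor(sample(levels, n, replace = TRUE, prob = prob), levels = levels)
}

#' Generate a synthetic case-control population
#'
#' Simulates participant records with the joint structure the downstream
#' analysis assumes: ln VPD linear in age and BMI with Gaussian residual;
#' BI-RADS grade from latent noisy ln VPD against the grade cutoffs; fat and
#' fibroglandular volumes consistent with `vpd = 100 * fibro / (fibro + fat)`
#' exactly; baseline 10-year risk log-normal; demographic covariates with
#' independent multiplicative case odds; case log-odds containing
#' `beta_vpd * (VPD residual) + beta_birads * (grade residual) +
#' tc_coef * ln(tc10)` plus the covariate effects; and cases
#' frequency-matched to the control 5-year age distribution.
#'
#' Case records are drawn by exact exponential tilting of the (factorized)
#' control distribution, with a rejection step for the grade-residual
#' effect, which preserves all logistic coefficients under case-control
#' sampling.
#'
#' @param config a [generator_config()].
#' @return `data.frame` with one row per participant and columns `id`,
#'   `status` (`control`/`case`), `age_mammogram`, `age_group`, `bmi`, the
#'   demographic covariates, `tc10` (percent), `vpd` (percent),
#'   `fibro_volume`, `fat_volume` (cm^3) and `birads` (integer 1--4).
#' @export
generate_population <- function(config = generator_config()) {
  if (!inherits(config, "generator_config")) {
    config <- do.call(generator_config, config)
  }
  validate_generator_config(config)
  cfg <- config
  seed <- cfg$seed
  n0 <- cfg$n_controls
  n1 <- cfg$n_cases

  # ---- controls -----------------------------------------------------------
  age0 <- with_substream(seed, "control_age",
    rtrunc_norm(n0, cfg$age_mean, cfg$age_sd,
                cfg$age_range[1], cfg$age_range[2] + 1))
  bmi0 <- with_substream(seed, "control_bmi",
    exp(rnorm(n0, cfg$bmi_log_mean, cfg$bmi_log_sd)))
  demog0 <- lapply(names(cfg$demographic_prevalences), function(nm) {
    d <- cfg$demographic_prevalences[[nm]]
    with_substream(seed, paste0("control_demog_", nm),
      sample_categorical(n0, d$levels, d$control_prob))
  })
  names(demog0) <- names(cfg$demographic_prevalences)
  sd_tc <- diff(log(cfg$tc_risk_iqr_pct)) / (2 * qnorm(0.75))
  mu_tc <- log(cfg$tc_risk_median_pct)
  tc0 <- with_substream(seed, "control_tc10", exp(rnorm(n0, mu_tc, sd_tc)))
  mu_dens0 <- cfg$density_intercept +
    cfg$density_age_slope * (age0 - cfg$age_mean) +
    cfg$density_bmi_slope * (bmi0 - exp(cfg$bmi_log_mean))
  dd0 <- with_substream(seed, "control_density",
    draw_density(mu_dens0, cfg, tilted = FALSE))

  # ---- cases --------------------------------------------------------------
  br <- age_bin_breaks(cfg$age_range)
  bin0 <- findInterval(age0, br)
  counts0 <- tabulate(bin0, nbins = length(br) - 1)
  case_counts <- if (n1 > 0) apportion(n1, counts0 / n0) else integer(length(counts0))
  age1 <- with_substream(seed, "case_age", {
    unlist(lapply(seq_along(case_counts), function(b) {
      if (case_counts[b] == 0) return(numeric(0))
      rtrunc_norm(case_counts[b], cfg$age_mean, cfg$age_sd,
                  max(br[b], cfg$age_range[1]),
                  min(br[b + 1], cfg$age_range[2] + 1))
    }))
  })
  bmi1 <- with_substream(seed, "case_bmi",
    exp(rnorm(n1, cfg$bmi_log_mean, cfg$bmi_log_sd)))
  demog1 <- lapply(names(cfg$demographic_prevalences), function(nm) {
    d <- cfg$demographic_prevalences[[nm]]
    p1 <- d$control_prob * d$case_or
    with_substream(seed, paste0("case_demog_", nm),
      sample_categorical(n1, d$levels, p1 / sum(p1)))
  })
  names(demog1) <- names(cfg$demographic_prevalences)
  tc1 <- with_substream(seed, "case_tc10",
    exp(rnorm(n1, mu_tc + cfg$tc_coef * sd_tc^2, sd_tc)))
  mu_dens1 <- cfg$density_intercept +
    cfg$density_age_slope * (age1 - cfg$age_mean) +
    cfg$density_bmi_slope * (bmi1 - exp(cfg$bmi_log_mean))
  dd1 <- with_substream(seed, "case_density",
    draw_density(mu_dens1, cfg, tilted = TRUE))

  # ---- assemble -----------------------------------------------------------
  age <- c(age0, age1)
  bmi <- c(bmi0, bmi1)
  vpd <- exp(c(mu_dens0 + dd0$resid, mu_dens1 + dd1$resid))
  log_total <- with_substream(seed, "breast_volume",
    log(cfg$volume_median_cm3) +
      cfg$volume_bmi_slope * (log(bmi) - cfg$bmi_log_mean) +
      rnorm(n0 + n1, 0, cfg$volume_sd))
  total <- exp(log_total)
  fibro <- total * vpd / 100
  fat <- total - fibro

  out <- data.frame(
    id = c(sprintf("ctrl_%05d", seq_len(n0)),
           if (n1 > 0) sprintf("case_%05d", seq_len(n1))),
    status = factor(rep(c("control", "case"), c(n0, n1)),
                    levels = c("control", "case")),
    age_mammogram = age,
    age_group = age_group_5y(age, cfg$age_range),
    bmi = bmi,
    stringsAsFactors = FALSE
  )
  for (nm in names(demog0)) {
    out[[nm]] <- factor(c(as.character(demog0[[nm]]),
                          as.character(demog1[[nm]])),
                        levels = levels(demog0[[nm]]))
  }
  out$tc10 <- c(tc0, tc1)
  out$vpd <- vpd
  out$fibro_volume <- fibro
  out$fat_volume <- fat
  out$birads <- c(dd0$grade, dd1$grade)
  out
}

#' Summaries of a generated or observed population
#'
#' Per-status medians and IQRs of age, BMI, baseline risk and density
#' measures; demographic prevalences; the BI-RADS grade distribution; and
#' Spearman correlations of the density measures with age and BMI among
#' controls.
#'
#' @param tab participant table as from [generate_population()].
#' @return List with elements `n`, `continuous`, `categorical`,
#'   `correlations`.
#' @export
summarize_population <- function(tab) {
  if (is.null(tab) || nrow(tab) == 0) {
    stop("summarize_population: empty participant table", call. = FALSE)
  }
  med_iqr <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE, type = 7)
    c(median = q[2], q25 = q[1], q75 = q[3])
  }
  cont_vars <- intersect(c("age_mammogram", "bmi", "tc10", "vpd",
                           "fibro_volume", "fat_volume"), names(tab))
  by_status <- split(tab, tab$status)
  continuous <- lapply(by_status, function(d) {
    if (nrow(d) == 0) return(NULL)
    t(vapply(cont_vars, function(v) med_iqr(d[[v]]), numeric(3)))
  })
  cat_vars <- intersect(c("region", "insurance", "financial_screen",
                          "education", "ethnicity", "birads"), names(tab))
  categorical <- lapply(by_status, function(d) {
    if (nrow(d) == 0) return(NULL)
    lapply(setNames(cat_vars, cat_vars),
           function(v) prop.table(table(d[[v]])))
  })
  ctrl <- tab[tab$status == "control", , drop = FALSE]
  dens_vars <- intersect(c("vpd", "fibro_volume", "fat_volume"), names(tab))
  correlations <- if (nrow(ctrl) >= 3) {
    sapply(dens_vars, function(v) {
      c(age = spearman_rho(ctrl[[v]], ctrl$age_mammogram),
        bmi = spearman_rho(ctrl[[v]], ctrl$bmi))
    })
  } else NULL
  list(
    n = table(tab$status),
    continuous = continuous,
    categorical = categorical,
    correlations = correlations
  )
}
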