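#' Prepare a participant table for adjusted logistic modelling
#'
#' Adds the derived analysis columns: `age_group` (5-year-bin factor, the
#' matching variable, entered as indicators), `log_tc10` (natural log of the
#' baseline 10-year risk), and a 0/1 `case` outcome. Categorical covariates
#' with missing values get an explicit `"Unknown"` level; rows with missing
#' continuous covariates are dropped with a message.
#'
#' @param tab participant table.
#' @param age_range range used for the age bins.
#' @return The augmented table.
#' @export
prepare_analysis_data <- function(tab, age_range = c(40, 79)) {
  stopifnot("status" %in% names(tab))
  tab$case <- as.integer(tab$status == "case")
  if (!"age_group" %in% names(tab) && "age_mammogram" %in% names(tab)) {
    tab$age_group <- age_group_5y(tab$age_mammogram, age_range)
  }
  if ("age_group" %in% names(tab)) tab$age_group <- droplevels(factor(tab$age_group))
  if ("tc10" %in% names(tab)) {
    if (any(tab$tc10 <= 0, na.rm = TRUE)) {
      stop("prepare_analysis_data: tc10 must be > 0", call. = FALSE)
    }
    tab$log_tc10 <- log(tab$tc10)
  }
  for (v in names(tab)) {
    if (is.factor(tab[[v]]) && anyNA(tab[[v]])) {
      levels(tab[[v]]) <- c(levels(tab[[v]]), "Unknown")
      tab[[v]][is.na(tab[[v]])] <- "Unknown"
    }
  }
  num_cols <- names(tab)[vapply(tab, is.numeric, logical(1))]
  bad <- rowSums(is.na(tab[, num_cols, drop = FALSE])) > 0
  if (any(bad)) {
    message(sprintf("prepare_analysis_data: dropped %d row(s) with missing continuous values",
                    sum(bad)))
    tab <- tab[!bad, , drop = FALSE]
  }
  tab
}

#' Standard adjustment set
#'
#' The covariates the adjusted density odds ratios condition on: 5-year age
#' group (matching variable), region, insurance, financial screening,
#' education, ethnicity, BMI and log baseline 10-year risk.
#'
#' @return Character vector of column names.
#' @export
standard_adjustments <- function() {
  c("age_group", "region", "insurance", "financial_screen",
    "education", "ethnicity", "bmi", "log_tc10")
}

#' Adjusted case-control logistic regression
#'
#' Maximum-likelihood logistic fit of case status on a predictor plus an
#' adjustment set, by iteratively reweighted least squares with a tight
#' convergence tolerance. Categorical terms are indicator-coded with their
#' first level as reference. Separation is flagged through extreme
#' coefficients.
#'
#' @param tab table from [prepare_analysis_data()] (must contain `case`).
#' @param predictor name of the predictor column (or `NULL` for a
#'   covariates-only null model); may also be a vector of names.
#' @param adjustments character vector of adjustment columns (possibly
#'   empty).
#' @param extra_terms optional raw formula terms (e.g. interaction products)
#'   appended verbatim.
#' @return Object of class `logistic_fit` with elements `coefficients`,
#'   `vcov`, `loglik`, `n_cases`, `n_controls`, `terms`, `converged`,
#'   `design` and the underlying `glm` object.
#' @export
fit_adjusted_logistic <- function(tab, predictor, adjustments = character(0),
                                  extra_terms = character(0)) {
  if (!"case" %in% names(tab)) {
    stop("fit_adjusted_logistic: run prepare_analysis_data() first ('case' column missing)",
         call. = FALSE)
  }
  if (length(unique(tab$case)) < 2) {
    stop("fit_adjusted_logistic: degenerate outcome (all cases or all controls)",
         call. = FALSE)
  }
  rhs <- c(predictor, adjustments, extra_terms)
  missing_cols <- setdiff(c(predictor, adjustments), names(tab))
  if (length(missing_cols)) {
    stop(sprintf("fit_adjusted_logistic: column(s) not found: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (v in c(predictor, adjustments)) {
    x <- tab[[v]]
    if (length(unique(x[!is.na(x)])) < 2) {
      stop(sprintf("fit_adjusted_logistic: term '%s' is constant (collinear)", v),
           call. = FALSE)
    }
  }
  if (!length(rhs)) rhs <- "1"
  fm <- as.formula(paste("case ~", paste(rhs, collapse = " + ")))
  fit <- glm(fm, family = binomial(), data = tab,
             control = glm.control(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) {
    stop("fit_adjusted_logistic: IRLS did not converge (possible separation)",
         call. = FALSE)
  }
  cf <- coef(fit)
  if (anyNA(cf)) {
    warning(sprintf("fit_adjusted_logistic: aliased term(s) dropped: %s",
                    paste(names(cf)[is.na(cf)], collapse = ", ")))
  }
  big <- names(cf)[!is.na(cf) & abs(cf) > 15]
  if (length(big)) {
    stop(sprintf("fit_adjusted_logistic: separation suspected for term(s): %s",
                 paste(big, collapse = ", ")), call. = FALSE)
  }
  out <- list(
    coefficients = cf,
    vcov = vcov(fit),
    loglik = as.numeric(logLik(fit)),
    n_cases = sum(tab$case == 1),
    n_controls = sum(tab$case == 0),
    n = nrow(fit$model),
    terms = rhs[rhs != "1"],
    formula = fm,
    converged = fit$converged,
    design = paste(rhs, collapse = " + "),
    glm = fit
  )
  class(out) <- "logistic_fit"
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Adjusted logistic fit:", deparse(x$formula), "\n")
  cat(sprintf("  %d cases / %d controls; log-likelihood %.3f\n",
              x$n_cases, x$n_controls, x$loglik))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Interquartile odds ratio
#'
#' Odds ratio (and Wald 95% CI on the log-odds scale) for a change from the
#' 25th to the 75th percentile of the control residual distribution:
#' `OR = exp(coef * (q75 - q25))`.
#'
#' @param fit a [fit_adjusted_logistic()] fit.
#' @param term coefficient name of the density term (default: the fit's
#'   first term).
#' @param q25,q75 control residual quartiles (e.g. from [residual_iqr()]).
#' @param conf confidence level.
#' @return List of class `iq_or` with `or`, `lo`, `hi`, `iqr_width`, `coef`,
#'   `se`.
#' @export
iq_or <- function(fit, q25, q75, term = fit$terms[1], conf = 0.95) {
  if (q75 <= q25) stop("iq_or: require q75 > q25", call. = FALSE)
  if (!term %in% names(fit$coefficients)) {
    stop(sprintf("iq_or: term '%s' not in fit", term), call. = FALSE)
  }
  b <- unname(fit$coefficients[term])
  se <- sqrt(fit$vcov[term, term])
  w <- q75 - q25
  z <- qnorm(1 - (1 - conf) / 2)
  out <- list(or = exp(b * w),
              lo = exp((b - z * se) * w),
              hi = exp((b + z * se) * w),
              iqr_width = w, coef = b, se = se)
  class(out) <- "iq_or"
  out
}

#' @export
print.iq_or <- function(x, ...) {
  cat(sprintf("IQ-OR %.2f (95%% CI %.2f-%.2f); IQR width %.3f\n",
              x$or, x$lo, x$hi, x$iqr_width))
  invisible(x)
}

#' Likelihood-ratio test of nested logistic fits
#'
#' @param fit_full,fit_null nested [fit_adjusted_logistic()] fits on the
#'   same rows (the null model's terms must be a subset of the full
#'   model's).
#' @return List `chi2`, `df`, `p`.
#' @export
lr_test <- function(fit_full, fit_null) {
  stopifnot(inherits(fit_full, "logistic_fit"), inherits(fit_null, "logistic_fit"))
  if (fit_full$n != fit_null$n) {
    stop("lr_test: fits use different numbers of rows", call. = FALSE)
  }
  full_terms <- colnames(model.matrix(fit_full$glm))
  null_terms <- colnames(model.matrix(fit_null$glm))
  if (!all(null_terms %in% full_terms)) {
    stop("lr_test: models are not nested", call. = FALSE)
  }
  df <- length(full_terms) - length(null_terms)
  chi2 <- max(0, 2 * (fit_full$loglik - fit_null$loglik))
  list(chi2 = chi2, df = df,
       p = if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else 1)
}

#' Interaction (effect heterogeneity) test
#'
#' Likelihood-ratio test of a predictor-by-modifier product term on top of
#' the adjusted main-effects model.
#'
#' @inheritParams fit_adjusted_logistic
#' @param modifier modifier column name (continuous or binary).
#' @return List `chi2`, `df`, `p`.
#' @export
interaction_test <- function(tab, predictor, modifier,
                             adjustments = character(0)) {
  adj <- union(adjustments, modifier)
  fit0 <- fit_adjusted_logistic(tab, predictor, adj)
  fit1 <- fit_adjusted_logistic(tab, predictor, adj,
                                extra_terms = paste0(predictor, ":", modifier))
  lr_test(fit1, fit0)
}

#' Check of linearity in the density residual
#'
#' Likelihood-ratio test of a cubic-spline expansion of the residual against
#' the linear-in-residual model, both with the same adjustments. A small p
#' rejects linearity.
#'
#' @inheritParams fit_adjusted_logistic
#' @param residual_col residual column name.
#' @param df spline degrees of freedom for the flexible alternative.
#' @return List `chi2`, `df`, `p`.
#' @export
nonlinearity_check <- function(tab, residual_col,
                               adjustments = character(0), df = 4) {
  fit_lin <- fit_adjusted_logistic(tab, residual_col, adjustments)
  fit_spl <- fit_adjusted_logistic(
    tab, NULL, adjustments,
    extra_terms = sprintf("splines::bs(%s, df = %d)", residual_col, df))
  # the spline span contains the linear term, so the models are nested even
  # though the linear column is not literally present in the larger design
  df_diff <- sum(!is.na(coef(fit_spl$glm))) - sum(!is.na(coef(fit_lin$glm)))
  chi2 <- max(0, 2 * (fit_spl$loglik - fit_lin$loglik))
  list(chi2 = chi2, df = df_diff,
       p = if (df_diff > 0) pchisq(chi2, df_diff, lower.tail = FALSE) else 1)
}

#' Bootstrap comparison of the predictive ability of two density measures
#'
#' The statistic is the difference in added likelihood-ratio chi-square
#' (measure A minus measure B, each against the covariates-only model).
#' Participants are resampled with replacement within case/control strata;
#' the two-sided p-value comes from the bootstrap distribution centred at
#' the observed difference.
#'
#' @inheritParams fit_adjusted_logistic
#' @param predictor_a,predictor_b residual column names being compared.
#' @param n_boot number of bootstrap replicates (>= 199).
#' @param seed RNG seed for the resampling.
#' @return List `delta` (observed LR-chi2 difference), `p`, `n_boot_used`,
#'   `n_failed`, plus the two observed LR statistics.
#' @export
bootstrap_compare <- function(tab, predictor_a, predictor_b,
                              adjustments = character(0),
                              n_boot = 499, seed = 1) {
  if (n_boot < 199) stop("bootstrap_compare: n_boot must be >= 199", call. = FALSE)
  lr_stat <- function(d) {
    f0 <- fit_adjusted_logistic(d, NULL, adjustments)
    fa <- fit_adjusted_logistic(d, predictor_a, adjustments)
    fb <- fit_adjusted_logistic(d, predictor_b, adjustments)
    c(a = lr_test(fa, f0)$chi2, b = lr_test(fb, f0)$chi2)
  }
  obs <- lr_stat(tab)
  delta <- unname(obs["a"] - obs["b"])
  idx_case <- which(tab$case == 1)
  idx_ctrl <- which(tab$case == 0)
  deltas <- rep(NA_real_, n_boot)
  with_substream(seed, "bootstrap_compare", {
    for (b in seq_len(n_boot)) {
      idx <- c(sample(idx_case, length(idx_case), replace = TRUE),
               sample(idx_ctrl, length(idx_ctrl), replace = TRUE))
      st <- try(lr_stat(tab[idx, , drop = FALSE]), silent = TRUE)
      if (!inherits(st, "try-error")) deltas[b] <- st["a"] - st["b"]
    }
  })
  ok <- !is.na(deltas)
  if (mean(!ok) > 0.05) {
    warning(sprintf("bootstrap_compare: %d/%d replicates failed and were dropped",
                    sum(!ok), n_boot))
  }
  centred <- deltas[ok] - delta
  p <- (1 + sum(abs(centred) >= abs(delta))) / (sum(ok) + 1)
  list(delta = delta, p = p,
       lr_a = unname(obs["a"]), lr_b = unname(obs["b"]),
       n_boot_used = sum(ok), n_failed = sum(!ok))
}

# Quantile-group boundaries from control values: boundaries at the order
# statistics round(i * n / k), reproducing equal control groups (+/- 1).
control_quantile_groups <- function(values, is_control, n_groups) {
  v0 <- values[is_control]
  n0 <- length(v0)
  srt <- sort(v0)
  cuts <- srt[round(seq_len(n_groups - 1) * n0 / n_groups)]
  # controls grouped by rank so exact group sizes hold even with ties
  grp <- integer(length(values))
  rk <- rank(v0, ties.method = "first")
  bounds_r <- round(seq_len(n_groups) * n0 / n_groups)
  grp[is_control] <- findInterval(rk - 1, c(0, bounds_r))
  grp[!is_control] <- 1L + vapply(values[!is_control],
                                  function(x) sum(x > cuts), integer(1))
  list(group = grp, cuts = cuts)
}

#' Odds ratios across quantile groups of a density residual
#'
#' Splits the residual into `n_groups` groups with boundaries at control
#' quantiles (controls split into equal groups up to +/- 1) and fits an
#' indicator-coded adjusted logistic model with the least-dense group as
#' reference.
#'
#' @inheritParams fit_adjusted_logistic
#' @param residual_col residual column name.
#' @param n_groups number of groups (default quintiles).
#' @return List with a per-group data frame (`n_controls`, `n_cases`, `or`,
#'   `lo`, `hi`), the cut points, and the underlying fit.
#' @export
quantile_group_ors <- function(tab, residual_col, n_groups = 5,
                               adjustments = character(0)) {
  if (n_groups < 2) stop("quantile_group_ors: n_groups must be >= 2", call. = FALSE)
  is_ctrl <- tab$case == 0
  qg <- control_quantile_groups(tab[[residual_col]], is_ctrl, n_groups)
  if (min(tabulate(qg$group[is_ctrl], n_groups)) < 10) {
    stop("quantile_group_ors: fewer than 10 controls in a group", call. = FALSE)
  }
  tab$.qgroup <- factor(qg$group, levels = seq_len(n_groups))
  fit <- fit_adjusted_logistic(tab, ".qgroup", adjustments)
  z <- qnorm(0.975)
  or <- lo <- hi <- rep(1, n_groups)
  for (g in 2:n_groups) {
    nm <- paste0(".qgroup", g)
    b <- unname(fit$coefficients[nm])
    se <- sqrt(fit$vcov[nm, nm])
    or[g] <- exp(b); lo[g] <- exp(b - z * se); hi[g] <- exp(b + z * se)
  }
  lo[1] <- hi[1] <- NA_real_
  groups <- data.frame(
    group = seq_len(n_groups),
    n_controls = tabulate(qg$group[is_ctrl], n_groups),
    n_cases = tabulate(qg$group[!is_ctrl], n_groups),
    or = or, lo = lo, hi = hi
  )
  list(groups = groups, cuts = qg$cuts, fit = fit)
}

#' Calibration coefficient of a predicted risk
#'
#' Slope (x 100, with Wald 95% CI) from the logistic regression of case
#' status on the natural log of the predicted risk. 100% means the
#' predicted relative risks are fully expressed in the case-control
#' contrast; below 100% means they are over-dispersed relative to the
#' observed outcome.
#'
#' @param tab table from [prepare_analysis_data()].
#' @param risk_col positive predicted-risk column (percent or probability;
#'   the slope is scale-invariant).
#' @return List `slope_pct`, `lo_pct`, `hi_pct`, `se_pct`.
#' @export
calibration_coefficient <- function(tab, risk_col = "tc10") {
  r <- tab[[risk_col]]
  if (any(r <= 0, na.rm = TRUE)) {
    stop("calibration_coefficient: risk must be positive", call. = FALSE)
  }
  if (sd(log(r), na.rm = TRUE) == 0) {
    stop("calibration_coefficient: risk column has zero variance", call. = FALSE)
  }
  tab$.logrisk <- log(r)
  fit <- fit_adjusted_logistic(tab, ".logrisk")
  b <- unname(fit$coefficients[".logrisk"])
  se <- sqrt(fit$vcov[".logrisk", ".logrisk"])
  z <- qnorm(0.975)
  list(slope_pct = 100 * b,
       lo_pct = 100 * (b - z * se),
       hi_pct = 100 * (b + z * se),
       se_pct = 100 * se)
}
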