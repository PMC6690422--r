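#' Fit the expected-density surface on controls
#'
#' Models transformed density as an additive cubic B-spline function of age
#' and BMI, fitted by least squares to control participants only. The
#' residual from this surface -- observed minus expected transformed
#' density -- is the density signal independent of age and BMI that all
#' downstream odds-ratio and concordance analyses use.
#'
#' Transforms by measure: `vpd_log`, `fibro_log`, `fat_log` use the natural
#' log of the measure; `birads_integer` uses the grade codes 1--4 untransformed
#' (a log of category codes has no scale meaning).
#'
#' @param controls participant table containing only controls.
#' @param measure one of `"vpd_log"`, `"birads_integer"`, `"fibro_log"`,
#'   `"fat_log"`.
#' @param df_age,df_bmi degrees of freedom of the cubic B-spline basis per
#'   covariate (>= 2; default 4).
#' @return Object of class `expected_density_model` holding the basis
#'   specification, coefficients, training ranges and the control residual
#'   quartiles (type-7 linear interpolation of order statistics).
#' @seealso [residualize()], [residual_iqr()], [write_density_model()]
#' @export
fit_expected_density <- function(controls,
                                 measure = c("vpd_log", "birads_integer",
                                             "fibro_log", "fat_log"),
                                 df_age = 4, df_bmi = 4) {
  measure <- match.arg(measure)
  if (!all(c("age_mammogram", "bmi") %in% names(controls))) {
    stop("fit_expected_density: 'age_mammogram' and 'bmi' columns required",
         call. = FALSE)
  }
  if ("status" %in% names(controls) && any(controls$status != "control")) {
    stop("fit_expected_density: input must contain controls only",
         call. = FALSE)
  }
  if (df_age < 2 || df_bmi < 2) {
    stop("fit_expected_density: spline df must be >= 2 per covariate",
         call. = FALSE)
  }
  y <- transform_measure(controls, measure)
  age <- controls$age_mammogram
  bmi <- controls$bmi
  ok <- is.finite(y) & is.finite(age) & is.finite(bmi)
  y <- y[ok]; age <- age[ok]; bmi <- bmi[ok]
  p <- 1 + df_age + df_bmi
  if (length(y) < p) {
    stop(sprintf(
      "fit_expected_density: underdetermined fit (%d rows < basis dimension %d)",
      length(y), p), call. = FALSE)
  }
  if (length(y) < 10 * p) {
    warning(sprintf(
      "fit_expected_density: only %d rows for basis dimension %d (< 10 per parameter)",
      length(y), p))
  }
  spec_age <- bspline_spec(age, df_age)
  spec_bmi <- bspline_spec(bmi, df_bmi)
  X <- cbind(1, bspline_eval(age, spec_age), bspline_eval(bmi, spec_bmi))
  fit <- lm.fit(X, y)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  res <- y - drop(X %*% coefs)
  model <- list(
    measure = measure,
    spec_age = spec_age,
    spec_bmi = spec_bmi,
    coefficients = unname(coefs),
    training_n = length(y),
    training_ranges = list(age = range(age), bmi = range(bmi)),
    control_residual_quartiles = unname(
      quantile(res, c(0.25, 0.5, 0.75), type = 7))
  )
  class(model) <- "expected_density_model"
  model
}

transform_measure <- function(tab, measure) {
  switch(measure,
    vpd_log = {
      if (any(tab$vpd <= 0, na.rm = TRUE)) {
        stop("vpd must be > 0 for a log measure", call. = FALSE)
      }
      log(tab$vpd)
    },
    fibro_log = {
      if (any(tab$fibro_volume <= 0, na.rm = TRUE)) {
        stop("fibro_volume must be > 0 for a log measure", call. = FALSE)
      }
      log(tab$fibro_volume)
    },
    fat_log = {
      if (any(tab$fat_volume <= 0, na.rm = TRUE)) {
        stop("fat_volume must be > 0 for a log measure", call. = FALSE)
      }
      log(tab$fat_volume)
    },
    birads_integer = {
      b <- as.numeric(tab$birads)
      if (any(!b %in% 1:4, na.rm = TRUE)) {
        stop("birads must be an integer in 1..4", call. = FALSE)
      }
      b
    })
}

# Cubic B-spline basis spec with interior knots at equally spaced quantiles,
# stored explicitly so models serialize and predict reproducibly.
bspline_spec <- function(x, df) {
  degree <- 3L
  n_interior <- max(df - degree, 0L)
  knots <- if (n_interior > 0) {
    unname(quantile(x, seq_len(n_interior) / (n_interior + 1), type = 7))
  } else numeric(0)
  list(df = df, degree = degree, knots = knots,
       boundary = range(x))
}

bspline_eval <- function(x, spec) {
  x <- pmin(pmax(x, spec$boundary[1]), spec$boundary[2])
  splines::bs(x, knots = spec$knots, degree = spec$degree,
              Boundary.knots = spec$boundary, intercept = FALSE)[, , drop = FALSE]
}

predict_expected <- function(model, age, bmi) {
  X <- cbind(1, bspline_eval(age, model$spec_age),
             bspline_eval(bmi, model$spec_bmi))
  mu <- drop(X %*% model$coefficients)
  if (model$measure == "birads_integer") mu <- pmin(pmax(mu, 1), 4)
  mu
}

#' Age/BMI-adjusted density residual
#'
#' Transformed observed density minus the model's expectation at the
#' participant's age and BMI. Ages or BMIs outside the training range are
#' clamped to the range boundary (spline extrapolation is avoided) and a
#' warning reports how many inputs were clamped.
#'
#' @param model an [fit_expected_density()] model.
#' @param age,bmi covariate values (vectors).
#' @param observed observed density on the measure's natural scale (VPD
#'   percent, volume in cm^3, or grade 1--4).
#' @return Numeric vector of residuals on the model's transformed scale.
#' @export
residualize <- function(model, age, bmi, observed) {
  stopifnot(inherits(model, "expected_density_model"))
  n_out <- sum(age < model$training_ranges$age[1] |
                 age > model$training_ranges$age[2] |
                 bmi < model$training_ranges$bmi[1] |
                 bmi > model$training_ranges$bmi[2], na.rm = TRUE)
  if (n_out > 0) {
    warning(sprintf(
      "residualize: %d input(s) outside the training range were clamped", n_out))
  }
  tab <- data.frame(vpd = observed, fibro_volume = observed,
                    fat_volume = observed, birads = observed)
  obs_t <- transform_measure(tab, model$measure)
  obs_t - predict_expected(model,
                           pmin(pmax(age, model$training_ranges$age[1]),
                                model$training_ranges$age[2]),
                           pmin(pmax(bmi, model$training_ranges$bmi[1]),
                                model$training_ranges$bmi[2]))
}

#' Add a density-residual column to a participant table
#'
#' Convenience wrapper applying [residualize()] to every row, reading the
#' observed value from the column the model's measure refers to.
#'
#' @param tab participant table.
#' @param model an [fit_expected_density()] model.
#' @param col name of the new column.
#' @return `tab` with the residual column appended.
#' @export
add_residual <- function(tab, model,
                         col = paste0(sub("_.*$", "", model$measure), "_residual")) {
  src <- switch(model$measure,
                vpd_log = tab$vpd,
                fibro_log = tab$fibro_volume,
                fat_log = tab$fat_volume,
                birads_integer = tab$birads)
  tab[[col]] <- residualize(model, tab$age_mammogram, tab$bmi, src)
  tab
}

#' Control residual quartiles of a fitted expected-density model
#'
#' @param model an [fit_expected_density()] model.
#' @return Named vector `c(q25, q75)` of the stored control residual
#'   quartiles.
#' @export
residual_iqr <- function(model) {
  if (!inherits(model, "expected_density_model") ||
      is.null(model$control_residual_quartiles)) {
    stop("residual_iqr: model has not been fitted", call. = FALSE)
  }
  q <- model$control_residual_quartiles
  c(q25 = q[1], q75 = q[3])
}

#' @export
print.expected_density_model <- function(x, ...) {
  q <- x$control_residual_quartiles
  cat("Expected-density model\n")
  cat(sprintf("  measure: %s\n", x$measure))
  cat(sprintf("  basis: cubic B-splines, df %d (age) + %d (bmi)\n",
              x$spec_age$df, x$spec_bmi$df))
  cat(sprintf("  trained on %d controls; age %.1f-%.1f, bmi %.1f-%.1f\n",
              x$training_n,
              x$training_ranges$age[1], x$training_ranges$age[2],
              x$training_ranges$bmi[1], x$training_ranges$bmi[2]))
  cat(sprintf("  control residual quartiles: %.3f / %.3f / %.3f\n",
              q[1], q[2], q[3]))
  invisible(x)
}

#' Serialize / restore an expected-density model as JSON
#'
#' The JSON carries the basis specification, coefficients, training ranges
#' and control residual quartiles; `read_density_model()` round-trips to a
#' model giving identical predictions.
#'
#' @param model an [fit_expected_density()] model.
#' @param path file path.
#' @return `write_density_model()` returns `path` invisibly;
#'   `read_density_model()` returns the model.
#' @export
write_density_model <- function(model, path) {
  stopifnot(inherits(model, "expected_density_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_density_model
#' @export
read_density_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$spec_age$knots <- as.numeric(m$spec_age$knots)
  m$spec_bmi$knots <- as.numeric(m$spec_bmi$knots)
  class(m) <- "expected_density_model"
  m
}
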