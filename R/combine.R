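#' Density relative risk from a residual and its log-odds coefficient
#'
#' `rr = exp(beta * residual) / normalizer`, where the normalizer is the
#' mean of `exp(beta * residual)` over the control residuals, so the mean
#' relative risk over controls is exactly 1 and adding density leaves the
#' population-average risk approximately unchanged.
#'
#' @param residual density residual(s).
#' @param beta log-odds coefficient per unit residual.
#' @param control_residuals control residuals defining the normalizer
#'   (ignored when `normalizer` is given).
#' @param normalizer optional precomputed normalizer (> 0).
#' @return Positive relative-risk multiplier(s).
#' @export
density_relative_risk <- function(residual, beta,
                                  control_residuals = NULL,
                                  normalizer = NULL) {
  if (any(!is.finite(residual))) {
    stop("density_relative_risk: residual must be finite", call. = FALSE)
  }
  if (is.null(normalizer)) {
    if (is.null(control_residuals)) {
      stop("density_relative_risk: supply control_residuals or normalizer",
           call. = FALSE)
    }
    normalizer <- mean(exp(beta * control_residuals))
  }
  if (!is.finite(normalizer) || normalizer <= 0) {
    stop("density_relative_risk: normalizer must be > 0", call. = FALSE)
  }
  exp(beta * residual) / normalizer
}

#' Combine a 10-year absolute risk with a density relative risk
#'
#' Combination on the hazard scale,
#' `combined = 100 * (1 - (1 - tc10/100)^rr)`, which is a valid probability
#' for any positive `rr` and close to `tc10 * rr` for small risks.
#'
#' @param tc10 baseline 10-year risk in percent, in (0, 100).
#' @param rr positive relative-risk multiplier.
#' @return Combined 10-year risk in percent, always < 100.
#' @export
combine_risk <- function(tc10, rr) {
  if (any(!is.finite(tc10)) || any(tc10 <= 0) || any(tc10 >= 100)) {
    stop("combine_risk: tc10 must lie in (0, 100) percent", call. = FALSE)
  }
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop("combine_risk: rr must be positive", call. = FALSE)
  }
  100 * (1 - (1 - tc10 / 100)^rr)
}

#' Proportions in clinical 10-year risk strata
#'
#' Fractions of participants below the lower threshold (decreased risk), at
#' or above the upper threshold (increased risk), and in between. Boundary
#' convention: low is `< thresholds[1]`, high is `>= thresholds[2]`, so the
#' strata are exhaustive.
#'
#' @param risks combined 10-year risks in percent.
#' @param thresholds increasing pair of percent thresholds (default 2 and
#'   8).
#' @return Named vector `c(low, average, high)` summing to 1.
#' @export
risk_strata_proportions <- function(risks, thresholds = c(2, 8)) {
  if (!length(risks)) {
    stop("risk_strata_proportions: empty input", call. = FALSE)
  }
  if (length(thresholds) != 2 || thresholds[1] >= thresholds[2]) {
    stop("risk_strata_proportions: thresholds must be increasing", call. = FALSE)
  }
  low <- mean(risks < thresholds[1])
  high <- mean(risks >= thresholds[2])
  c(low = low, average = 1 - low - high, high = high)
}

#' Histogram of predicted risks for the report
#'
#' Fixed-width binning starting at 0; counts conserve the number of
#' observations.
#'
#' @param risks risks in percent (>= 0).
#' @param bin_width bin width in percent.
#' @return Data frame with `lower`, `upper`, `count`.
#' @export
risk_histogram <- function(risks, bin_width = 0.5) {
  if (!length(risks)) stop("risk_histogram: empty input", call. = FALSE)
  if (bin_width <= 0) stop("risk_histogram: bin_width must be > 0", call. = FALSE)
  idx <- pmax(ceiling(risks / bin_width), 1)  # values at 0 fall in bin 1
  n_bins <- max(idx)
  data.frame(
    lower = (seq_len(n_bins) - 1) * bin_width,
    upper = seq_len(n_bins) * bin_width,
    count = tabulate(idx, n_bins)
  )
}
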