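#' Residualize a predictor on adjustment factors by linear regression
#'
#' Ordinary-least-squares residual of the predictor on the indicator-coded
#' adjustment design (the discrimination analogue of covariate adjustment).
#' A rank-deficient design is handled by dropping aliased columns, with a
#' warning.
#'
#' @param tab participant table.
#' @param predictor predictor column name.
#' @param adjustments character vector of adjustment columns.
#' @return Numeric residual vector (mean zero over the fitted rows).
#' @export
adjust_predictor <- function(tab, predictor, adjustments = character(0)) {
  y <- tab[[predictor]]
  if (is.null(y)) {
    stop(sprintf("adjust_predictor: column '%s' not found", predictor),
         call. = FALSE)
  }
  if (!length(adjustments)) return(y - mean(y))
  fm <- as.formula(paste("~", paste(adjustments, collapse = " + ")))
  X <- model.matrix(fm, data = tab)
  fit <- lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    warning(sprintf(
      "adjust_predictor: adjustment design rank-deficient (%d aliased column(s) dropped)",
      ncol(X) - fit$rank))
  }
  unname(fit$residuals)
}

#' Matched concordance index (mC)
#'
#' Discrimination of an (adjusted) predictor compared within matching
#' strata: over all within-stratum case-control pairs,
#' `mC = (#(case > control) + 0.5 * #ties) / #pairs`. 0.5 means no
#' discrimination. The confidence interval comes from a nonparametric
#' bootstrap resampling cases and controls within each stratum.
#'
#' @param tab participant table with a `status` column.
#' @param score_col column holding the (adjusted) predictor.
#' @param strata_col stratification column (default the 5-year age groups
#'   used for frequency matching).
#' @param n_boot bootstrap replicates for the CI (0 to skip).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level.
#' @return Object of class `concordance_result`: `mC`, `lo`, `hi`,
#'   `n_pairs`, `n_strata_used`, `n_strata_skipped`.
#' @export
matched_concordance <- function(tab, score_col, strata_col = "age_group",
                                n_boot = 1000, seed = 1, conf = 0.95) {
  strata <- split(seq_len(nrow(tab)), tab[[strata_col]], drop = TRUE)
  usable <- vapply(strata, function(idx) {
    s <- tab$status[idx]
    any(s == "case") && any(s == "control")
  }, logical(1))
  if (!any(usable)) {
    stop("matched_concordance: no stratum contains both a case and a control",
         call. = FALSE)
  }
  mc_stat <- function(scores_by_stratum) {
    wins <- 0; pairs <- 0
    for (sc in scores_by_stratum) {
      n1 <- length(sc$case); n0 <- length(sc$control)
      # midrank identity: sum of case ranks in the pooled sample minus
      # n1(n1+1)/2 equals #(case > control) + 0.5 * #ties
      r <- rank(c(sc$case, sc$control))
      wins <- wins + sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
      pairs <- pairs + n1 * n0
    }
    wins / pairs
  }
  split_scores <- function(idx_list, resample = FALSE) {
    lapply(idx_list, function(idx) {
      s <- tab$status[idx]
      case <- tab[[score_col]][idx[s == "case"]]
      control <- tab[[score_col]][idx[s == "control"]]
      if (resample) {
        case <- sample(case, length(case), replace = TRUE)
        control <- sample(control, length(control), replace = TRUE)
      }
      list(case = case, control = control)
    })
  }
  used <- strata[usable]
  obs <- split_scores(used)
  mC <- mc_stat(obs)
  n_pairs <- sum(vapply(obs, function(sc) {
    length(sc$case) * length(sc$control)
  }, numeric(1)))
  lo <- hi <- NA_real_
  if (n_boot > 0) {
    reps <- with_substream(seed, "matched_concordance",
      vapply(seq_len(n_boot),
             function(b) mc_stat(split_scores(used, resample = TRUE)),
             numeric(1)))
    alpha <- (1 - conf) / 2
    ci <- quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
    lo <- ci[1]; hi <- ci[2]
  }
  out <- list(mC = mC, lo = lo, hi = hi, n_pairs = n_pairs,
              n_strata_used = sum(usable),
              n_strata_skipped = sum(!usable))
  class(out) <- "concordance_result"
  out
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Matched concordance mC = %.3f (95%% CI %.3f-%.3f), %d pairs in %d strata\n",
              x$mC, x$lo, x$hi, x$n_pairs, x$n_strata_used))
  if (x$n_strata_skipped > 0) {
    cat(sprintf("  %d stratum/strata without both outcomes skipped\n",
                x$n_strata_skipped))
  }
  invisible(x)
}
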