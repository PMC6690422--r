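#' Weighted kappa for agreement between two ordinal gradings
#'
#' `kappa = 1 - sum(w * p) / sum(w * e)` with disagreement weights
#' `w_ij = |i - j| / (k - 1)` (linear) or `((i - j) / (k - 1))^2`
#' (quadratic), where `p` is the observed proportion table and `e` the
#' expected table from the margin products. The CI is a seeded multinomial
#' bootstrap of the count table.
#'
#' @param tab k x k count matrix (rows: first grading, columns: second).
#' @param weighting `"linear"` or `"quadratic"`.
#' @param n_boot bootstrap replicates for the CI (0 to skip).
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return List `kappa`, `lo`, `hi`, `weighting`, `n`.
#' @export
weighted_kappa <- function(tab, weighting = c("linear", "quadratic"),
                           n_boot = 2000, seed = 1, conf = 0.95) {
  weighting <- match.arg(weighting)
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab) || nrow(tab) < 2) {
    stop("weighted_kappa: need a square table with k >= 2", call. = FALSE)
  }
  if (any(tab < 0) || sum(tab) <= 0) {
    stop("weighted_kappa: counts must be non-negative with positive total",
         call. = FALSE)
  }
  k <- nrow(tab)
  w <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  if (weighting == "quadratic") w <- w^2
  kap <- function(m) {
    p <- m / sum(m)
    e <- outer(rowSums(p), colSums(p))
    1 - sum(w * p) / sum(w * e)
  }
  kappa <- kap(tab)
  lo <- hi <- NA_real_
  if (n_boot > 0) {
    n <- sum(tab)
    pvec <- as.vector(tab) / n
    reps <- with_substream(seed, "weighted_kappa", {
      draws <- rmultinom(n_boot, n, pvec)
      apply(draws, 2, function(cnt) kap(matrix(cnt, k, k)))
    })
    alpha <- (1 - conf) / 2
    ci <- quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
    lo <- ci[1]; hi <- ci[2]
  }
  list(kappa = kappa, lo = lo, hi = hi, weighting = weighting, n = sum(tab))
}

#' Crude odds ratio with Woolf confidence interval
#'
#' For a 2 x 2 table with rows = exposure (exposed first) and columns =
#' outcome (case first): `OR = (a * d) / (b * c)` and
#' `CI = exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Zero cells get a
#' 0.5 continuity correction with a warning; a zero margin is an error.
#'
#' @param t 2 x 2 count matrix: `t[1,1]` exposed cases, `t[1,2]` exposed
#'   controls, `t[2,1]` unexposed cases, `t[2,2]` unexposed controls.
#' @param conf confidence level.
#' @return List `or`, `lo`, `hi`, `se_log`.
#' @export
crude_odds_ratio <- function(t, conf = 0.95) {
  t <- as.matrix(t)
  if (!all(dim(t) == c(2, 2)) || any(t < 0)) {
    stop("crude_odds_ratio: need a non-negative 2 x 2 table", call. = FALSE)
  }
  if (any(rowSums(t) == 0) || any(colSums(t) == 0)) {
    stop("crude_odds_ratio: zero margin, odds ratio undefined", call. = FALSE)
  }
  if (any(t == 0)) {
    warning("crude_odds_ratio: zero cell(s), applying 0.5 continuity correction")
    t <- t + 0.5
  }
  lor <- log(t[1, 1]) + log(t[2, 2]) - log(t[1, 2]) - log(t[2, 1])
  se <- sqrt(sum(1 / t))
  z <- qnorm(1 - (1 - conf) / 2)
  list(or = exp(lor), lo = exp(lor - z * se), hi = exp(lor + z * se),
       se_log = se)
}

#' Spearman rank correlation with midranks
#'
#' Pearson correlation of the midranks of `x` and `y`; ties share the mean
#' of the ranks they occupy. A constant input yields `NA` with a warning.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return Correlation in `[-1, 1]`, or `NA` for degenerate input.
#' @export
spearman_rho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    stop("spearman_rho: need at least 3 complete pairs", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warning("spearman_rho: constant input, correlation undefined")
    return(NA_real_)
  }
  cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}
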