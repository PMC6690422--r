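test_that("adjust_predictor equals the normal-equations solution", {
  d <- data.frame(
    y = c(3.2, -1.5, 0.7, 4.4, 2.1, -0.3),
    g = factor(c("a", "a", "b", "b", "c", "c")),
    z = c(0.5, 1.2, -0.7, 0.3, 2.2, -1.1)
  )
  r <- adjust_predictor(d, "y", c("g", "z"))
  X <- model.matrix(~ g + z, d)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(r, as.numeric(d$y - X %*% beta), tolerance = 1e-10)
  expect_lt(abs(mean(r)), 1e-10)

  # predictor that is an exact linear function of the adjustments
  d$y2 <- 2 - 3 * d$z + as.numeric(d$g)
  expect_lt(max(abs(adjust_predictor(d, "y2", c("g", "z")))), 1e-10)

  # orthogonal predictor is only mean-centred
  d2 <- data.frame(y = c(5, 7, 5, 7), g = factor(c("a", "a", "b", "b")))
  expect_equal(adjust_predictor(d2, "y", "g"), c(-1, 1, -1, 1))

  # collinear design is handled with a warning
  d$z2 <- d$z * 2
  expect_warning(adjust_predictor(d, "y", c("z", "z2")), "rank-deficient")
})

brute_mc <- function(tab, col, strata) {
  wins <- 0; pairs <- 0
  for (s in unique(tab[[strata]])) {
    d <- tab[tab[[strata]] == s, ]
    cs <- d[[col]][d$status == "case"]
    ct <- d[[col]][d$status == "control"]
    if (!length(cs) || !length(ct)) next
    for (a in cs) for (b in ct) {
      wins <- wins + (a > b) + 0.5 * (a == b)
      pairs <- pairs + 1
    }
  }
  wins / pairs
}

test_that("matched concordance equals brute-force pair counting on small strata", {
  tab <- data.frame(
    status = rep(c("case", "case", "case", "control", "control", "control"), 2),
    score = c(3.1, 2.0, 2.0, 1.5, 2.0, 4.0,   # stratum A, with ties
              0.4, 0.9, 1.7, 0.4, 0.2, 1.7),  # stratum B, with ties
    stratum = rep(c("A", "B"), each = 6)
  )
  res <- matched_concordance(tab, "score", "stratum", n_boot = 0)
  expect_equal(res$mC, brute_mc(tab, "score", "stratum"))
  expect_equal(res$n_pairs, 18)

  # single stratum, no ties: equals the normalized rank-sum statistic
  tab2 <- data.frame(status = rep(c("case", "control"), c(3, 4)),
                     score = c(5, 9, 2, 1, 3, 8, 6), stratum = "s")
  res2 <- matched_concordance(tab2, "score", "stratum", n_boot = 0)
  w <- sum(rank(tab2$score)[1:3]) - 3 * 4 / 2
  expect_equal(res2$mC, w / 12)
  expect_equal(res2$mC, brute_mc(tab2, "score", "stratum"))
})

test_that("mC respects label swap, monotone transforms and extremes", {
  pop <- prepare_analysis_data(make_pop(800, 200, seed = 28))
  pop$score <- adjust_predictor(pop, "vpd", c("bmi", "region"))
  res <- matched_concordance(pop, "score", "age_group", n_boot = 0)

  swapped <- pop
  swapped$status <- factor(ifelse(pop$status == "case", "control", "case"),
                           levels = c("control", "case"))
  res_sw <- matched_concordance(swapped, "score", "age_group", n_boot = 0)
  expect_equal(res_sw$mC, 1 - res$mC, tolerance = 1e-12)

  pop$score_t <- pop$score^3  # strictly increasing, no floating-point saturation
  res_t <- matched_concordance(pop, "score_t", "age_group", n_boot = 0)
  expect_equal(res_t$mC, res$mC, tolerance = 1e-12)

  # a score that perfectly separates cases from controls in every stratum
  pop$sep <- ifelse(pop$status == "case", 2, 1)
  expect_equal(matched_concordance(pop, "sep", "age_group", n_boot = 0)$mC, 1)

  # independent score gives mC near 1/2
  set.seed(61)
  pop$rand <- rnorm(nrow(pop))
  mc0 <- matched_concordance(pop, "rand", "age_group", n_boot = 0)$mC
  expect_gt(mc0, 0.45)
  expect_lt(mc0, 0.55)
})

test_that("bootstrap CI is seeded, ordered, and strata without both outcomes are skipped", {
  pop <- prepare_analysis_data(make_pop(300, 100, seed = 30))
  pop$score <- pop$vpd
  r1 <- matched_concordance(pop, "score", "age_group", n_boot = 100, seed = 4)
  r2 <- matched_concordance(pop, "score", "age_group", n_boot = 100, seed = 4)
  expect_identical(r1, r2)
  expect_true(r1$lo <= r1$mC && r1$mC <= r1$hi)
  expect_true(r1$lo >= 0 && r1$hi <= 1)

  tab <- data.frame(status = c("case", "control", "control"),
                    score = c(1, 2, 3),
                    stratum = c("A", "A", "B"))
  res <- matched_concordance(tab, "score", "stratum", n_boot = 0)
  expect_equal(res$n_strata_skipped, 1)
  only_ctrl <- tab[tab$status == "control", ]
  expect_error(matched_concordance(only_ctrl, "score", "stratum", n_boot = 0),
               "case and a control")
})
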