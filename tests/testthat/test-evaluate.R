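test_that("the 3x2 table cross-tabulates decisions against labels", {
  toy <- toy_sample_12()
  tab <- three_by_two(toy, decision_zones(4.2, 6.2))
  # hand tabulation: non-diseased 1,2,3,4 below; 5,6 inside; none above
  #                  diseased 4.5,5.5 inside; 6.5,7,8,9 above
  expect_equal(as.vector(tab), c(4L, 2L, 0L, 0L, 2L, 4L))
  expect_equal(sum(tab), 12)
  # sentinel zones below every score: everything positive
  tab2 <- three_by_two(toy, decision_zones(-Inf, -Inf))
  expect_equal(as.vector(tab2["positive", ]), c(6L, 6L))
  # a separating band leaves the outer off-diagonals empty
  sep <- labeled_sample(c(1, 2, 3, 7, 8, 9), rep(c(0, 1), each = 3))
  tab3 <- three_by_two(sep, decision_zones(4, 6))
  expect_equal(tab3["negative", "1"] + tab3["positive", "0"], 0L)
})

test_that("outer-section metrics summarize the decided records", {
  tab <- matrix(c(80L, 15L, 5L, 5L, 15L, 80L), nrow = 3,
                dimnames = list(c("negative", "inconclusive", "positive"),
                                c("0", "1")))
  om <- outer_metrics(tab, total_n = 200)
  expect_equal(om$proportion, 0.85)
  expect_equal(om$prevalence, 0.5)
  expect_equal(om$se, 80 / 85)
  expect_equal(om$sp, 80 / 85)
  expect_equal(om$accuracy, 160 / 170)
  expect_equal(om$yield, 0.80)
})

test_that("an empty inconclusive row reduces to ordinary dichotomous metrics", {
  s <- toy_sample_12()
  th <- youden_threshold(s)
  tab <- three_by_two(s, decision_zones(th, th))
  # shrink the band to a point below any tied score: here only scores == th
  # are inconclusive; build a truly empty middle with a band between scores
  tab0 <- three_by_two(s, decision_zones(4.25, 4.25))
  om <- outer_metrics(tab0)
  expect_equal(om$proportion, 1)
  base <- oracle_se_sp(s$scores[s$labels == 0], s$scores[s$labels == 1], 4.25)
  expect_equal(om$se, unname(base["se"]))
  expect_equal(om$sp, unname(base["sp"]))
})

test_that("yield = accuracy x proportion identically, and edge cases are flagged", {
  set.seed(13)
  for (i in 1:25) {
    counts <- matrix(rpois(6, 20), nrow = 3,
                     dimnames = list(c("negative", "inconclusive", "positive"),
                                     c("0", "1")))
    if (sum(counts[c(1, 3), ]) == 0) next
    om <- outer_metrics(counts)
    expect_equal(om$yield, om$accuracy * om$proportion, tolerance = 1e-12)
  }
  allcorrect <- matrix(c(50L, 10L, 0L, 0L, 10L, 50L), nrow = 3,
                       dimnames = list(c("negative", "inconclusive", "positive"),
                                       c("0", "1")))
  om2 <- outer_metrics(allcorrect)
  expect_equal(om2$accuracy, 1)
  expect_equal(om2$yield, om2$proportion)
  onlyneg <- matrix(c(50L, 0L, 0L, 0L, 0L, 0L), nrow = 3,
                    dimnames = list(c("negative", "inconclusive", "positive"),
                                    c("0", "1")))
  expect_warning(om3 <- outer_metrics(onlyneg), "se undefined")
  expect_true(is.na(om3$se))
  empty <- matrix(c(0L, 5L, 0L, 0L, 5L, 0L), nrow = 3,
                  dimnames = list(c("negative", "inconclusive", "positive"),
                                  c("0", "1")))
  expect_error(outer_metrics(empty), "no records")
})

test_that("model-based outer metrics are exact normal tail arithmetic", {
  m <- binormal_model(0, 1, 2, 1)
  om <- outer_metrics_binormal(m, 0.5, decision_zones(0.6, 1.4))
  expect_equal(om$se, om$sp, tolerance = 1e-12)  # symmetric zones about 1
  expect_equal(om$prevalence, 0.5, tolerance = 1e-12)
  # collapsed zones reduce to the dichotomous expected accuracy
  I <- intersection_binormal(m)
  omc <- outer_metrics_binormal(m, 0.5, decision_zones(I, I))
  base <- dichotomous_baseline(m, 0.5)
  expect_equal(omc$proportion, 1, tolerance = 1e-12)
  expect_equal(omc$se, base$se, tolerance = 1e-12)
  expect_equal(omc$accuracy, base$accuracy, tolerance = 1e-12)
})

test_that("simulated counts agree with the closed-form outer metrics", {
  m <- binormal_model(0, 1, 2, 1.3)
  z <- decision_zones(0.5, 1.6)
  expected <- outer_metrics_binormal(m, 0.3, z)
  set.seed(99)
  n <- 1e6
  n1 <- rbinom(1, n, 0.3)
  s <- sample_binormal(m, n - n1, n1)
  got <- outer_metrics(three_by_two(s, z))
  for (f in c("proportion", "prevalence", "se", "sp", "accuracy", "yield")) {
    expect_equal(got[[f]], expected[[f]], tolerance = 0.005)
  }
})

test_that("the dichotomous Youden baseline matches closed forms and sweeps", {
  sep <- labeled_sample(c(1, 2, 3, 7, 8, 9), rep(c(0, 1), each = 3))
  b <- dichotomous_baseline(sep)
  expect_equal(c(b$se, b$sp, b$accuracy), c(1, 1, 1))
  m <- binormal_model(0, 1, 2, 1)
  bm <- dichotomous_baseline(m, 0.5)
  expect_equal(bm$threshold, 1)
  expect_equal(bm$se, pnorm(1), tolerance = 1e-12)
  expect_equal(bm$sp, pnorm(1), tolerance = 1e-12)
  toy <- toy_sample_12()
  bt <- dichotomous_baseline(toy)
  cl <- list(s0 = toy$scores[toy$labels == 0], s1 = toy$scores[toy$labels == 1])
  expect_equal(sum(oracle_se_sp(cl$s0, cl$s1, bt$threshold)),
               oracle_youden(cl$s0, cl$s1)$max_j)
})

test_that("AUC matches the bi-normal closed form and pairwise concordance", {
  expect_equal(auc(binormal_model(0, 1, 0, 1)), 0.5)
  expect_equal(auc(binormal_model(0, 1, 2, 1)), pnorm(sqrt(2)))
  set.seed(17)
  s0 <- round(rnorm(10), 1); s1 <- round(rnorm(10, 1), 1)  # rounding gives ties
  s <- labeled_sample(c(s0, s1), rep(c(0, 1), each = 10))
  expect_equal(auc(s), oracle_auc(s0, s1))
  # direction-aware: lower scores indicating disease flips concordance
  slow <- labeled_sample(c(s0, s1), rep(c(1, 0), each = 10), direction = "lower")
  expect_equal(auc(slow), oracle_auc(-s1, -s0))
})

test_that("empirical outer metrics converge to the model-based ones", {
  m <- binormal_model(0, 1, 1.8, 1.2)
  z <- decision_zones(0.4, 1.5)
  expected <- outer_metrics_binormal(m, 0.5, z)
  s <- sample_binormal(m, 5e4, 5e4, seed = 7)
  got <- outer_metrics(three_by_two(s, z))
  # 3 standard errors on a proportion at n = 1e5
  tol <- 3 * 0.5 / sqrt(5e4)
  for (f in c("proportion", "prevalence", "se", "sp", "accuracy", "yield")) {
    expect_equal(got[[f]], expected[[f]], tolerance = tol)
  }
})

test_that("zones bracketing the Youden point improve outer se/sp and shift prevalence", {
  for (mu1 in c(1.2, 1.8, 2.4)) for (sd1 in c(1, 1.5)) {
    m <- binormal_model(0, 1, mu1, sd1)
    I <- intersection_binormal(m)
    z <- decision_zones(I - 0.4, I + 0.4)
    om <- outer_metrics_binormal(m, 0.36, z)
    base <- dichotomous_baseline(m, 0.36)
    expect_gte(om$se, base$se)
    expect_gte(om$sp, base$sp)
    # wider diseased distribution: more non-diseased deselected near I
    p0_in <- pnorm(z$upper) - pnorm(z$lower)
    p1_in <- pnorm(z$upper, mu1, sd1) - pnorm(z$lower, mu1, sd1)
    if (p1_in < p0_in - 1e-9) expect_gt(om$prevalence, 0.36)
  }
})
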