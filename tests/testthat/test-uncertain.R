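test_that("the density intersection is exact for symmetric and equal-sd models", {
  expect_equal(intersection_binormal(binormal_model(0, 1, 2, 1)), 1)
  expect_equal(intersection_binormal(binormal_model(0, 2, 2, 2)), 1)
  expect_error(intersection_binormal(binormal_model(0, 1, 0, 1)), "identical")
})

test_that("the unequal-sd intersection matches a fine-grid density scan", {
  for (m in list(binormal_model(0, 1, 2, 2), binormal_model(0, 1.5, 1.8, 0.7),
                 binormal_model(-1, 0.5, 0.4, 1.1))) {
    I <- intersection_binormal(m)
    grid <- seq(m$mu0, m$mu1, length.out = 200001)
    gap <- abs(dnorm(grid, m$mu1, m$sd1) - dnorm(grid, m$mu0, m$sd0))
    expect_equal(I, grid[which.min(gap)], tolerance = 1e-4)
    expect_equal(dnorm(I, m$mu1, m$sd1), dnorm(I, m$mu0, m$sd0),
                 tolerance = 1e-12)
    expect_true(I > m$mu0 && I < m$mu1)
  }
})

test_that("the intersection maps back correctly for lower-direction markers", {
  m <- fixture_model("iron-deficiency")
  I <- intersection_binormal(m)
  expect_equal(I, (m$mu0 + m$mu1) / 2)  # equal sds: midpoint, original scale
  expect_true(I > m$mu1 && I < m$mu0)
})

test_that("the empirical Youden threshold maximizes Se + Sp", {
  s <- labeled_sample(c(5, 6, 7, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  expect_equal(youden_threshold(s), 5)  # observed-scores rule

  toy <- toy_sample_12()
  cl <- list(s0 = toy$scores[toy$labels == 0], s1 = toy$scores[toy$labels == 1])
  th <- youden_threshold(toy)
  orc <- oracle_youden(cl$s0, cl$s1)
  expect_true(th %in% orc$argmax)
  expect_equal(sum(oracle_se_sp(cl$s0, cl$s1, th)), orc$max_j)

  big <- sample_binormal(binormal_model(0, 1, 2, 1), 2e4, 2e4, seed = 31)
  expect_equal(youden_threshold(big), 1, tolerance = 0.1)
})

test_that("the ROC(0,1) threshold minimizes distance to the corner", {
  expect_equal(roc01_threshold(binormal_model(0, 1, 2, 1)), 1,
               tolerance = 1e-6)
  # grid oracle on an asymmetric model
  m <- binormal_model(0, 1, 2, 2)
  th <- roc01_threshold(m)
  grid <- seq(-3, 6, length.out = 100001)
  d <- (1 - pnorm(grid, 2, 2, lower.tail = FALSE))^2 + (1 - pnorm(grid))^2
  expect_equal(th, grid[which.min(d)], tolerance = 1e-3)
  # on toys the empirical version agrees with its sweep oracle
  toy <- toy_sample_12()
  cl <- list(s0 = toy$scores[toy$labels == 0], s1 = toy$scores[toy$labels == 1])
  expect_true(roc01_threshold(toy) %in% oracle_roc01(cl$s0, cl$s1)$argmin)
  sep <- labeled_sample(c(5, 6, 7, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  expect_equal(roc01_threshold(sep), youden_threshold(sep))
})

test_that("the intersection equals the theoretical Youden maximizer on a model grid", {
  for (mu1 in c(0.8, 1.2, 1.6, 2.0, 2.4)) {
    for (sd1 in c(0.6, 0.8, 1.0, 1.3, 1.7)) {
      m <- binormal_model(0, 1, mu1, sd1)
      I <- intersection_binormal(m)
      J <- function(t) pnorm(t, mu1, sd1, lower.tail = FALSE) + pnorm(t)
      opt <- optimize(J, c(m$mu0 - 2, m$mu1 + 2), maximum = TRUE,
                      tol = 1e-10)
      expect_equal(I, opt$maximum, tolerance = 1e-6)
    }
  }
})

test_that("at equal class sizes total misclassification is minimal at the intersection", {
  for (m in list(binormal_model(0, 1, 2, 1), binormal_model(0, 1, 1.5, 1.8))) {
    I <- intersection_binormal(m)
    err <- function(t) pnorm(t, m$mu1, m$sd1) + pnorm(t, lower.tail = FALSE)
    grid <- seq(m$mu0 - 1, m$mu1 + 1, length.out = 20001)
    expect_equal(I, grid[which.min(err(grid))], tolerance = 1e-3)
  }
})

test_that("the bi-normal uncertain interval attains its targets exactly", {
  sol <- ui_binormal(binormal_model(0, 1, 2, 1), 0.55, 0.55)
  expect_equal(sol$intersection, 1)
  # symmetry: L = 2 - U
  expect_equal(sol$zones$lower, 2 - sol$zones$upper, tolerance = 1e-9)
  expect_equal(sol$achieved_ui_se, 0.55, tolerance = 1e-8)
  expect_equal(sol$achieved_ui_sp, 0.55, tolerance = 1e-8)
  # unequal sds and unequal targets still satisfy both defining equations
  m <- binormal_model(0, 1, 1.8, 1.5)
  s2 <- ui_binormal(m, 0.6, 0.58)
  F0 <- function(q) pnorm(q, 0, 1); F1 <- function(q) pnorm(q, 1.8, 1.5)
  I <- intersection_binormal(m); L <- s2$zones$lower; U <- s2$zones$upper
  expect_equal((F1(U) - F1(I)) / (F1(U) - F1(L)), 0.6, tolerance = 1e-8)
  expect_equal((F0(I) - F0(L)) / (F0(U) - F0(L)), 0.58, tolerance = 1e-8)
  expect_true(L <= I && I <= U)
})

test_that("the uncertain interval collapses onto the intersection as targets drop to 0.5", {
  m <- binormal_model(0, 1, 2, 1)
  targets <- c(0.60, 0.57, 0.55, 0.52, 0.505, 0.5005)
  widths <- sapply(targets, function(t) {
    z <- ui_binormal(m, t, t)$zones
    z$upper - z$lower
  })
  expect_true(all(diff(widths) < 0))     # monotone shrink
  expect_lt(widths[length(widths)], 0.01)
  expect_error(ui_binormal(m, 0.5, 0.55), "coin flip")
  expect_error(ui_binormal(m, 0.55, 0.45), "coin flip")
})

test_that("mirror-symmetric models deselect both classes equally", {
  for (sep in c(1, 1.5, 2)) {
    m <- binormal_model(0, 1, sep, 1)
    z <- ui_binormal(m, 0.55, 0.55)$zones
    in0 <- pnorm(z$upper) - pnorm(z$lower)
    in1 <- pnorm(z$upper, sep, 1) - pnorm(z$lower, sep, 1)
    expect_equal(in0, in1, tolerance = 1e-8)
  }
})

test_that("deselecting the uncertain interval always improves outer accuracy", {
  # accuracy on the scores outside the UI (decided at the intersection)
  # strictly exceeds whole-population accuracy at the same cutpoint; for
  # mirror-symmetric models Se and Sp improve individually as well
  for (mu1 in c(1.0, 1.6, 2.2)) for (sd1 in c(0.8, 1, 1.4)) {
    for (t in c(0.55, 0.65)) {
      m <- binormal_model(0, 1, mu1, sd1)
      I <- intersection_binormal(m)
      z <- ui_binormal(m, t, t)$zones
      om <- outer_metrics_binormal(m, 0.5, z)
      base <- dichotomous_baseline(m, 0.5)
      expect_gt(om$accuracy, base$accuracy)
      if (sd1 == 1) {
        expect_gt(om$se, base$se)
        expect_gt(om$sp, base$sp)
      }
    }
  }
})

test_that("the distribution-free interval equals the exhaustive pair search", {
  s <- sample_binormal(binormal_model(0, 1, 0.5, 1), 15, 15, seed = 2019)
  sol <- ui_nonparametric(s, 0.55, 0.55)
  cl <- list(s0 = s$scores[s$labels == 0], s1 = s$scores[s$labels == 1])
  orc <- oracle_ui_pairs(cl$s0, cl$s1, sol$intersection, 0.55, 0.55)
  expect_equal(sol$zones$lower, orc$L)
  expect_equal(sol$zones$upper, orc$U)
  expect_equal(sol$achieved_ui_se, orc$wse)
  expect_equal(sol$achieved_ui_sp, orc$wsp)
  # a second configuration with unequal targets and ties in the scores
  set.seed(78)
  s2raw <- round(rnorm(30, rep(c(0, 1.2), each = 15), 1), 1)
  s2 <- labeled_sample(s2raw, rep(c(0, 1), each = 15))
  sol2 <- ui_nonparametric(s2, 0.6, 0.55)
  cl2 <- list(s0 = s2$scores[s2$labels == 0], s1 = s2$scores[s2$labels == 1])
  orc2 <- oracle_ui_pairs(cl2$s0, cl2$s1, sol2$intersection, 0.6, 0.55)
  expect_equal(sol2$zones$lower, orc2$L)
  expect_equal(sol2$zones$upper, orc2$U)
})

test_that("the distribution-free interval approaches the bi-normal one on large samples", {
  m <- binormal_model(0, 1, 2, 1)
  s <- sample_binormal(m, 1e4, 1e4, seed = 55)
  np <- ui_nonparametric(s, 0.55, 0.55)
  bn <- ui_binormal(m, 0.55, 0.55)
  expect_equal(np$zones$lower, bn$zones$lower, tolerance = 0.1)
  expect_equal(np$zones$upper, bn$zones$upper, tolerance = 0.1)
})

test_that("sparse overlap triggers the advisory error", {
  s <- labeled_sample(c(1:5, 101:105), rep(c(0, 1), each = 5))
  expect_error(ui_nonparametric(s), "overlap")
})

test_that("uncertain intervals map back to lower-direction scales correctly", {
  m <- fixture_model("iron-deficiency")
  sol <- ui_binormal(m, 0.55, 0.55)
  expect_true(sol$zones$lower <= sol$intersection)
  expect_true(sol$intersection <= sol$zones$upper)
  expect_equal(sol$zones$direction, "lower")
  # interval is symmetric about the intersection (equal sds, equal targets)
  expect_equal(sol$intersection - sol$zones$lower,
               sol$zones$upper - sol$intersection, tolerance = 1e-8)
})
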