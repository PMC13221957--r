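test_that("Levene statistic is zero for identical spreads and detects unequal ones", {
  x <- c(1, 2, 3, 5, 8)
  lv <- levene_test(x, x)
  expect_equal(lv$W, 0)
  expect_equal(lv$p, 1)

  # two 2-point samples with equal ranges
  expect_equal(levene_test(c(0, 1), c(10, 11))$W, 0)

  expect_error(levene_test(rep(2, 5), rep(7, 4)), "degenerate")

  # power at spread ratio 100, n = 50/group
  hits <- 0L
  for (s in 1:200) {
    set.seed(s)
    p <- levene_test(rnorm(50, sd = 1), rnorm(50, sd = 100))$p
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("pooled t test matches the closed-form textbook formula", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  res <- two_sample_t(x, y)
  expect_equal(res$test_kind, "student")
  # hand formula: sp2 = 1, se = sqrt(1*(1/3+1/3)), t = -3/se, df = 4
  se <- sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(res$t, -3 / se, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p_raw, 2 * pt(-abs(-3 / se), 4), tolerance = 1e-12)
  expect_equal(res$cohen_d, -3)  # pooled SD 1
  expect_equal(sign(res$t), sign(res$mean1 - res$mean2))
})

test_that("identical samples give t = 0, p = 1; degenerate input errors", {
  x <- c(1, 2, 3, 4)
  res <- two_sample_t(x, x)
  expect_equal(res$t, 0)
  expect_equal(res$p_raw, 1)
  expect_error(two_sample_t(rep(1, 3), rep(1, 3)), "undefined t")
})

test_that("swapping groups negates t and d, preserving p and df", {
  set.seed(3)
  x <- rnorm(20, 1); y <- rnorm(25, 0, 2)
  a <- two_sample_t(x, y)
  b <- two_sample_t(y, x)
  expect_equal(b$t, -a$t)
  expect_equal(b$df, a$df)
  expect_equal(b$p_raw, a$p_raw)
  expect_equal(b$cohen_d, -a$cohen_d)
})

test_that("Cohen's d is 0 for equal means and 1 by construction", {
  x <- c(1, 2, 3, 4)
  expect_equal(cohens_d(x, x), 0)
  # shift one group by exactly the pooled SD
  sp <- sqrt(var(x))
  expect_equal(cohens_d(x + sp, x), 1)
  expect_error(cohens_d(rep(1, 3), rep(1, 3)), "pooled SD")
})

test_that("planted standardized effect is recovered by cohens_d", {
  est <- numeric(100)
  for (s in 1:100) {
    set.seed(s)
    est[s] <- cohens_d(rnorm(200, mean = 0.5), rnorm(200, mean = 0))
  }
  expect_lt(abs(median(est) - 0.5), 0.15)
})

test_that("BH adjustment matches hand-computed and reference step-up values", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  p <- rep(0.2, 5)
  expect_equal(bh_adjust(p), p)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(99)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), bh_reference(p), tolerance = 1e-12)
  }
})

test_that("ANCOVA absorbs a perfect confound and keeps nominal type-I error", {
  # y exactly equal to the covariate, balanced groups -> group effect 0
  cov <- c(1:10, 1:10)
  grp <- rep(c("a", "b"), each = 10)
  # perfect fit triggers a summary.lm precision warning; the estimate is the point
  res <- suppressWarnings(ancova_group_effect(cov, grp, cov))
  expect_equal(res$group_effect, 0, tolerance = 1e-10)

  expect_error(ancova_group_effect(rnorm(10), rep(c("a", "b"), 5), rep(3, 10)),
               "constant")

  rej <- 0L
  for (s in 1:400) {
    set.seed(s)
    y <- rnorm(100)
    g <- rep(c("a", "b"), each = 50)
    cv <- rnorm(100)
    if (ancova_group_effect(y, g, cv)$group_effect_p < 0.05) rej <- rej + 1L
  }
  expect_lt(abs(rej / 400 - 0.05), 0.035)
})

test_that("ANCOVA detects a planted group offset with an irrelevant covariate", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    g <- rep(c("a", "b"), each = 50)
    y <- rnorm(100, sd = 1) + ifelse(g == "a", 2, 0)
    if (ancova_group_effect(y, g, rnorm(100))$group_effect_p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 100, 0.99)
})

test_that("partial correlation recovers proportional and planted relationships", {
  set.seed(5)
  x <- rnorm(50); ctl <- rnorm(50)
  res <- partial_correlation(x, 2 * x, ctl)
  expect_equal(res$r_partial, 1)

  expect_error(partial_correlation(x, ctl, ctl), "zero residual variance")

  # trivariate normal with true partial correlation 0.3 at n = 5000
  set.seed(17)
  n <- 5000
  c0 <- rnorm(n)
  e1 <- rnorm(n)
  e2 <- 0.3 * e1 + sqrt(1 - 0.09) * rnorm(n)
  res2 <- partial_correlation(c0 + e1, c0 + e2, c0)
  expect_lt(abs(res2$r_partial - 0.3), 0.05)
})

test_that("the comparison battery adjusts within family and handles degenerate input", {
  set.seed(8)
  feats <- data.frame(
    narrative_id = sprintf("n%02d", 1:20),
    v1 = rnorm(20), v2 = rnorm(20), v3 = rnorm(20)
  )
  g <- rep(c("a", "b"), each = 10)
  bat <- run_comparison_battery(feats, g,
                                families = list(one = "v1", two = c("v2", "v3")))
  expect_equal(bat$p_adj[bat$variable == "v1"],
               bat$p_raw[bat$variable == "v1"])  # single-member family
  expect_true(all(bat$p_adj >= bat$p_raw))

  # identical groups: all t = 0, p_adj = 1
  feats2 <- data.frame(v1 = rep(c(1, 2, 3, 4, 5), 2))
  bat2 <- run_comparison_battery(feats2, rep(c("a", "b"), each = 5),
                                 families = list(f = "v1"))
  expect_equal(bat2$t, 0)
  expect_equal(bat2$p_adj, 1)

  expect_error(run_comparison_battery(feats, rep("a", 20),
                                      families = list(f = "v1")),
               "2 represented levels")
})

test_that("Welch and Student coincide for equal n and equal variances", {
  set.seed(21)
  x <- rnorm(30)
  y <- x + 1  # same sample variance, shifted
  welch <- stats::t.test(x, y, var.equal = FALSE)
  student <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(unname(welch$statistic), unname(student$statistic),
               tolerance = 1e-10)
  res <- two_sample_t(x, y)
  expect_equal(res$t, unname(student$statistic), tolerance = 1e-10)
})
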