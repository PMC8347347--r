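# The statistical battery.

test_that("the Lilliefors statistic matches an independent implementation", {
  set.seed(1)
  for (k in 1:20) {
    x <- rnorm(sample(10:60, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
    expect_equal(footsga:::lilliefors_stat(x),
                 unname(nortest::lillie.test(x)$statistic),
                 tolerance = 1e-12)
  }
})

test_that("the Lilliefors statistic is location-scale invariant", {
  set.seed(2)
  x <- rnorm(40)
  expect_equal(footsga:::lilliefors_stat(3 * x + 7),
               footsga:::lilliefors_stat(x), tolerance = 1e-12)
})

test_that("Lilliefors rejects a uniform sample decisively", {
  set.seed(3)
  x <- runif(1000)
  res <- lilliefors_test(x, n_sim = 2000, seed = 4)
  expect_lt(res$p_value, 0.01)
  expect_error(lilliefors_test(rep(1, 10)), "constant")
  expect_error(lilliefors_test(rnorm(3)), "at least 4")
})

test_that("two-group comparison picks the test by normality and records it", {
  set.seed(5)
  x <- rnorm(20)
  same <- compare_two_groups(x, x, seed = 6)
  expect_gt(same$p_value, 0.9)
  expect_lt(abs(same$statistic), 1e-10)
  expect_match(same$method, "t-test")

  y <- rnorm(20, mean = 3)   # three-SD separation
  strong <- compare_two_groups(x, y, seed = 7)
  expect_lt(strong$p_value, 0.001)

  heavy <- rcauchy(40)       # heavy tails switch to the rank test
  res <- compare_two_groups(x, heavy, seed = 8)
  expect_match(res$method, "rank-sum")
  expect_error(compare_two_groups(rnorm(3), rnorm(10)), "at least 4")
})

test_that("two-way ANOVA sums of squares match a hand-computed cell-means oracle", {
  set.seed(9)
  y <- round(rnorm(20, 10, 3), 2)
  g <- rep(c("PD", "control"), each = 10)
  s <- rep(rep(c("a", "b"), each = 5), 2)
  res <- gait_anova(y, g, s)

  r <- 5
  grand <- mean(y)
  mg <- tapply(y, g, mean)
  ms <- tapply(y, s, mean)
  mcell <- tapply(y, list(g, s), mean)
  ss_g <- 2 * r * sum((mg - grand)^2)
  ss_s <- 2 * r * sum((ms - grand)^2)
  ss_int <- r * sum((sweep(sweep(mcell, 1, mg), 2, ms) + grand)^2)
  ss_err <- sum((y - mcell[cbind(g, s)])^2)
  tab <- res$table
  expect_equal(tab$sumsq[tab$term == "group"], ss_g, tolerance = 1e-9)
  expect_equal(tab$sumsq[tab$term == "side"], ss_s, tolerance = 1e-9)
  expect_equal(tab$sumsq[tab$term == "group:side"], ss_int, tolerance = 1e-9)
  expect_equal(tab$sumsq[tab$term == "Residuals"], ss_err, tolerance = 1e-9)
})

test_that("ANOVA sums of squares decompose the total on balanced data", {
  set.seed(10)
  for (k in 1:10) {
    y <- rnorm(40)
    g <- rep(c("PD", "control"), each = 20)
    s <- rep(rep(c("a", "b"), each = 10), 2)
    tab <- gait_anova(y, g, s)$table
    expect_equal(sum(tab$sumsq), sum((y - mean(y))^2),
                 tolerance = 1e-9 * sum(tab$sumsq))
  }
})

test_that("degenerate and malformed ANOVA inputs are handled", {
  y <- rep(5, 20)
  g <- rep(c("PD", "control"), each = 10)
  s <- rep(rep(c("a", "b"), each = 5), 2)
  res <- gait_anova(y, g, s)
  expect_true(res$zero_variance)
  expect_true(all(res$table$p[res$table$term != "Residuals"] == 1))
  expect_error(gait_anova(rnorm(10), rep("PD", 10), rep(c("a", "b"), 5)),
               "empty cell")
})

test_that("Tukey post-hoc is returned for non-degenerate fits", {
  set.seed(11)
  y <- rnorm(40, rep(c(0, 2), each = 20))
  g <- rep(c("PD", "control"), each = 20)
  s <- rep(rep(c("a", "b"), each = 10), 2)
  res <- gait_anova(y, g, s)
  expect_s3_class(res$tukey, "TukeyHSD")
  expect_true("group" %in% names(res$tukey))
})

test_that("Hedges' g reproduces the hand-computed worked example", {
  res <- hedges_g(c(0, 2), c(1, 3))
  expect_equal(res$g_uncorrected, -1 / sqrt(2), tolerance = 1e-12)
  expect_equal(res$g, (1 - 3 / 7) * (-1 / sqrt(2)), tolerance = 1e-12)
  expect_equal(res$g, -0.4040610, tolerance = 1e-6)
  expect_true(res$correction_applied)
})

test_that("Hedges' g symmetry, invariance and correction properties hold", {
  set.seed(12)
  for (k in 1:20) {
    x <- rnorm(sample(5:25, 1)); y <- rnorm(sample(5:25, 1), mean = runif(1, -2, 2))
    a <- runif(1, 0.5, 3); c0 <- runif(1, -5, 5)
    expect_equal(hedges_g(x, y)$g, -hedges_g(y, x)$g, tolerance = 1e-12)
    expect_equal(hedges_g(a * x + c0, a * y + c0)$g, hedges_g(x, y)$g,
                 tolerance = 1e-9)
    res <- hedges_g(x, y)
    expect_lt(abs(res$g), abs(res$g_uncorrected))
    # disabling the correction reproduces the literal quotient
    sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                 (length(x) + length(y) - 2))
    expect_equal(hedges_g(x, y, correct = FALSE)$g,
                 (mean(x) - mean(y)) / sp, tolerance = 1e-12)
  }
  expect_equal(hedges_g(c(1, 2, 3), c(2, 3, 1))$g, 0)
  expect_error(hedges_g(rep(1, 5), rep(1, 5)), "pooled SD")
})

test_that("subgroup threshold is the control mean plus one sample SD", {
  res <- select_subgroup(c(14, 15, 15.01, 40), c(5, 10, 15))
  expect_equal(res$threshold, 15)   # mean 10 + sample SD 5
  expect_equal(res$selected, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(res$n_selected, 2)
  none <- select_subgroup(c(1, 2), c(5, 10, 15))
  expect_equal(none$n_selected, 0)
  expect_error(select_subgroup(10, 5), "at least 2 control")
})

test_that("bootstrap correlation handles collinear data and symmetry", {
  x <- 1:10
  res <- pearson_bootstrap(x, 2 * x + 1, seed = 13)
  expect_equal(res$r, 1)
  expect_equal(res$p_value, 0)
  expect_equal(c(res$ci_low, res$ci_high), c(1, 1))

  set.seed(14)
  a <- rnorm(20); b <- a + rnorm(20, sd = 0.7)
  r1 <- pearson_bootstrap(a, b, seed = 15)
  r2 <- pearson_bootstrap(a, -b, seed = 15)
  expect_equal(r1$r, -r2$r, tolerance = 1e-12)
  expect_true(r1$ci_low <= 1 && r1$ci_high <= 1 && r1$ci_low >= -1)
  expect_error(pearson_bootstrap(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(pearson_bootstrap(1:2, 2:1), "at least 3")
})

test_that("the bootstrap is bit-reproducible under a fixed seed", {
  set.seed(16)
  x <- rnorm(20); y <- x + rnorm(20)
  r1 <- pearson_bootstrap(x, y, seed = 99)
  r2 <- pearson_bootstrap(x, y, seed = 99)
  expect_identical(r1[c("r", "ci_low", "ci_high")],
                   r2[c("r", "ci_low", "ci_high")])
  r3 <- pearson_bootstrap(x, y, seed = 100)
  expect_false(identical(r1$ci_low, r3$ci_low))
})

test_that("percentile intervals bracket the point estimate", {
  set.seed(17)
  for (k in 1:10) {
    x <- rnorm(25); y <- 0.5 * x + rnorm(25)
    res <- pearson_bootstrap(x, y, seed = k, ci_type = "percentile")
    expect_true(res$ci_low <= res$r && res$r <= res$ci_high)
  }
})
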