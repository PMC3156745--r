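test_that("spearman_survival handles monotone and tied inputs", {
  expect_equal(spearman_survival(c(1, 2, 3), c(3, 2, 1))$r_s, -1)
  expect_equal(spearman_survival(c(1, 2, 3), c(10, 20, 30))$r_s, 1)
  # mid-ranks (1.5, 1.5, 3) vs (1, 2, 3): Pearson = sqrt(3)/2
  expect_equal(spearman_survival(c(1, 1, 2), c(1, 2, 3))$r_s, sqrt(3) / 2,
               tolerance = 1e-12)
  expect_error(spearman_survival(c(2, 2, 2), 1:3), "constant")
  expect_error(spearman_survival(1:3, 1:4), "same length")
})

test_that("the t approximation reproduces the screening significance scale", {
  # r = 0.32 at n = 63: t* = 0.32 sqrt(61 / (1 - 0.32^2)), p ~ 0.011 < 0.05
  p <- 2 * pt(-0.32 * sqrt(61 / (1 - 0.32^2)), df = 61)
  x <- isir:::spearman_t_pvalue(0.32, 63)
  expect_equal(x, p, tolerance = 1e-12)
  expect_lt(x, 0.05)
  expect_equal(x, 0.011, tolerance = 0.05)
})

test_that("spearman equals the Pearson-on-mid-ranks oracle on random tied data", {
  set.seed(404)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    x <- sample(1:4, n, replace = TRUE)
    t <- round(rexp(n, 1 / 20), sample(0:1, 1)) + 0.5
    if (length(unique(x)) < 2 || length(unique(t)) < 2) next
    rx <- rank(x); rt <- rank(t)
    oracle <- sum((rx - mean(rx)) * (rt - mean(rt))) /
      sqrt(sum((rx - mean(rx))^2) * sum((rt - mean(rt))^2))
    expect_equal(spearman_survival(x, t)$r_s, oracle, tolerance = 1e-12)
  }
})

test_that("spearman is antisymmetric under order reversal of survival", {
  set.seed(11)
  for (i in 1:50) {
    x <- sample(1:4, 20, replace = TRUE)
    t <- rexp(20)
    if (length(unique(x)) < 2) next
    a <- spearman_survival(x, t)
    b <- spearman_survival(x, max(t) + min(t) - t)
    expect_equal(a$r_s, -b$r_s, tolerance = 1e-12)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  }
})

test_that("exact permutation p-value agrees with the t approximation in rank order", {
  set.seed(5)
  x <- c(1, 2, 2, 3, 4, 1)
  t <- rexp(6)
  ex <- spearman_survival(x, t, p_method = "exact")
  expect_gte(ex$p_value, 0)
  expect_lte(ex$p_value, 1)
  # perfect monotone pair is the most extreme of the 4! permutations
  expect_equal(spearman_survival(1:4, 1:4, p_method = "exact")$p_value,
               2 / 24, tolerance = 1e-12)
  expect_error(spearman_survival(rep(1:3, 4), rexp(12), p_method = "exact"),
               "n <= 8")
})

test_that("kaplan_meier matches the empirical survival function without censoring", {
  km <- kaplan_meier(c(5, 10, 15), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  set.seed(2)
  tt <- sample(1:100, 30)
  km2 <- kaplan_meier(tt, rep(1, 30))
  emp <- vapply(km2$time, function(s) mean(tt > s), 0)
  expect_equal(km2$survival, emp, tolerance = 1e-12)
  expect_true(all(diff(km2$survival) <= 0))
  expect_true(all(diff(km2$n_risk) <= 0))
})

test_that("kaplan_meier handles censoring by shrinking the risk set", {
  km <- kaplan_meier(c(5, 10, 15), c(1, 0, 1))
  expect_equal(km$survival[km$time == 5], 2 / 3)
  expect_equal(km$survival[km$time == 15], 0)  # risk set of 1 at t = 15
  all_cens <- kaplan_meier(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(all_cens$survival == 1))
  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
  expect_error(kaplan_meier(c(0, 5), c(1, 1)), "positive")
})

test_that("logrank_test is zero on identical groups and detects separation", {
  tt <- c(3, 7, 12, 20, 41)
  ev <- c(1, 1, 0, 1, 1)
  same <- logrank_test(c(tt, tt), c(ev, ev), rep(c("a", "b"), each = 5))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  sep <- logrank_test(c(1, 2, 3, 10, 20, 30), rep(1, 6), rep(c("a", "b"), each = 3))
  expect_gt(sep$statistic, 3.84)
  expect_lt(sep$p_value, 0.05)

  four <- logrank_test(rexp(40, 1 / 20) + 1, rep(1, 40), rep(1:4, each = 10))
  expect_equal(four$df, 3L)

  expect_error(logrank_test(tt, ev, factor(rep("a", 5), levels = c("a", "b"))),
               "group")
  expect_error(logrank_test(tt, rep(0, 5), rep(c("a", "b"), length.out = 5)),
               "no events")
})

test_that("logrank statistic is invariant to relabeling and monotone time transforms", {
  set.seed(77)
  tt <- rexp(40, 1 / 25) + 0.1
  ev <- rbinom(40, 1, 0.8)
  g <- sample(c("x", "y", "z"), 40, replace = TRUE)
  a <- logrank_test(tt, ev, g)
  b <- logrank_test(tt, ev, chartr("xyz", "zxy", g))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-10)
  c_ <- logrank_test(log(1 + tt), ev, g)
  expect_equal(a$statistic, c_$statistic, tolerance = 1e-10)
})

test_that("survival groups split at 12 and 60 months with inclusive boundaries", {
  expect_equal(as.character(assign_survival_group(10, 1)), "le12")
  expect_equal(as.character(assign_survival_group(25, 1)), "mid")
  expect_equal(as.character(assign_survival_group(12, 1)), "le12")
  expect_equal(as.character(assign_survival_group(60, 0)), "ge60")
  expect_equal(as.character(assign_survival_group(100, 0)), "ge60")
  expect_error(assign_survival_group(0), "positive")
  grp <- assign_survival_group(c(5, 30, 80), c(1, 1, 0))
  expect_equal(levels(grp), c("le12", "mid", "ge60"))
  expect_false(anyNA(grp))
})
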