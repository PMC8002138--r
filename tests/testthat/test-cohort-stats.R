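# Cohort statistics: normality gate, group comparisons, chi-square,
# correlation grids, and standardized regressions.

test_that("KS normality check accepts normal samples and rejects exponential ones", {
  set.seed(14)
  normal_ok <- sum(vapply(1:50, function(i) {
    test_normality(rnorm(200))$is_normal
  }, logical(1)))
  expect_gte(normal_ok, 45)  # >= 90% of seeds

  expo_flagged <- sum(vapply(1:50, function(i) {
    !test_normality(rexp(500))$is_normal
  }, logical(1)))
  expect_gte(expo_flagged, 48)  # >= 95% of seeds

  const <- test_normality(rep(3, 10))
  expect_true(const$degenerate)
  expect_error(test_normality(c(1, 2)), "at least 3")
})

test_that("group comparison picks ANOVA with Tukey post hoc for normal data and degenerates sensibly", {
  set.seed(23)
  tab <- data.frame(group = rep(c("a", "b", "c"), each = 50),
                    v = rnorm(150, 100, 10))
  gc <- compare_groups(tab, "v")
  expect_equal(gc$test_used, "anova")
  expect_length(gc$posthoc, 3L)
  expect_true(all(gc$posthoc >= 0 & gc$posthoc <= 1))

  # identical groups: F = 0, p = 1
  same <- data.frame(group = rep(c("a", "b", "c"), each = 10),
                     v = rep(rnorm(10, 50, 5), 3))
  gs <- compare_groups(same, "v")
  expect_equal(gs$statistic, 0, tolerance = 1e-12)
  expect_equal(gs$p_value, 1, tolerance = 1e-12)

  # a strongly skewed variable goes down the Kruskal-Wallis path
  skew <- data.frame(group = rep(c("a", "b", "c"), each = 100),
                     v = rexp(300)^2)
  expect_equal(compare_groups(skew, "v")$test_used, "kruskal-wallis")

  expect_error(compare_groups(tab, "missing_var"), "missing variable")
  small <- data.frame(group = c("a", "a", "a", "b", "b"), v = 1:5)
  expect_error(compare_groups(small, "v"), "n < 3")
})

test_that("shifted group means are detected with high power", {
  set.seed(37)
  hits <- sum(vapply(1:40, function(i) {
    tab <- data.frame(
      group = rep(c("a", "b", "c"), each = 50),
      v = c(rnorm(50, 0), rnorm(50, 0), rnorm(50, 2))  # 2 SD shift
    )
    compare_groups(tab, "v")$p_value < 0.05
  }, logical(1)))
  expect_gte(hits, 40 * 0.99 - 1)
})

test_that("chi-square matches the hand formula and rejects degenerate tables", {
  m <- matrix(c(10, 20, 20, 10), 2, 2, byrow = TRUE)
  res <- chi_square_counts(m)
  # hand formula: sum((O - E)^2 / E) with E from the margins
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(res$statistic, sum((m - expected)^2 / expected), tolerance = 1e-9)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-9)
  expect_equal(res$p_value, 1 - pchisq(20 / 3, 1), tolerance = 1e-9)

  eq <- matrix(c(10, 20, 10, 20), 2, 2, byrow = TRUE)
  res_eq <- chi_square_counts(eq)
  expect_equal(res_eq$statistic, 0, tolerance = 1e-12)
  expect_equal(res_eq$p_value, 1, tolerance = 1e-12)

  expect_error(chi_square_counts(matrix(c(5, 0, 7, 0), 2, 2)), "zero marginal")
})

test_that("pearson grid returns r = 1 for identical layers and near-zero for independent ones", {
  set.seed(61)
  tab <- data.frame(group = rep(c("a", "b"), each = 40))
  tab$gcl_central <- rnorm(80, 16, 4)
  tab$mrnfl_central <- tab$gcl_central  # y = x
  grid <- pearson_grid(tab, "gcl", "mrnfl", "central")
  expect_true(all(abs(grid$r - 1) < 1e-12))

  tab$mrnfl_central <- rnorm(80)
  tab_big <- data.frame(group = "a",
                        gcl_central = rnorm(5000),
                        mrnfl_central = rnorm(5000))
  g2 <- pearson_grid(tab_big, "gcl", "mrnfl", "central")
  expect_lt(abs(g2$r), 0.05)

  tab$gcl_central <- 5  # constant -> flagged
  gf <- pearson_grid(tab, "gcl", "mrnfl", "central")
  expect_true(all(gf$flagged))
  expect_true(all(is.na(gf$r)))
})

test_that("standardized univariate coefficient equals the Pearson correlation exactly", {
  co <- generate_cohort(default_cohort_spec(seed = 31))
  for (dep in c("raod", "wcsa", "wlr")) {
    reg <- univariate_regression(co, dep, "gcl_central")
    expect_equal(reg$standardized_coefficient,
                 cor(co[[dep]], co$gcl_central), tolerance = 1e-9)
  }
  # affine self-prediction: standardized coefficient 1 (lm warns about the
  # deliberately perfect fit)
  co$double_gcl <- 2 * co$gcl_central + 7
  reg1 <- suppressWarnings(univariate_regression(co, "double_gcl", "gcl_central"))
  expect_equal(reg1$standardized_coefficient, 1, tolerance = 1e-12)
  expect_lt(reg1$p_value, 1e-12)

  expect_error(univariate_regression(transform(co, k = 1), "raod", "k"),
               "constant predictor")
})

test_that("adjusted regression matches the univariate fit under independent covariates and flags collinearity", {
  set.seed(91)
  n <- 2000
  tab <- data.frame(
    x = rnorm(n), age = rnorm(n, 60, 10), gender_male = rbinom(n, 1, 0.5),
    diabetes_duration = rnorm(n, 10, 5), hba1c = rnorm(n, 9, 2)
  )
  tab$y <- 0.4 * tab$x + rnorm(n)
  uni <- univariate_regression(tab, "y", "x")
  adj <- adjusted_regression(tab, "y", "x")
  expect_lt(abs(adj$standardized_coefficient - uni$standardized_coefficient), 0.05)

  tab$x2 <- tab$x
  expect_error(adjusted_regression(tab, "y", "x", covariates = c("age", "x2")),
               "collinear.*x2")

  # pure confounding: u drives both; the adjusted coefficient collapses
  u <- rnorm(n)
  conf <- data.frame(x = u + 0.3 * rnorm(n), y = u + 0.3 * rnorm(n), u = u)
  uni_c <- univariate_regression(conf, "y", "x")
  adj_c <- adjusted_regression(conf, "y", "x", covariates = "u")
  expect_gt(uni_c$standardized_coefficient, 0.6)
  expect_lt(abs(adj_c$standardized_coefficient), 0.1)
})

test_that("Tukey-adjusted pairwise p-values are no smaller than unadjusted pairwise t-tests", {
  set.seed(43)
  for (i in 1:10) {
    tab <- data.frame(
      group = rep(c("a", "b", "c"), each = 30),
      v = rnorm(90, 100, 10) + rep(c(0, 1, 2), each = 30) * runif(1, 0, 1)
    )
    gc <- compare_groups(tab, "v")
    if (gc$test_used != "anova") next
    for (pair in names(gc$posthoc)) {
      gs <- strsplit(pair, "-")[[1]]
      raw <- t.test(tab$v[tab$group == gs[1]], tab$v[tab$group == gs[2]],
                    var.equal = TRUE)$p.value
      expect_gte(gc$posthoc[[pair]] + 1e-9, raw)
    }
  }
})
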