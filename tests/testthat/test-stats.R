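test_that("normality gate passes normal cohorts and flags bimodal ones", {
  ok <- 0L
  for (s in 1:20) {
    set.seed(s)
    g <- normality_gate(list(a = rnorm(30, 0.8, 0.05)))
    if (g$shapiro$a$decision == "fail_to_reject") ok <- ok + 1L
  }
  expect_gte(ok, 18L)  # type-I control at alpha 0.05
  set.seed(1)
  bimodal <- c(rep(0.5, 15), rep(0.9, 15)) + rnorm(30, 0, 1e-3)
  g <- normality_gate(list(a = bimodal, b = rnorm(30, 0.8, 0.05)))
  expect_identical(g$shapiro$a$decision, "reject")
  expect_true(g$recommend_nonparametric)
  # degenerate constant sample rejects with a diagnostic note
  gc <- normality_gate(list(a = rep(1, 10)))
  expect_identical(gc$shapiro$a$decision, "reject")
  expect_match(gc$shapiro$a$note, "degenerate")
  expect_error(normality_gate(list(a = c(1, 2))), "n < 3")
})

test_that("rank-sum p-values match brute-force enumeration at small n", {
  w <- wilcoxon_vs_control(c(1, 2, 3), list(t = c(4, 5, 6)), m = 1)
  expect_equal(w$t$p_value, 0.1, tolerance = 1e-12)
  expect_equal(w$t$p_value, wilcoxon_enum_p(c(4, 5, 6), c(1, 2, 3)),
               tolerance = 1e-12)
  set.seed(42)
  for (sizes in list(c(4L, 4L), c(5L, 5L), c(4L, 6L))) {
    ctrl <- runif(sizes[1]); test <- runif(sizes[2]) + 0.3
    w <- wilcoxon_vs_control(ctrl, list(t = test), m = 1)
    expect_equal(w$t$p_value, wilcoxon_enum_p(test, ctrl),
                 tolerance = 1e-12)
  }
})

test_that("identical cohorts fail to reject; Bonferroni is monotone", {
  x <- c(0.7, 0.8, 0.9, 1.0, 1.1)
  w <- wilcoxon_vs_control(x, list(same = x), m = 7)
  expect_identical(w$same$decision, "fail_to_reject")
  expect_gte(w$same$p_value, 0.99)
  set.seed(3)
  for (m in c(1, 3, 7, 20)) {
    w <- wilcoxon_vs_control(rnorm(10), list(t = rnorm(10) + 1), m = m)
    expect_gte(w$t$adjusted_p, w$t$p_value)
    expect_equal(w$t$adjusted_p, min(1, m * w$t$p_value))
    expect_equal(w$t$alpha_cutoff, 0.05 / m)
  }
})

test_that("Pearson correlation: exact limits and null behaviour", {
  lin <- data.frame(normalized_intensity = 1:10,
                    surface_factor = 2 * (1:10) + 3)
  expect_equal(pearson_intensity_vs_shape(lin)$r, 1, tolerance = 1e-12)
  lin$surface_factor <- -lin$surface_factor
  expect_equal(pearson_intensity_vs_shape(lin)$r, -1, tolerance = 1e-12)
  ok <- 0L
  for (s in 1:20) {
    set.seed(s)
    d <- data.frame(normalized_intensity = rnorm(30),
                    surface_factor = rnorm(30))
    if (abs(pearson_intensity_vs_shape(d)$r) < 0.36) ok <- ok + 1L
  }
  expect_gte(ok, 18L)   # 0.36 is the 5% critical value at n = 30
  bad <- data.frame(normalized_intensity = rep(1, 5),
                    surface_factor = 1:5)
  expect_error(pearson_intensity_vs_shape(bad), "zero variance")
})

test_that("chi-square independence statistic matches hand computation", {
  even <- matrix(c(10, 10, 10, 10), 2)
  r <- chi_square_independence(even)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # hand computation: all E = 12.5, sum((O-E)^2/E) = 4 * 7.5^2 / 12.5 = 18
  skew <- matrix(c(20, 5, 5, 20), 2)
  hand <- sum((skew - outer(rowSums(skew), colSums(skew)) / sum(skew))^2 /
                (outer(rowSums(skew), colSums(skew)) / sum(skew)))
  expect_equal(chi_square_independence(skew)$statistic, hand)
  expect_equal(chi_square_independence(skew)$statistic, 18)
  # proportional rows are exactly independent
  prop <- matrix(c(10, 20, 15, 30), 2)
  expect_equal(chi_square_independence(prop)$statistic, 0,
               tolerance = 1e-12)
  # invariance under row and column swaps
  expect_equal(chi_square_independence(skew[2:1, ])$statistic, 18)
  expect_equal(chi_square_independence(skew[, 2:1])$statistic, 18)
  expect_error(chi_square_independence(matrix(c(0, 0, 5, 5), 2)),
               "marginal")
})

test_that("comparative-Ct fold changes follow the definition", {
  expect_equal(ddct_fold_change(20, 20, 20, 20)$fold_change, 1)
  # ddCt = -1 doubles expression
  r <- ddct_fold_change(19, 18, 20, 18)
  expect_equal(r$ddct, -1)
  expect_equal(r$fold_change, 2)
  r2 <- ddct_fold_change(c(20, 20, 20), c(18, 18, 18),
                         c(22, 22, 22), c(18, 18, 18))
  expect_equal(r2$ddct, -2)
  expect_equal(r2$fold_change, 4)
  # reciprocal property: fold(x) * fold(-x) = 1
  a <- ddct_fold_change(21, 18, 20, 18)$fold_change
  b <- ddct_fold_change(19, 18, 20, 18)$fold_change
  expect_equal(a * b, 1, tolerance = 1e-12)
  expect_error(ddct_fold_change(numeric(0), 1, 1, 1), "non-empty")
})

test_that("reporter repression percentages and sign convention", {
  expect_equal(reporter_repression(350, 100, 1000, 100), 65)
  expect_equal(reporter_repression(500, 100, 500, 100), 0)
  expect_equal(reporter_repression(1000, 100, 500, 100), -100)
  expect_error(reporter_repression(350, 0, 1000, 100), "> 0")
})

test_that("population intensity ratio with bootstrap CI", {
  expect_equal(population_intensity_ratio(125, 100)$percent_difference,
               25)
  expect_equal(population_intensity_ratio(1:10, 1:10)$percent_difference,
               0)
  set.seed(99)
  a <- rnorm(138, 125, 125 * 0.3)
  b <- rnorm(249, 100, 100 * 0.3)
  r <- population_intensity_ratio(a, b, seed = 7L)
  expect_lt(r$ci[1], 25)
  expect_gt(r$ci[2], 25)
  r2 <- population_intensity_ratio(a, b, seed = 7L)
  expect_identical(r$ci, r2$ci)   # seeded bootstrap is reproducible
})

test_that("box-plot summaries report quartiles and outliers per cohort", {
  v <- c(rnorm(29, 0.8, 0.02), 2)
  bs <- cohort_box_stats(list(ctrl = v, other = rnorm(30)))
  expect_equal(nrow(bs), 2L)
  expect_equal(bs$median[1], median(v))
  expect_equal(bs$q1[1], unname(quantile(v, 0.25)))
  expect_gte(bs$n_outliers[1], 1L)
})
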