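test_that("normality gate selects branches as expected on seeded samples", {
  # normal data: parametric in >= 90% of 100 seeds
  hits <- sum(sapply(1:100, function(s) {
    g <- gen_group_measurements(seed = s, effects = c(a = 0), n = 30)
    normality_gate(g)$branch == "parametric"
  }))
  expect_gte(hits, 90)
  # strongly log-normal data: nonparametric in >= 90% of seeds
  hits_ln <- sum(sapply(1:100, function(s) {
    g <- gen_group_measurements(seed = s, effects = c(a = 0), n = 30,
                                distribution = "lognormal", sd = 1)
    normality_gate(g)$branch == "nonparametric"
  }))
  expect_gte(hits_ln, 90)
  # degenerate group -> nonparametric with warning
  expect_warning(gt <- normality_gate(list(a = rep(1, 5), b = rnorm(5))),
                 "degenerate|small")
  expect_equal(gt$branch, "nonparametric")
  expect_warning(normality_gate(list(a = c(1, 2), b = rnorm(5))))
})

test_that("one-way ANOVA matches the closed-form sum-of-squares oracle", {
  data <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  # independent oracle: SSB/(k-1) / (SSW/(N-k))
  gm <- mean(unlist(data))
  ssb <- sum(sapply(data, function(g) length(g) * (mean(g) - gm)^2))
  ssw <- sum(sapply(data, function(g) sum((g - mean(g))^2)))
  f_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(f_oracle, 3)
  rep <- compare_groups(data, design = "oneway",
                        gate = list(branch = "parametric",
                                    shapiro_p = c(1, 1, 1)))
  expect_equal(rep$statistic, f_oracle, tolerance = 1e-9)
  expect_equal(rep$test_used, "one-way ANOVA + Tukey")
  # identical groups: F = 0, p = 1
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  rep0 <- compare_groups(same, design = "oneway",
                         gate = list(branch = "parametric",
                                     shapiro_p = c(1, 1, 1)))
  expect_equal(rep0$statistic, 0)
  expect_equal(rep0$p_value, 1)
})

test_that("two-group comparisons detect a 5-sd shift on both branches", {
  g <- gen_group_measurements(seed = 77, effects = c(a = 0, b = 5), n = 20)
  rep_t <- compare_groups(g, design = "two",
                          gate = list(branch = "parametric",
                                      shapiro_p = c(1, 1)))
  rep_w <- compare_groups(g, design = "two",
                          gate = list(branch = "nonparametric",
                                      shapiro_p = c(0, 0)))
  expect_lt(rep_t$p_value, 0.001)
  expect_lt(rep_w$p_value, 0.001)
  expect_equal(rep_t$test_used, "t-test")
  expect_equal(rep_w$test_used, "Mann-Whitney U")
})

test_that("post-hoc adjusted p-values never undercut the unadjusted ones", {
  set.seed(5)
  data <- list(a = rnorm(12), b = rnorm(12, 0.8), c = rnorm(12, 1.6))
  sk <- compare_groups(data, design = "oneway", posthoc = "sidak",
                       gate = list(branch = "parametric",
                                   shapiro_p = c(1, 1, 1)))
  expect_true(all(sk$posthoc$p_adj >= sk$posthoc$p_unadj - 1e-12))
  dn <- compare_groups(data, design = "oneway",
                       gate = list(branch = "nonparametric",
                                   shapiro_p = c(0, 0, 0)))
  expect_true(all(dn$posthoc$p_adj >= dn$posthoc$p_unadj - 1e-12))
  expect_equal(dn$test_used, "Kruskal-Wallis + Dunn")
})

test_that("rank-based branch is invariant to monotone affine transforms", {
  set.seed(6)
  data <- list(a = rnorm(15), b = rnorm(15, 1), c = rnorm(15, 2))
  gate <- list(branch = "nonparametric", shapiro_p = c(0, 0, 0))
  r1 <- compare_groups(data, design = "oneway", gate = gate)
  r2 <- compare_groups(lapply(data, function(v) 3 * v + 10),
                       design = "oneway", gate = gate)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_equal(r1$posthoc$p_adj, r2$posthoc$p_adj, tolerance = 1e-12)
  # ordering invariance
  r3 <- compare_groups(data[c(3, 1, 2)], design = "oneway", gate = gate)
  expect_equal(r3$statistic, r1$statistic, tolerance = 1e-12)
})

test_that("two-way ANOVA handles grouped designs", {
  set.seed(8)
  df <- expand.grid(group = c("ctrl", "ftd"),
                    factor2 = c("vehicle", "topotecan"),
                    rep = 1:8)
  df$value <- rnorm(nrow(df)) + 2 * (df$factor2 == "topotecan")
  rep <- compare_groups(df, design = "grouped_twoway")
  expect_equal(rep$test_used, "two-way ANOVA + Tukey")
  expect_true(is.finite(rep$statistic))
  expect_error(compare_groups(list(a = 1:3, b = 1:3), design = "oneway"),
               "> 2 groups")
})

test_that("chi-square matches closed-form and brute-force oracles", {
  r <- chi_square(matrix(c(10, 20, 20, 10), 2))
  # closed form N(ad-bc)^2 / (r1 r2 c1 c2)
  expect_equal(r$statistic, 60 * (10 * 10 - 20 * 20)^2 / (30 * 30 * 30 * 30),
               tolerance = 1e-9)
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-9)
  expect_equal(r$df, 1)
  # proportional rows -> 0
  expect_equal(chi_square(matrix(c(10, 20, 30, 60), 2))$statistic, 0)
  # random small tables vs sum((O-E)^2/E)
  set.seed(13)
  for (i in 1:5) {
    tab <- matrix(rpois(6, 20) + 1, 2, 3)
    ex <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(chi_square(tab)$statistic, sum((tab - ex)^2 / ex),
                 tolerance = 1e-9)
  }
  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2)), "zero marginal")
})

test_that("ANOVA type-I error is calibrated at ~5% under the null", {
  rejections <- sum(sapply(1:1000, function(s) {
    g <- gen_group_measurements(seed = 2000 + s,
                                effects = c(a = 0, b = 0, c = 0), n = 10)
    rep <- compare_groups(g, design = "oneway",
                          gate = list(branch = "parametric",
                                      shapiro_p = c(1, 1, 1)))
    rep$p_value < 0.05
  }))
  expect_gte(rejections / 1000, 0.03)
  expect_lte(rejections / 1000, 0.07)
})

test_that("a 2-sd shift is detected with >= 80% power at n = 20", {
  hits <- sum(sapply(1:200, function(s) {
    g <- gen_group_measurements(seed = 3000 + s, effects = c(a = 0, b = 2),
                                n = 20)
    compare_groups(g, design = "two",
                   gate = list(branch = "parametric",
                               shapiro_p = c(1, 1)))$p_value < 0.05
  }))
  expect_gte(hits / 200, 0.8)
})

test_that("ROUT-style screen flags gross outliers and spares clean data", {
  r <- rout_outliers(c(1:10, 100))
  expect_equal(r$flagged, 100)
  expect_equal(sort(c(r$kept, r$flagged)), sort(c(1:10, 100)))
  # clean normal clusters: flags at most 1 point in >= 95% of seeds
  ok <- sum(sapply(1:100, function(s) {
    set.seed(s)
    length(rout_outliers(rnorm(50))$flagged) <= 1
  }))
  expect_gte(ok, 95)
  expect_warning(r2 <- rout_outliers(c(1, 2)), "fewer than 3")
  expect_equal(length(r2$flagged), 0)
})
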