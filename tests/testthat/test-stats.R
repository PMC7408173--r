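# Frozen reference values for the D'Agostino-Pearson omnibus statistic,
# computed once with an independent implementation of the same published
# transformations (scipy.stats.normaltest) on the vectors below.
dp_normal30 <- c(10.609434, 7.920032, 11.500902, 11.881129, 6.09793,
                 7.395641, 10.255681, 9.367515, 9.966398, 8.293912,
                 11.758796, 11.555584, 10.132061, 12.254482, 10.935019,
                 8.281415, 10.737502, 8.082235, 11.756901, 9.900148,
                 9.630275, 8.638141, 12.445083, 9.690941, 9.143344,
                 9.295733, 11.064618, 10.730888, 10.825465, 10.861642)
dp_heavy30 <- c(10.714263, 1.849551, 7.307119, 4.397499, 0.460977,
                6.890672, -8.001839, 3.284415, 5.661488, 11.421624,
                19.00831, 5.756356, -0.823252, 2.762542, 2.707445,
                2.785534, 2.809066, 5.380702, 7.771891, 3.930358,
                7.096048, -1.64127, 2.131721, 5.471541, 3.522919,
                8.492412, 8.630326, 0.341937, -0.356206, 3.543635)

test_that("the normality K^2 statistic matches the frozen reference", {
  a <- dagostino_pearson(dp_normal30)
  expect_equal(a$statistic, 1.9577805740469905, tolerance = 1e-10)
  expect_equal(a$p.value, 0.3757278176243716, tolerance = 1e-10)
  b <- dagostino_pearson(dp_heavy30)
  expect_equal(b$statistic, 6.3091358482364015, tolerance = 1e-10)
  expect_equal(b$p.value, 0.04265682799800602, tolerance = 1e-10)
  expect_error(dagostino_pearson(rnorm(5)), "n >= 8")
})

test_that("identically drawn groups show no significant differences", {
  set.seed(101)
  v <- rnorm(60)
  g <- rep(c("ctrl", "b", "c"), each = 20)
  rep <- compare_groups(v, g, control = "ctrl", alpha = 0.001)
  expect_gt(rep$omnibus$p.value, 0.001)
  expect_false(any(rep$comparisons$significant))
  expect_true(all(rep$comparisons$p_adjusted >= rep$comparisons$p_unadjusted,
                  na.rm = TRUE))
})

test_that("heavy-tailed groups route to the nonparametric path", {
  set.seed(7)
  v <- c(rt(40, df = 2), rt(40, df = 2), rt(40, df = 2) + 2)
  g <- rep(c("ctrl", "b", "c"), each = 40)
  # path-selection oracle: the normality gate applied by hand
  gate <- vapply(split(v, g), function(x) dagostino_pearson(x)$p.value, 1)
  expect_true(any(gate <= 0.05))
  rep <- compare_groups(v, g, control = "ctrl")
  expect_equal(rep$family, "nonparametric")
  expect_equal(rep$omnibus$method, "Kruskal-Wallis")
})

test_that("near-normal groups route to ANOVA + Dunnett", {
  set.seed(8)
  v <- rnorm(90, mean = rep(c(0, 0, 1.5), each = 30))
  g <- rep(c("ctrl", "b", "c"), each = 30)
  gate <- vapply(split(v, g), function(x) dagostino_pearson(x)$p.value, 1)
  expect_true(all(gate > 0.05))
  rep <- compare_groups(v, g, control = "ctrl", alpha = 0.01)
  expect_equal(rep$family, "parametric")
  expect_equal(rep$omnibus$method, "one-way ANOVA")
  expect_true(rep$comparisons$significant[rep$comparisons$group == "c"])
  expect_false(rep$comparisons$significant[rep$comparisons$group == "b"])
})

test_that("small groups force the nonparametric path with a flag", {
  set.seed(9)
  v <- c(rnorm(6), rnorm(20), rnorm(20))
  g <- rep(c("ctrl", "b", "c"), c(6, 20, 20))
  rep <- compare_groups(v, g, control = "ctrl")
  expect_equal(rep$family, "nonparametric")
  expect_match(rep$flags, "n < 8")
})

test_that("large median shifts are detected at alpha 0.001 in >=95% of runs", {
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    v <- c(rlnorm(100, 0, 0.5), rlnorm(100, 1.2, 0.5))
    g <- rep(c("ctrl", "shift"), each = 100)
    rep <- compare_groups(v, g, control = "ctrl", alpha = 0.001,
                          family = "nonparametric")
    if (rep$comparisons$significant[1]) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("null rejection rate of the nonparametric path is calibrated", {
  set.seed(2024)
  rejections <- 0
  n_sim <- 2000
  for (i in seq_len(n_sim)) {
    v <- rexp(45)
    g <- rep(c("ctrl", "b", "c"), each = 15)
    p <- stats::kruskal.test(v, factor(g))$p.value
    if (p < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections / n_sim, 0.03)
  expect_lte(rejections / n_sim, 0.07)
})

test_that("Dunn adjusted p values are monotone in the number of comparisons", {
  set.seed(30)
  v <- rnorm(80)
  g4 <- rep(c("ctrl", "b", "c", "d"), each = 20)
  two <- nucquant:::dunn_vs_control(v[g4 %in% c("ctrl", "b")],
                                    g4[g4 %in% c("ctrl", "b")], "ctrl")
  four <- nucquant:::dunn_vs_control(v, g4, "ctrl")
  expect_gte(four$p_adjusted[four$group == "b"], two$p_adjusted)
})

test_that("two-group t test matches the hand-computed Welch statistic", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(2, 4, 6, 8, 10)
  got <- two_group_test(a, b)
  # hand calculation: t = (3 - 6) / sqrt(2.5/5 + 10/5)
  se <- sqrt(var(a) / 5 + var(b) / 5)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 5)^2 / 4 + (var(b) / 5)^2 / 4)
  expect_equal(got$statistic, t_hand, tolerance = 1e-6)
  expect_equal(got$df, df_hand, tolerance = 1e-6)
  expect_equal(got$p.value,
               2 * stats::pt(-abs(t_hand), df_hand), tolerance = 1e-6)
  # symmetry and identity
  swapped <- two_group_test(b, a)
  expect_equal(swapped$p.value, got$p.value)
  expect_equal(swapped$statistic, -got$statistic)
  same <- two_group_test(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # zero variance in both samples is undefined and flagged
  z <- two_group_test(c(1, 1, 1), c(1, 1, 1))
  expect_true(z$flagged)
  expect_true(is.na(z$p.value))
})
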