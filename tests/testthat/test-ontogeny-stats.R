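test_that("normality gate branches on Shapiro-Wilk per group", {
  # exact normal quantiles: as normal as data can be -> parametric
  g1 <- qnorm(ppoints(30)); g2 <- qnorm(ppoints(30)) * 2 + 5
  gate <- normality_gate(c(g1, g2), rep(c("a", "b"), each = 30))
  expect_equal(gate$branch, "parametric")
  expect_equal(nrow(gate$shapiro), 2L)
  expect_true(all(gate$shapiro$p_value > 0.05))
  # large uniform samples: decisively non-normal
  u <- vertiso:::with_seed(8, runif(1000))
  gate2 <- normality_gate(u, rep(c("a", "b"), each = 500))
  expect_equal(gate2$branch, "nonparametric")
  # degenerate groups are refused
  expect_error(normality_gate(c(1, 1, 1, g1), rep(c("a", "b"), c(3, 30))),
               "zero variance")
  expect_error(normality_gate(c(1, 2, g1), rep(c("a", "b"), c(2, 30))),
               "n >= 3")
})

test_that("Dunn post-hoc matches hand-enumerated ranks", {
  # groups {1,2} {3,4} {5,6}: mean ranks 1.5/3.5/5.5, no ties,
  # variance term N(N+1)/12 = 3.5 -> z13 = 4/sqrt(3.5), z12 = z23 = 2/sqrt(3.5)
  d <- dunn_test(1:6, rep(c("a", "b", "c"), each = 2))
  z13 <- 4 / sqrt(3.5)
  z12 <- 2 / sqrt(3.5)
  expect_equal(abs(d$z[d$group_a == "a" & d$group_b == "c"]), z13)
  expect_equal(abs(d$z[d$group_a == "a" & d$group_b == "b"]), z12)
  expect_equal(d$p_value, 2 * pnorm(-abs(d$z)))
  expect_equal(d$p_adjusted, pmin(1, d$p_value * 3))
  # tie correction: duplicated values lower the variance term
  dt <- dunn_test(c(1, 1, 2, 2, 5, 6), rep(c("a", "b", "c"), each = 2))
  expect_true(all(is.finite(dt$z)))
})

test_that("independent comparisons follow the gate branch", {
  vertiso:::with_seed(15, {
    a <- rnorm(40); b <- rnorm(40); c3 <- rnorm(40, 10, 0.5)
    rep3 <- compare_groups(c(a, b, c3), rep(c("a", "b", "c"), each = 40))
    expect_equal(rep3$test_name, "one-way ANOVA")
    expect_lt(rep3$p_value, 1e-6)
    ph <- rep3$posthoc
    expect_lt(ph$p_adjusted[ph$contrast == "c-a"], 1e-6)
    expect_lt(ph$p_adjusted[ph$contrast == "c-b"], 1e-6)
    expect_gt(ph$p_adjusted[ph$contrast == "b-a"], 0.05)
    expect_match(rep3$decision_path, "Tukey")
    # two identical groups: t/F statistic near 0, p near 1
    rep2 <- compare_groups(c(a, a), rep(c("g1", "g2"), each = 40))
    expect_lt(abs(rep2$statistic), 1e-10)
    expect_gt(rep2$p_value, 0.99)
    # nonparametric k = 3: Kruskal-Wallis + Dunn
    u <- runif(300)
    repnp <- compare_groups(c(u, u + 0.02, u + 5),
                            rep(c("a", "b", "c"), each = 300))
    expect_equal(repnp$test_name, "Kruskal-Wallis")
    expect_match(repnp$decision_path, "Dunn")
    expect_lt(repnp$posthoc$p_adjusted[repnp$posthoc$group_b == "c"][1],
              1e-6)
    # nonparametric k = 2: two-sample KS
    repks <- compare_groups(c(u, u + 5), rep(c("a", "b"), each = 300))
    expect_equal(repks$test_name, "two-sample Kolmogorov-Smirnov")
    expect_lt(repks$p_value, 1e-6)
  })
})

test_that("omnibus statistic is invariant to group relabelling", {
  vertiso:::with_seed(16, {
    v <- rnorm(90)
    g <- rep(c("a", "b", "c"), each = 30)
    relab <- c(a = "z", b = "x", c = "y")[g]
    r1 <- compare_groups(v, g)
    r2 <- compare_groups(v, relab)
    expect_equal(r1$statistic, r2$statistic)
    expect_equal(r1$p_value, r2$p_value)
  })
})

test_that("paired designs pair by position and handle degeneracy", {
  vertiso:::with_seed(17, {
    x <- rnorm(20)
    y <- x + 0.5 + rnorm(20, 0, 0.1)
    rep <- compare_groups(c(x, y), rep(c("m", "f"), each = 20),
                          design = "paired_2")
    expect_equal(rep$test_name, "paired t-test")
    expect_lt(rep$p_value, 1e-8)
    # identical vectors: no-difference degenerate result, not a crash
    u2 <- runif(300)
    repw <- compare_groups(c(u2, u2 + 0), rep(c("m", "f"), each = 300),
                           design = "paired_2")
    expect_true(repw$p_value > 0.99 || is.na(repw$p_value) ||
                  abs(repw$statistic) < 1e-10)
    expect_error(compare_groups(c(x, y[1:10]),
                                rep(c("m", "f"), c(20, 10)),
                                design = "paired_2"), "equal group lengths")
  })
})

test_that("isotope-age regression recovers exact and degenerate lines", {
  age <- 1:10
  # noiseless line: lm warns about the perfect fit, which is the point here
  fit <- suppressWarnings(isotope_age_regression(age, 0.15 * age - 15))
  expect_equal(fit$slope, 0.15)
  expect_equal(fit$intercept, -15)
  expect_equal(fit$r_squared, 1)
  expect_true(fit$increasing)
  flat <- isotope_age_regression(age, rep(12, 10))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_false(flat$increasing)
  expect_error(isotope_age_regression(c(1, 1, 2), c(1, 2, 3)),
               "distinct ages")
})

test_that("pooled regressions on simulated chronologies recover the trend", {
  cfg <- synthetic_config(n_individuals = 200, sex_counts = c(100, 100),
                          maternal_offset_d13C = 0,
                          maternal_offset_d15N = 0, seed = 23)
  x <- simulate_chronologies(cfg)
  reg <- ontogeny_regressions(x, "13C", "pooled-by-sex")
  pooled <- reg[reg$unit == "combined", ]
  expect_lt(abs(pooled$slope - 0.15), 2 * pooled$se_slope)
  expect_true(pooled$increasing)
  regN <- ontogeny_regressions(x, "15N", "pooled-by-sex")
  expect_false(regN[regN$unit == "combined", "increasing"])
  # per-individual level produces one row per individual with >= 3 bands
  ri <- ontogeny_regressions(x, "13C", "individual")
  expect_equal(nrow(ri), 200L)
})
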