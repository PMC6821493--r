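test_that("the pooled z statistic matches hand-computed values", {
  # pooled p = 0.35, se = sqrt(0.35 * 0.65 * (1/50 + 1/50))
  z <- proportion_z_test(25, 50, 10, 50)
  expect_equal(z$z, 0.3 / sqrt(0.35 * 0.65 * 0.04), tolerance = 1e-12)
  expect_equal(z$z, 3.1449, tolerance = 1e-4)
  expect_equal(z$p_value, 0.001663, tolerance = 1e-3)

  # equal proportions: no signal
  z0 <- proportion_z_test(20, 50, 20, 50)
  expect_identical(z0$z, 0)
  expect_identical(z0$p_value, 1)

  # swapping groups negates z, p unchanged
  zs <- proportion_z_test(10, 50, 25, 50)
  expect_equal(zs$z, -z$z)
  expect_equal(zs$p_value, z$p_value)

  # degenerate pooled proportions carry no information
  expect_identical(proportion_z_test(0, 10, 0, 10)$p_value, 1)
  expect_identical(proportion_z_test(10, 10, 10, 10)$p_value, 1)
})

test_that("z-test type-I error is calibrated on null data", {
  set.seed(23)
  n <- 60
  reps <- 3000
  x1 <- rbinom(reps, n, 0.4)
  x2 <- rbinom(reps, n, 0.4)
  rej <- mapply(function(a, b) proportion_z_test(a, n, b, n)$p_value < 0.05,
                x1, x2)
  expect_gt(mean(rej), 0.035)
  expect_lt(mean(rej), 0.065)
})

test_that("power calculations match the reference implementation", {
  # null case: power collapses to the significance level
  expect_equal(power_two_proportions(0.4, 0.4, 50), 0.05, tolerance = 0.01)

  # agreement with stats::power.prop.test
  expect_equal(
    power_two_proportions(0.35, 0.65, 50),
    power.prop.test(n = 50, p1 = 0.35, p2 = 0.65)$power,
    tolerance = 1e-6
  )

  # more cells, more power
  expect_gt(power_two_proportions(0.35, 0.65, 100),
            power_two_proportions(0.35, 0.65, 50))

  # simulated power agrees with the analytic value within 2 points
  set.seed(5)
  sim <- power_two_proportions(0.35, 0.65, 50, method = "simulation",
                               n_sim = 10000L)
  expect_lt(abs(sim - power_two_proportions(0.35, 0.65, 50)), 0.02)
})

test_that("Chauvenet's criterion rejects the constructed outlier only", {
  expect_identical(chauvenet_outliers(c(10, 10, 10, 10, 50)), 5L)
  # symmetric sample without an extreme point
  expect_length(chauvenet_outliers(c(1, 2, 3, 4, 5)), 0)
  # zero spread: nothing to reject
  expect_length(chauvenet_outliers(rep(7, 5)), 0)
  expect_error(chauvenet_outliers(c(1, 2)), "at least 3")

  # affine invariance
  v <- c(3, 5, 4, 4.5, 20, 4.2, 3.9, 4.1)
  expect_identical(chauvenet_outliers(v), chauvenet_outliers(v * 7 - 100))

  # on standard-normal samples of n = 10 it rejects at most one point in
  # the vast majority of seeded replicates
  set.seed(29)
  n_reject <- replicate(300, length(chauvenet_outliers(rnorm(10))))
  expect_gte(mean(n_reject <= 1), 0.90)
})

test_that("log-transform ANOVA detects separated groups and not null ones", {
  set.seed(31)
  same <- rep(exp(rnorm(5, 0, 0.1)), 2)
  g <- rep(c("a", "b"), each = 5)
  res0 <- log_group_compare(same, g)
  expect_lt(res0$f_statistic, 1e-20)
  expect_gt(res0$p_value, 0.99)

  # ten-fold mean separation at 10% CV
  v <- c(rnorm(5, 1, 0.1), rnorm(5, 10, 1))
  res1 <- log_group_compare(v, g)
  expect_lt(res1$p_value, 0.01)

  # the log transform homogenizes lognormal group variances
  g3 <- rep(c("a", "b", "c"), each = 20)
  v3 <- exp(rnorm(60, rep(c(0, 2, 4), each = 20), 0.5))
  lv <- log(v3)
  med <- tapply(lv, g3, median)
  z <- abs(lv - med[g3])
  lev <- summary(aov(z ~ factor(g3)))[[1]][["Pr(>F)"]][1]
  expect_gt(lev, 0.05)

  expect_error(log_group_compare(c(1, -1, 2, 3), rep("a", 4)), "positive")

  # two-factor path returns a Sidak-adjusted table
  v2 <- exp(rnorm(24, rep(c(0, 1), each = 12), 0.2))
  res2 <- log_group_compare(v2, rep(c("a", "b"), each = 12),
                            rep(c("x", "y"), times = 12))
  expect_true(all(res2$posthoc$p_sidak >= res2$posthoc$p_raw - 1e-12))
})

test_that("sensor clustering uses correlation distance with stable topology", {
  m <- rbind(
    s1 = c(1, 2, 3, 4, 5),
    s2 = c(1, 2, 3, 4, 5),
    s3 = c(5, 4, 3, 2, 1)
  )
  cl <- cluster_sensors(m)
  # identical rows merge first at distance 0
  expect_equal(min(cl$tree$height), 0, tolerance = 1e-12)
  d <- as.matrix(cl$distance)
  expect_equal(d["s1", "s2"], 0, tolerance = 1e-12)
  expect_equal(d["s1", "s3"], 2, tolerance = 1e-12)

  # correlated pair merges before the anti-correlated row joins
  merged_first <- sort(cl$tree$merge[1, ])
  expect_identical(merged_first, c(-2L, -1L))

  # permuting rows changes labels, not topology
  cl2 <- cluster_sensors(m[c(3, 1, 2), ])
  expect_equal(sort(cl$tree$height), sort(cl2$tree$height), tolerance = 1e-12)

  # constant rows are flagged and placed at maximal distance
  m2 <- rbind(m, s4 = c(2, 2, 2, 2, 2))
  cl3 <- cluster_sensors(m2)
  expect_true(any(grepl("constant", cl3$flags)))
  expect_equal(as.matrix(cl3$distance)["s4", "s1"], 1, tolerance = 1e-12)

  # newick export keeps every sensor as a leaf
  nw <- as_newick(cl)
  expect_true(all(vapply(rownames(m), grepl, logical(1), x = nw,
                         fixed = TRUE)))

  expect_error(cluster_sensors(m[1, , drop = FALSE]), "at least 2")
})

test_that("frequency tables pivot into cluster-ready matrices", {
  calls <- data.frame(
    cell_id = rep(sprintf("c%d", 1:4), times = 2),
    condition = rep(c("LAT", "Grb2"), each = 4),
    time_s = 0,
    label = c("central", "central", "none", "peripheral",
              "none", "none", "central", "none")
  )
  freq <- tabulate_frequencies(calls)
  m <- frequency_matrix(freq)
  expect_identical(rownames(m), c("LAT", "Grb2"))
  expect_equal(m["LAT", "central.0"], 0.5)
  expect_equal(m["Grb2", "central.0"], 0.25)
})
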