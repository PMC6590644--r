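test_that("FE summary effect is the inverse-variance weighted mean", {
  expect_equal(fe_summary(0.5, 0.1), 0.5)
  expect_equal(fe_summary(c(0, 1), c(0.04, 0.04)), 0.5)
  expect_equal(fe_summary(c(0.2, 0.5, 0.8), rep(0.04, 3)), 0.5)
  # unequal weights against a direct weighted-mean oracle
  set.seed(4)
  d <- rnorm(9); vi <- runif(9, 0.01, 0.3)
  expect_equal(fe_summary(d, vi), sum(d / vi) / sum(1 / vi))
  expect_error(fe_summary(numeric(0), numeric(0)), "empty")
  expect_error(fe_summary(c(0, 1), c(0.04, -0.01)), "positive")
})

test_that("within-subgroup Q-statistic matches hand values and is zero iff constant", {
  expect_equal(within_q_fe(0.5, 0.1), 0)
  expect_equal(within_q_fe(c(0, 1), c(0.04, 0.04)), 12.5)
  expect_equal(within_q_fe(c(0.2, 0.5, 0.8), rep(0.04, 3)), 4.5)
  expect_equal(within_q_fe(rep(0.3, 5), runif(5, 0.01, 0.1)), 0)
  expect_gt(within_q_fe(c(0.3, 0.300001), c(0.01, 0.01)), 0)
})

test_that("FE partition fit decomposes Q_T into within and between parts", {
  es <- toy4()
  fit <- fe_partition_fit(es, c(1, 1, 2, 2))
  expect_equal(fit$Q_B, 6.25)
  expect_equal(sum(fit$Q_j), 0.25)
  expect_equal(fit$Q_T, 6.5)
  expect_equal(fit$tau2, 0)
  expect_equal(fit$est, c(0.15, 0.65))
  # one subgroup: Q_B = 0, Q_T = Q_1
  f1 <- fe_partition_fit(es, rep(1, 4))
  expect_equal(f1$Q_B, 0)
  expect_equal(f1$Q_T, f1$Q_j)
  # constant effects: everything 0
  esc <- effect_size_set(rep(0.4, 6), rep(0.05, 6))
  fc <- fe_partition_fit(esc, rep(1:2, 3))
  expect_equal(fc$Q_B, 0)
  expect_equal(fc$Q_T, 0)
  expect_error(fe_partition_fit(es, c(1, 1, 1, 3)), NA) # relabeled, fine
})

test_that("Q_T = sum(Q_j) + Q_B on random partitions (additivity)", {
  set.seed(11)
  for (i in 1:20) {
    K <- sample(5:40, 1)
    es <- effect_size_set(rnorm(K), runif(K, 0.01, 0.5))
    J <- sample(1:4, 1)
    part <- sample(seq_len(J), K, replace = TRUE)
    part[seq_len(J)] <- seq_len(J) # no empty subgroup
    fit <- fe_partition_fit(es, part)
    expect_equal(fit$Q_T, sum(fit$Q_j) + fit$Q_B, tolerance = 1e-8)
    rfit <- re_partition_fit(es, part)
    expect_equal(rfit$Q_T, sum(rfit$Q_j) + rfit$Q_B, tolerance = 1e-8)
  }
})

test_that("pooled DerSimonian-Laird heterogeneity matches hand values and truncates", {
  es2 <- effect_size_set(c(0, 1), c(0.04, 0.04))
  expect_equal(pooled_dl_tau2(es2), 0.46)
  # within-subgroup heterogeneity at/below expectation -> 0
  esh <- effect_size_set(c(0.1, 0.12), c(0.04, 0.04))
  expect_equal(pooled_dl_tau2(esh), 0)
  # identical effects within each subgroup -> 0
  esi <- effect_size_set(c(0.2, 0.2, 0.9, 0.9), rep(0.03, 4))
  expect_equal(pooled_dl_tau2(esi, c(1, 1, 2, 2)), 0)
  # all-singleton partition: zero with a warning, not an error
  expect_warning(t2 <- pooled_dl_tau2(es2, c(1, 2)), "singleton")
  expect_equal(t2, 0)
  # never negative, whatever the data
  set.seed(3)
  for (i in 1:10) {
    es <- effect_size_set(rnorm(15, 0, 0.1), runif(15, 0.05, 0.5))
    expect_gte(pooled_dl_tau2(es, sample(1:3, 15, replace = TRUE)), 0)
  }
})

test_that("RE partition fit reproduces hand values and degenerates to FE at tau2 = 0", {
  es2 <- effect_size_set(c(0, 1), c(0.04, 0.04))
  fit <- re_partition_fit(es2, c(1, 1))
  expect_equal(fit$tau2, 0.46)
  expect_equal(fit$wsum, 4) # two studies with w* = 1/(0.04+0.46) = 2
  expect_equal(fit$est, 0.5)
  expect_equal(fit$Q_j, 1.0)
  # DL estimate exactly 0 -> every RE quantity equals its FE counterpart
  esi <- effect_size_set(c(0.2, 0.2, 0.9, 0.9), rep(0.03, 4))
  fe <- fe_partition_fit(esi, c(1, 1, 2, 2))
  re <- re_partition_fit(esi, c(1, 1, 2, 2))
  expect_identical(re$tau2, 0)
  for (f in c("est", "grand", "Q_j", "Q_B", "Q_T", "wsum", "pvalue"))
    expect_identical(re[[f]], fe[[f]])
})

test_that("kernels agree with metafor on random data (independent oracle)", {
  set.seed(21)
  for (i in 1:5) {
    K <- 30
    d <- rnorm(K, 0.3, 0.4); vi <- runif(K, 0.02, 0.2)
    es <- effect_size_set(d, vi)
    g <- sample(1:3, K, replace = TRUE); g[1:3] <- 1:3
    m0 <- metafor::rma(yi = d, vi = vi, method = "FE")
    expect_equal(fe_summary(d, vi), as.numeric(m0$beta), tolerance = 1e-8)
    expect_equal(within_q_fe(d, vi), m0$QE, tolerance = 1e-8)
    mf <- metafor::rma(yi = d, vi = vi, mods = ~ factor(g), method = "FE")
    fit <- fe_partition_fit(es, g)
    expect_equal(fit$Q_B, mf$QM, tolerance = 1e-6)
    expect_equal(sum(fit$Q_j), mf$QE, tolerance = 1e-6)
    mdl <- metafor::rma(yi = d, vi = vi, mods = ~ factor(g), method = "DL")
    expect_equal(pooled_dl_tau2(es, g), mdl$tau2, tolerance = 1e-8)
    rfit <- re_partition_fit(es, g)
    expect_equal(rfit$Q_B, mdl$QM, tolerance = 1e-6)
  }
})

test_that("the between-subgroups Q test is an upper-tail chi-squared test", {
  expect_equal(qb_test(0, 2), 1)
  expect_equal(qb_test(6.25, 2), 0.01241933, tolerance = 1e-6)
  expect_lt(qb_test(40.59, 3), 0.001)
  expect_error(qb_test(5, 1), "two subgroups")
  expect_error(qb_test(-1, 2), "non-negative")
})

test_that("subgroup confidence intervals are Wald intervals on the weighted mean", {
  es2 <- effect_size_set(c(0, 1), c(0.04, 0.04))
  fit <- fe_partition_fit(es2, c(1, 1))
  ci <- subgroup_ci(fit, 0.95)
  expect_equal(unname(ci[1, "lower"]), 0.5 - qnorm(0.975) * sqrt(1 / 50))
  expect_equal(unname(ci[1, "upper"]), 0.5 + qnorm(0.975) * sqrt(1 / 50))
  # RE interval is at least as wide as FE for the same partition
  set.seed(9)
  es <- effect_size_set(rnorm(20, 0, 0.8), runif(20, 0.02, 0.1))
  g <- rep(1:2, 10)
  wfe <- diff(t(subgroup_ci(fe_partition_fit(es, g))))
  wre <- diff(t(subgroup_ci(re_partition_fit(es, g))))
  expect_true(all(wre >= wfe - 1e-12))
  expect_error(subgroup_ci(fit, 1.2), "level")
})

test_that("Q_T is calibrated against its chi-squared null", {
  # d_k ~ N(delta, v_k) with known variances: Q_T ~ chi2_{K-1}
  set.seed(31)
  K <- 25; reps <- 3000
  rej <- 0
  for (i in seq_len(reps)) {
    vi <- runif(K, 0.02, 0.2)
    d <- rnorm(K, 0.4, sqrt(vi))
    q <- within_q_fe(d, vi)
    rej <- rej + (pchisq(q, K - 1, lower.tail = FALSE) < 0.05)
  }
  expect_proportion_close(rej / reps, 0.05, reps, "null Q_T rejection rate")
})
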