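test_that("moderator generation matches the declared marginal structure", {
  des <- sim_design(K = 4000, M = 4, type = "binary", model = "A",
                    deltaI = 0)
  X <- gen_moderators(des, seed = 1)
  # mean split of a symmetric normal: both levels near frequency 1/2
  expect_lt(max(abs(colMeans(X == 1) - 0.5)), 0.03)
  deso <- sim_design(K = 6000, M = 3, type = "ordinal", model = "A",
                     deltaI = 0)
  Xo <- gen_moderators(deso, seed = 2)
  expect_lt(max(abs(prop.table(table(Xo$x1)) - 1 / 3)), 0.03)
  desn <- sim_design(K = 6000, M = 3, type = "nominal", model = "A",
                     deltaI = 0)
  Xn <- gen_moderators(desn, seed = 3)
  expect_s3_class(Xn$x1, "factor")
  expect_setequal(levels(Xn$x1), c("A", "B", "C"))
})

test_that("continuous moderators have the expected distinct-value richness", {
  # rounding N(20, 10) to one decimal: average unique count near 71 at K = 80
  des <- sim_design(K = 80, M = 1, type = "continuous", model = "A",
                    deltaI = 0)
  set.seed(4)
  u <- replicate(60, length(unique(gen_moderators(des)$x1)))
  expect_gt(mean(u), 66)
  expect_lt(mean(u), 76)
})

test_that("random correlation matrices are proper and polytomization attenuates r", {
  set.seed(5)
  for (M in c(5, 20)) {
    R <- random_cor_matrix(M)
    expect_equal(diag(R), rep(1, M))
    expect_equal(R, t(R))
    expect_true(all(eigen(R, only.values = TRUE)$values > 0))
    expect_lt(max(abs(R[upper.tri(R)])), 0.5 + 1e-12)
  }
  # identical latent draws, different coding: the cut versions correlate less
  des_c <- sim_design(K = 4000, M = 5, type = "continuous",
                      correlated = TRUE, model = "A", deltaI = 0)
  des_o <- sim_design(K = 4000, M = 5, type = "ordinal",
                      correlated = TRUE, model = "A", deltaI = 0)
  rc <- cor(sapply(gen_moderators(des_c, seed = 6), as.numeric))
  ro <- cor(sapply(gen_moderators(des_o, seed = 6), as.numeric))
  expect_lt(mean(abs(ro[upper.tri(ro)])), mean(abs(rc[upper.tri(rc)])))
})

test_that("study sizes follow the declared normal with clamping to even sizes", {
  n <- sample_study_sizes(20000, 40, seed = 7)
  expect_true(all(n >= 10))
  expect_true(all(n %% 2 == 0))
  expect_lt(abs(mean(n) - 40), 1)
  expect_lt(abs(sd(n) - 40 / 3), 1)
  expect_identical(sample_study_sizes(50, 80, seed = 8),
                   sample_study_sizes(50, 80, seed = 8))
  # across the design levels, realized sizes stay in a plausible range
  nall <- c(sample_study_sizes(2000, 40, seed = 9),
            sample_study_sizes(2000, 160, seed = 10))
  expect_gte(min(nall), 10)
  expect_lt(max(nall), 450)
})

test_that("observed effects are unbiased with the expected variance decomposition", {
  n <- rep(80L, 40000)
  # null: mean 0, variance close to 4/n
  e0 <- sample_effects(rep(0, length(n)), 0, n, seed = 11)
  expect_lt(abs(mean(e0$d)), 0.005)
  expect_lt(abs(var(e0$d) - 4 / 80) / (4 / 80), 0.05)
  # shifted: small-sample corrected SMD is nearly unbiased
  e5 <- sample_effects(rep(0.5, length(n)), 0, n, seed = 12)
  expect_lt(abs(mean(e5$d) - 0.5), 0.01)
  # residual heterogeneity adds to the sampling variance
  eh <- sample_effects(rep(0.5, length(n)), 0.05, n, seed = 13)
  expected <- 4 / 80 + 0.05 + 0.5^2 / (2 * 80)
  expect_lt(abs(var(eh$d) - expected) / expected, 0.08)
  expect_true(all(e0$vi > 0))
})

test_that("true-model predicates mark the designed effective subgroups", {
  X <- data.frame(x1 = c(0, 1, 1, 0), x2 = c(1, 0, 1, 1),
                  x3 = c(0, 1, 0, 1))
  tm <- true_model("C", "binary")
  expect_equal(true_subgroup_means(tm, X, 0.5), c(0, 0, 0.5, 0))
  tmA <- true_model("A", "binary")
  expect_equal(true_subgroup_means(tmA, X, 0.5), rep(0, 4))
  tmD <- true_model("D", "binary")
  # effective: (x1 & x2) or (!x1 & x3)
  expect_equal(true_subgroup_means(tmD, X, 0.4), c(0, 0, 0.4, 0.4))
  # three-way interaction: about 1/8 of studies effective for binaries
  desE <- sim_design(K = 8000, M = 3, type = "binary", model = "E",
                     deltaI = 0.5)
  XE <- gen_moderators(desE, seed = 14)
  frac <- mean(true_subgroup_means(true_model("E", "binary"), XE, 1) > 0)
  expect_lt(abs(frac - 1 / 8), 0.02)
  expect_error(true_subgroup_means(tmD, X[, 1:2], 0.4), "true moderator")
})

test_that("data generation is reproducible and calibrated under the null", {
  des <- sim_design(K = 40, nbar = 80, tau2 = 0, deltaI = 0, M = 5,
                    type = "binary", model = "A")
  s1 <- gen_dataset(des, seed = 15)
  s2 <- gen_dataset(des, seed = 15)
  expect_identical(s1$data$d, s2$data$d)
  expect_identical(s1$data$X, s2$data$X)
  expect_true(all(s1$Delta == 0))
  # FE meta-analysis of null data rejects homogeneity at about alpha
  rej <- 0; reps <- 400
  for (i in seq_len(reps)) {
    sim <- gen_dataset(des, seed = 10000 + i)
    q <- within_q_fe(sim$data$d, sim$data$vi)
    rej <- rej + (pchisq(q, 39, lower.tail = FALSE) < 0.05)
  }
  expect_proportion_close(rej / reps, 0.05, reps,
                          "null Q_T rejection through the SMD generator")
  # effective-subgroup mean approaches deltaI without heterogeneity
  desb <- sim_design(K = 2000, nbar = 160, tau2 = 0, deltaI = 0.5, M = 2,
                     type = "binary", model = "B")
  simb <- gen_dataset(desb, seed = 16)
  eff <- simb$Delta > 0
  expect_lt(abs(mean(simb$data$d[eff]) - 0.5), 0.03)
  expect_lt(abs(fe_summary(simb$data$d[!eff], simb$data$vi[!eff])), 0.03)
})
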