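test_that("success criteria score detection and exact moderator recovery", {
  # strong main effect: detected and recovered
  sim <- gen_dataset(sim_design(model = "B", K = 80, nbar = 160, tau2 = 0,
                                deltaI = 0.8, M = 5, type = "binary"),
                     seed = 2)
  fit <- metatree(sim$data, model = "FE", seed = 3)
  cr <- evaluate_criteria(fit, sim$truth)
  expect_equal(unname(cr), c(1L, 1L))
  # same tree judged against a two-moderator truth: spurious/missing -> 0
  truthC <- true_model("C", "binary")
  expect_equal(evaluate_criteria(fit, truthC)[["recover"]], 0L)
  # trivial tree: neither detected nor recovered (for a nontrivial truth)
  simA <- gen_dataset(sim_design(model = "A", K = 40, nbar = 40, tau2 = 0,
                                 deltaI = 0, M = 5, type = "binary"),
                      seed = 3)
  fitA <- metatree(simA$data, model = "FE", c = 5, seed = 4)
  expect_true(fitA$trivial)
  expect_equal(unname(evaluate_criteria(fitA, sim$truth)), c(0L, 0L))
  # recovery of a nonempty moderator set implies a nontrivial tree
  expect_true(cr[["recover"]] <= as.integer(nrow(fit$tree$splits) > 0))
})

test_that("meta-regression with the true structure specified has near-complete power", {
  hits <- 0
  for (i in 1:25) {
    sim <- gen_dataset(sim_design(model = "B", K = 120, nbar = 80, tau2 = 0,
                                  deltaI = 0.8, M = 5, type = "binary"),
                       seed = 100 + i)
    hits <- hits + metareg_recovery(sim$data, sim$truth, "FE")
  }
  expect_gte(hits / 25, 0.95)
  # null calibration: with deltaI = 0 the true term is significant at ~alpha
  null_hits <- 0
  for (i in 1:40) {
    sim <- gen_dataset(sim_design(model = "B", K = 80, nbar = 80, tau2 = 0,
                                  deltaI = 0, M = 5, type = "binary"),
                       seed = 200 + i)
    null_hits <- null_hits + metareg_recovery(sim$data, sim$truth, "FE")
  }
  expect_lte(null_hits / 40, 0.2)
  simA <- gen_dataset(sim_design(model = "A", K = 40, deltaI = 0, M = 5,
                                 type = "binary"), seed = 5)
  expect_error(metareg_recovery(simA$data, simA$truth), "models B")
})

test_that("design-cell runs aggregate reproducibly with binomial uncertainty", {
  des <- sim_design(model = "B", K = 40, nbar = 160, tau2 = 0, deltaI = 0.8,
                    M = 5, type = "binary")
  out1 <- run_cell(des, reps = 8, model = "FE", c = c(0.5, 1), seed = 42)
  out2 <- run_cell(des, reps = 8, model = "FE", c = c(0.5, 1), seed = 42)
  expect_identical(out1$rates, out2$rates)
  expect_equal(nrow(out1$rates), 2)
  expect_true(all(out1$rates$detect >= 0 & out1$rates$detect <= 1))
  expect_equal(out1$rates$detect_se,
               sqrt(out1$rates$detect * (1 - out1$rates$detect) / 8))
  one <- run_cell(des, reps = 1, model = "FE", seed = 7)
  expect_true(all(one$rates$detect %in% c(0, 1)))
})

test_that("canonical interaction trees are identified and scored for coverage", {
  # a strong interaction data set whose pruned tree is exactly canonical
  des <- sim_design(model = "C", K = 80, nbar = 80, tau2 = 0, deltaI = 0.8,
                    M = 5, type = "binary")
  sim <- gen_dataset(des, seed = 3)
  sel <- metatree_select(metatree_curve(sim$data, "FE", seed = 3), c = 0.5)
  truth <- true_model("C", "binary")
  m <- metatree:::canonical_c_subgroups(sel, truth)
  expect_false(is.null(m))
  expect_length(m$order, 3)
  # ordering: subgroup 3 is the effective one (largest estimate)
  expect_equal(which.max(sel$fit$est[m$order]), 3L)
  expect_gt(sel$fit$est[m$order][3], 0.5)
  # a trivial tree never matches
  simA <- gen_dataset(sim_design(model = "C", K = 40, deltaI = 0, M = 5,
                                 type = "binary"), seed = 8)
  fitA <- metatree(simA$data, model = "FE", c = 10, seed = 9)
  expect_null(metatree:::canonical_c_subgroups(fitA, truth))
})

test_that("table reproduction is driven by configuration", {
  expect_equal(reproduce_tables(list()), list())
  cfg <- list(type1 = list(list(model = "FE", K = 40, c_values = 1,
                                n_cells = 2, reps = 4, seed = 1)))
  out <- reproduce_tables(cfg)
  expect_named(out, "type1")
  expect_equal(out$type1$K, 40)
  expect_true(out$type1$type1 >= 0 && out$type1$type1 <= 1)
})
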