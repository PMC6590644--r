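test_that("nested families are nested and anchored at the root", {
  # root-only tree
  es3 <- effect_size_set(rnorm(3), rep(0.1, 3), data.frame(x = 1:3))
  fam0 <- nested_sequence(grow_fe(es3))
  expect_equal(fam0$sizes, 1L)
  # FE: weakest-link family, nested, sizes strictly increasing from 1
  es <- random_es(30, 3, seed = 14)
  tree <- grow_fe(es)
  fam <- nested_sequence(tree)
  expect_equal(fam$sizes[1], 1L)
  expect_true(all(diff(fam$sizes) > 0))
  for (i in seq_along(fam$splits)[-1])
    expect_true(all(fam$splits[[i - 1]] %in% fam$splits[[i]]))
  expect_true(all(diff(fam$alpha) <= 0)) # cp decreases as size grows
})

test_that("weakest-link pruning removes a zero-gain split before a strong one", {
  # two clean halves; the second split within a constant half gains nothing
  es <- effect_size_set(
    d = c(rep(0.1, 4), rep(0.9, 4)), vi = rep(0.04, 8),
    X = data.frame(x1 = rep(0:1, each = 4), x2 = rep(0:1, 4)),
    types = c("binary", "binary"))
  tree <- grow_fe(es)
  fam <- nested_sequence(tree)
  two <- fam$splits[[which(fam$sizes == 2)]]
  expect_equal(tree$splits$var[two], 1) # only the strong x1 split survives
})

test_that("the c*SE rule selects the smallest size within the band", {
  curve <- structure(list(sizes = 1:3, error = c(10, 4, 4.5),
                          se = c(1, 1, 1)), class = "cv_curve")
  expect_equal(select_c_se(curve, 1), 2)
  expect_equal(select_c_se(curve, 0), 2)
  mono <- structure(list(sizes = 1:4, error = c(1, 2, 3, 4),
                         se = rep(0.5, 4)), class = "cv_curve")
  expect_equal(select_c_se(mono, 0), 1)
  expect_equal(select_c_se(mono, 3), 1)
  expect_error(select_c_se(curve, -1), "non-negative")
  # monotone: chosen size is non-increasing in c, and c -> Inf gives 1
  set.seed(2)
  for (i in 1:20) {
    cv <- structure(list(sizes = 1:6, error = runif(6, 1, 3),
                         se = runif(6, 0.1, 0.5)), class = "cv_curve")
    sizes <- vapply(c(0, 0.25, 0.5, 1, 2, 100), select_c_se, 0, curve = cv)
    expect_true(all(diff(sizes) <= 0))
    expect_equal(sizes[6], 1)
  }
})

test_that("cross-validation curves are reproducible and sized consistently", {
  es <- random_es(40, 3, seed = 20)
  cv1 <- cv_curve(es, "FE", seed = 7)
  cv2 <- cv_curve(es, "FE", seed = 7)
  expect_identical(cv1$error, cv2$error)
  expect_identical(cv1$fold_assign, cv2$fold_assign)
  expect_length(cv1$se, length(cv1$sizes))
  expect_true(all(cv1$error >= 0))
})

test_that("pure-noise data selects the root; a strong split survives cross-validation", {
  # no moderator effect: the error-minimizing size is 1 in most runs
  set.seed(40)
  argmin1 <- 0
  for (i in 1:30) {
    sim <- gen_dataset(sim_design(model = "A", K = 40, nbar = 80, tau2 = 0,
                                  deltaI = 0, M = 5, type = "binary"),
                       seed = 400 + i)
    cv <- metatree_curve(sim$data, "FE", seed = i)
    argmin1 <- argmin1 + (select_c_se(cv$cv, 0) == 1)
  }
  expect_gt(argmin1 / 30, 0.5)
  # strong single moderator: size-2 CV error beats size 1 almost always
  better <- 0
  for (i in 1:30) {
    sim <- gen_dataset(sim_design(model = "B", K = 80, nbar = 80, tau2 = 0,
                                  deltaI = 0.8, M = 5, type = "binary"),
                       seed = 800 + i)
    cv <- metatree_curve(sim$data, "FE", seed = i)$cv
    i2 <- match(2, cv$sizes)
    better <- better + (!is.na(i2) && cv$error[i2] < cv$error[1])
  }
  expect_gte(better / 30, 0.95)
})

test_that("metatree returns a tested subgrouping or a trivial tree", {
  sim <- gen_dataset(sim_design(model = "B", K = 60, nbar = 80, tau2 = 0,
                                deltaI = 0.8, M = 5, type = "binary"),
                     seed = 2)
  fit <- metatree(sim$data, model = "FE", seed = 3)
  expect_s3_class(fit, "metatree")
  expect_false(fit$trivial)
  expect_lt(fit$fit$pvalue, 0.05)
  expect_equal(sort(unique(fit$tree$term)),
               as.integer(names(coef(fit)) |> sub("node", "", x = _)) |>
                 sort())
  # the pruned tree is a member of the master's nested family
  curve <- metatree_curve(sim$data, "FE", seed = 3)
  sel <- metatree_select(curve, c = fit$c)
  expect_equal(sel$size, fit$size)
  expect_true(fit$size %in% curve$family$sizes)
  # c = Inf prunes to the root
  expect_equal(metatree_select(curve, c = 1e6)$size, 1L)
  # degenerate input: single study, no test
  es1 <- effect_size_set(0.4, 0.05, data.frame(x = 1))
  f1 <- metatree(es1, model = "FE", seed = 1)
  expect_true(f1$trivial)
  expect_true(is.na(f1$fit$pvalue))
})

test_that("model methods (predict, residuals, simulate, coef) are consistent", {
  sim <- gen_dataset(sim_design(model = "B", K = 60, nbar = 80, tau2 = 0,
                                deltaI = 0.8, M = 5, type = "binary"),
                     seed = 4)
  fit <- metatree(sim$data, model = "RE", seed = 5)
  pr <- predict(fit)
  expect_length(pr, 60)
  expect_equal(unname(residuals(fit)), sim$data$d - pr)
  expect_setequal(unique(pr), unname(coef(fit)))
  nodes <- predict(fit, type = "node")
  expect_setequal(unique(nodes), sort(unique(fit$tree$term)))
  # prediction on new data follows the same rules
  pr2 <- predict(fit, newdata = sim$data$X[1:5, , drop = FALSE])
  expect_equal(pr2, pr[1:5])
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(60L, 3L))
})
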