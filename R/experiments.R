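# Monte-Carlo harness: per-dataset success criteria, the meta-regression
# comparator, design-cell runs, and scaled reproductions of the Type I
# error / recovery / coverage summary tables.

#' Evaluate the success criteria of one fitted tree against the truth
#'
#' * `detect`: the pruned tree has at least one split and the
#'   between-subgroups Q-test is significant at `alpha`.  On data from the
#'   no-moderator model this is a Type I error; on data with true
#'   moderator effects it is power.
#' * `recover`: the set of distinct moderators used by the pruned tree
#'   equals the true moderator set exactly (no spurious moderators, none
#'   missing).  By default significance is not additionally required;
#'   set `recovery_requires_sig = TRUE` to require it.
#'
#' @param fit a `"metatree"`.
#' @param truth a [true_model()].
#' @param alpha significance level (default 0.05).
#' @param recovery_requires_sig see above.
#' @return Named integer vector `c(detect = 0/1, recover = 0/1)`.
#' @export
evaluate_criteria <- function(fit, truth, alpha = 0.05,
                              recovery_requires_sig = FALSE) {
  stopifnot(inherits(fit, "metatree"), inherits(truth, "true_model"))
  sig <- !fit$trivial && !is.na(fit$fit$pvalue) && fit$fit$pvalue < alpha
  used <- sort(unique(fit$tree$splits$var))
  rec <- setequal(used, truth$vars)
  if (recovery_requires_sig) rec <- rec && sig
  c(detect = as.integer(sig), recover = as.integer(rec))
}

#' Moderator recovery by meta-regression with the true structure specified
#'
#' Fits a weighted meta-regression (via [metafor::rma()]) with one
#' indicator regressor per effective-subgroup predicate term of the true
#' model: model B, the x1 indicator; C, the product indicator x1:x2; D,
#' the two products x1:x2 and (1-x1):x3; E, the triple product.  Under
#' the FE assumption weights are `1/vi` (`method = "FE"`), under RE the
#' DerSimonian-Laird residual heterogeneity is estimated first
#' (`method = "DL"`).  Recovery means every true term is significant at
#' 0.05.  This is the idealized comparator: the structure the tree must
#' discover is handed to the regression.
#'
#' @param data an [effect_size_set()].
#' @param truth a [true_model()] for models B..E.
#' @param assumption `"FE"` or `"RE"`.
#' @return 1 if all true terms have p < 0.05, else 0 (0 with a warning if
#'   the design is singular or the fit fails).
#' @export
metareg_recovery <- function(data, truth, assumption = c("FE", "RE")) {
  assumption <- match.arg(assumption)
  stopifnot(inherits(truth, "true_model"))
  if (truth$model == "A")
    stop("meta-regression recovery is defined for models B..E only")
  e <- lapply(truth$vars, function(j)
    as.numeric(effective_level(data$X[[j]], truth$type)))
  Z <- switch(truth$model,
              B = cbind(z1 = e[[1L]]),
              C = cbind(z1 = e[[1L]] * e[[2L]]),
              D = cbind(z1 = e[[1L]] * e[[2L]],
                        z2 = (1 - e[[1L]]) * e[[3L]]),
              E = cbind(z1 = e[[1L]] * e[[2L]] * e[[3L]]))
  fit <- tryCatch(
    metafor::rma(yi = data$d, vi = data$vi, mods = Z,
                 method = if (assumption == "FE") "FE" else "DL"),
    error = function(err) {
      warning("meta-regression failed: ", conditionMessage(err))
      NULL
    })
  if (is.null(fit)) return(0L)
  pv <- fit$pval[-1L] # drop intercept
  if (length(pv) != ncol(Z) || anyNA(pv)) return(0L)
  as.integer(all(pv < 0.05))
}

# Does a fitted tree have exactly the canonical two-way interaction shape:
# root split on x1 separating its effective side, second split on x2
# inside the x1-effective child separating its effective side, three
# terminal nodes?  Subgroups are returned in the conventional order
# (1: x1-ineffective, 2: x1-effective & x2-ineffective, 3: effective).
canonical_c_subgroups <- function(fit, truth) {
  tree <- fit$tree
  if (nrow(tree$splits) != 2L) return(NULL)
  if (!identical(sort(tree$splits$var), c(1L, 2L))) return(NULL)
  s1 <- which(tree$splits$node == 1L)
  if (length(s1) != 1L || tree$splits$var[s1] != 1L) return(NULL)
  e1 <- effective_level(fit$es$X[[1L]], truth$type)
  e2 <- effective_level(fit$es$X[[2L]], truth$type)
  lab <- tree$term
  side1 <- lab %/% 2L^(floor(log2(lab)) - 1L) # 2 = left of root, 3 = right
  eff_child <- if (all(side1[e1] == 3L) && all(side1[!e1] == 2L)) 3L
               else if (all(side1[e1] == 2L) && all(side1[!e1] == 3L)) 2L
               else return(NULL)
  s2 <- which(tree$splits$node == eff_child)
  if (length(s2) != 1L || tree$splits$var[s2] != 2L) return(NULL)
  ch <- c(2L * eff_child, 2L * eff_child + 1L)
  g3 <- unique(lab[e1 & e2])
  g2 <- unique(lab[e1 & !e2])
  if (length(g3) != 1L || length(g2) != 1L || !all(c(g2, g3) %in% ch))
    return(NULL)
  g1 <- setdiff(c(2L, 3L), eff_child)
  list(order = match(c(g1, g2, g3), sort(unique(lab))))
}

#' Run one design cell of the Monte-Carlo study
#'
#' Streams `reps` replications of generate-data / fit-tree / score.  The
#' grown tree and its cross-validation curve are shared across the values
#' of the pruning parameter `c`, which only affects size selection.
#' Optionally also scores the meta-regression comparator and, for model C
#' cells, collects subgroup estimates and confidence-interval coverage
#' over the replications whose pruned tree has exactly the canonical
#' model-C shape.
#'
#' @param design a [sim_design()].
#' @param reps number of replications.
#' @param model `"FE"` or `"RE"` tree.
#' @param c pruning parameter(s); may be a vector.  `NULL` uses the
#'   recommended rule for the model and K.
#' @param seed integer seed; replication seeds are derived from it.
#' @param alpha significance level of the Q_B test.
#' @param metareg if `TRUE`, also compute [metareg_recovery()] with the
#'   matching model assumption.
#' @param coverage if `TRUE` (model C only), collect canonical-tree
#'   subgroup estimates and 95% CI coverage.
#' @param folds,min_node_size,max_terminal passed to the tree fitter.
#' @return A `"cell_outcome"` list: `rates` (one row per `c`: detection
#'   and recovery proportions with binomial Monte-Carlo standard errors),
#'   and optionally `metareg` and `coverage`.
#' @export
run_cell <- function(design, reps = 100L, model = c("FE", "RE"), c = NULL,
                     seed = 1L, alpha = 0.05, metareg = FALSE,
                     coverage = FALSE, folds = 10L, min_node_size = 2L,
                     max_terminal = 10L) {
  model <- match.arg(model)
  stopifnot(inherits(design, "sim_design"), reps >= 1L)
  if (is.null(c)) c <- recommended_c(model, design$K)
  set.seed(seed)
  dseeds <- sample.int(.Machine$integer.max - 1L, reps)
  cseeds <- sample.int(.Machine$integer.max - 1L, reps)
  nc <- length(c)
  det <- rec <- matrix(0L, reps, nc)
  mreg <- rep(NA_integer_, reps)
  cover <- vector("list", nc)
  failed <- 0L
  truth_proto <- true_model(design$model, design$type)
  for (i in seq_len(reps)) {
    res <- tryCatch({
      sim <- gen_dataset(design, seed = dseeds[i])
      curve <- metatree_curve(sim$data, model, folds = folds,
                              seed = cseeds[i],
                              min_node_size = min_node_size,
                              max_terminal = max_terminal)
      out <- vector("list", nc)
      for (ci in seq_len(nc)) {
        sel <- metatree_select(curve, c = c[ci], alpha = alpha)
        cr <- evaluate_criteria(sel, sim$truth, alpha)
        cov_i <- NULL
        if (coverage && design$model == "C") {
          m <- canonical_c_subgroups(sel, sim$truth)
          if (!is.null(m)) {
            truev <- c(0, 0, design$deltaI)
            est <- sel$fit$est[m$order]
            ci95 <- sel$fit$ci[m$order, , drop = FALSE]
            cov_i <- cbind(est = est,
                           covered = as.integer(ci95[, 1] <= truev &
                                                truev <= ci95[, 2]))
          }
        }
        out[[ci]] <- list(cr = cr, cov = cov_i)
      }
      mr <- if (metareg) metareg_recovery(sim$data, sim$truth, model)
            else NA_integer_
      list(out = out, mr = mr)
    }, error = function(err) NULL)
    if (is.null(res)) { failed <- failed + 1L; next }
    for (ci in seq_len(nc)) {
      det[i, ci] <- res$out[[ci]]$cr[["detect"]]
      rec[i, ci] <- res$out[[ci]]$cr[["recover"]]
      if (!is.null(res$out[[ci]]$cov))
        cover[[ci]] <- c(cover[[ci]], list(res$out[[ci]]$cov))
    }
    mreg[i] <- res$mr
  }
  n_ok <- reps - failed
  p_se <- function(p) sqrt(p * (1 - p) / n_ok)
  rates <- data.frame(
    c = c, reps = n_ok,
    detect = colSums(det) / n_ok, recover = colSums(rec) / n_ok)
  rates$detect_se <- p_se(rates$detect)
  rates$recover_se <- p_se(rates$recover)
  out <- list(design = design, model = model, rates = rates,
              failed = failed, seed = seed)
  if (metareg) {
    p <- mean(mreg, na.rm = TRUE)
    out$metareg <- data.frame(recover = p, se = p_se(p))
  }
  if (coverage) {
    out$coverage <- lapply(cover, function(reps_list) {
      if (length(reps_list) == 0L) return(NULL)
      est <- t(vapply(reps_list, function(z) z[, "est"], numeric(3)))
      cov <- t(vapply(reps_list, function(z) z[, "covered"], numeric(3)))
      data.frame(subgroup = 1:3, true = c(0, 0, design$deltaI),
                 mean_est = colMeans(est), sd_est = apply(est, 2, sd),
                 coverage = colMeans(cov), n_matched = nrow(est))
    })
  }
  class(out) <- "cell_outcome"
  out
}

#' @export
print.cell_outcome <- function(x, ...) {
  cat(sprintf("Design cell: model %s, K=%d, nbar=%g, tau2=%g, deltaI=%g, M=%d, %s%s\n",
              x$design$model, x$design$K, x$design$nbar, x$design$tau2,
              x$design$deltaI, x$design$M, x$design$type,
              if (x$design$correlated) " (correlated)" else ""))
  cat(sprintf("%s meta-analytic tree, %d replications", x$model,
              x$rates$reps[1]))
  if (x$failed > 0) cat(sprintf(" (%d failed)", x$failed))
  cat("\n")
  print(x$rates, row.names = FALSE, digits = 3)
  invisible(x)
}

# Balanced stratified sample of design cells: each factor level appears
# equally often (up to rounding), pairings randomized by the seed.
sample_cells <- function(factors, n_cells, seed) {
  set.seed(seed)
  cols <- lapply(factors, function(lv) sample(rep_len(lv, n_cells)))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

type1_factors <- list(
  type = c("binary", "nominal", "ordinal", "continuous"),
  correlated = c(FALSE, TRUE),
  M = c(5L, 10L, 20L),
  nbar = c(40, 80, 160),
  tau2 = c(0, 0.025, 0.05))

#' Scaled Type I error study (no-moderator model)
#'
#' Runs model-A cells (all true effects zero) for one number of studies K,
#' over a balanced stratified sample of the remaining design factors
#' (moderator type, correlation structure, number of moderators, average
#' study size, residual heterogeneity), and averages the per-cell
#' rejection proportions.  The grown trees are shared across the pruning
#' parameters in `c_values`.
#'
#' @param model `"FE"` or `"RE"`.
#' @param K number of studies.
#' @param c_values pruning parameters to evaluate.
#' @param n_cells number of sampled design cells.
#' @param reps replications per cell.
#' @param seed integer seed.
#' @return A data.frame: one row per pruning parameter with the mean Type
#'   I error across cells, its Monte-Carlo standard error, and the
#'   between-cell standard deviation.
#' @export
mc_type1_error <- function(model = "FE", K = 40L, c_values = c(0.5, 1),
                           n_cells = 24L, reps = 100L, seed = 1L) {
  cells <- sample_cells(type1_factors, n_cells, seed)
  set.seed(seed + 1L)
  cellseeds <- sample.int(.Machine$integer.max - 1L, n_cells)
  props <- matrix(NA_real_, n_cells, length(c_values))
  for (i in seq_len(n_cells)) {
    des <- sim_design(K = K, nbar = cells$nbar[i], tau2 = cells$tau2[i],
                      deltaI = 0, M = cells$M[i], type = cells$type[i],
                      correlated = cells$correlated[i], model = "A")
    out <- run_cell(des, reps = reps, model = model, c = c_values,
                    seed = cellseeds[i])
    props[i, ] <- out$rates$detect
  }
  data.frame(model = model, K = K, c = c_values,
             type1 = colMeans(props),
             mc_se = sqrt(colMeans(props * (1 - props) / reps) / n_cells),
             cell_sd = apply(props, 2, sd),
             n_cells = n_cells, reps = reps)
}

recovery_factors <- c(type1_factors,
                      list(K = c(40L, 80L, 120L),
                           deltaI = c(0.3, 0.4, 0.5, 0.8)))

#' Scaled moderator-recovery study with meta-regression comparator
#'
#' Runs cells of a true model (default B) over a balanced stratified
#' sample of the full design (including K and the effect size), fits the
#' tree with the recommended pruning rule, and optionally the
#' meta-regression comparator with the true structure specified.  Returns
#' averages of the per-cell recovery proportions.
#'
#' @param model tree model assumption, `"FE"` or `"RE"`.
#' @param tree_model the true structure, `"B"`..`"E"`.
#' @param n_cells,reps,seed as in [mc_type1_error()].
#' @param metareg also run the comparator (default `TRUE`).
#' @return A one-row data.frame with mean recovery of the tree (and of
#'   the meta-regression if requested), Monte-Carlo standard errors and
#'   between-cell standard deviations.
#' @export
mc_recovery <- function(model = "FE", tree_model = "B", n_cells = 24L,
                        reps = 100L, seed = 1L, metareg = TRUE) {
  cells <- sample_cells(recovery_factors, n_cells, seed)
  set.seed(seed + 1L)
  cellseeds <- sample.int(.Machine$integer.max - 1L, n_cells)
  rec <- mrec <- rep(NA_real_, n_cells)
  for (i in seq_len(n_cells)) {
    des <- sim_design(K = cells$K[i], nbar = cells$nbar[i],
                      tau2 = cells$tau2[i], deltaI = cells$deltaI[i],
                      M = cells$M[i], type = cells$type[i],
                      correlated = cells$correlated[i], model = tree_model)
    out <- run_cell(des, reps = reps, model = model, c = NULL,
                    seed = cellseeds[i], metareg = metareg)
    rec[i] <- out$rates$recover
    if (metareg) mrec[i] <- out$metareg$recover
  }
  res <- data.frame(model = model, tree = tree_model,
                    tree_recovery = mean(rec),
                    tree_mc_se = sd(rec) / sqrt(n_cells),
                    tree_cell_sd = sd(rec),
                    n_cells = n_cells, reps = reps)
  if (metareg) {
    res$metareg_recovery <- mean(mrec)
    res$metareg_mc_se <- sd(mrec) / sqrt(n_cells)
  }
  res
}

#' Subgroup-estimate and coverage study for the canonical interaction cell
#'
#' The single mid-level design cell used for confidence-interval coverage:
#' model C, K = 80, nbar = 80, tau2 = 0.025, M = 10, deltaI = 0.5,
#' correlated ordinal moderators.  Both the FE and the RE tree are fitted
#' with their recommended pruning parameter; among the replications whose
#' pruned tree has exactly the canonical model-C shape, the per-subgroup
#' mean estimates and 95% CI coverage are reported.
#'
#' @param reps number of replications (default 1000).
#' @param seed integer seed.
#' @return A list with elements `FE` and `RE`, each a data.frame of
#'   subgroup summaries, plus the matched-tree counts.
#' @export
mc_coverage_cell <- function(reps = 1000L, seed = 1L) {
  des <- sim_design(K = 80L, nbar = 80, tau2 = 0.025, deltaI = 0.5,
                    M = 10L, type = "ordinal", correlated = TRUE,
                    model = "C")
  out <- list()
  for (model in c("FE", "RE")) {
    cell <- run_cell(des, reps = reps, model = model, c = NULL,
                     seed = seed, coverage = TRUE)
    out[[model]] <- cell$coverage[[1L]]
  }
  out
}

#' Reproduce the summary tables of the simulation study at chosen scale
#'
#' Drives [mc_type1_error()], [mc_recovery()] and [mc_coverage_cell()]
#' from a configuration list.  Each element is optional:
#' * `type1`: list of argument lists for [mc_type1_error()];
#' * `recovery`: list of argument lists for [mc_recovery()];
#' * `coverage`: argument list for [mc_coverage_cell()].
#'
#' @param config configuration list; an empty list yields empty output.
#' @return A list with elements `type1` (row-bound data.frame),
#'   `recovery` (row-bound data.frame) and `coverage`.
#' @export
reproduce_tables <- function(config = list()) {
  out <- list()
  if (!is.null(config$type1))
    out$type1 <- do.call(rbind, lapply(config$type1, function(a)
      do.call(mc_type1_error, a)))
  if (!is.null(config$recovery))
    out$recovery <- do.call(rbind, lapply(config$recovery, function(a)
      do.call(mc_recovery, a)))
  if (!is.null(config$coverage))
    out$coverage <- do.call(mc_coverage_cell, config$coverage)
  out
}
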