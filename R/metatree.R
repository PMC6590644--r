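#' Fit a meta-analytic regression tree with cross-validated pruning
#'
#' Grows a fixed-effect or random-effects meta-analytic regression tree
#' ([grow_fe()] / [grow_re()]), selects its size by k-fold cross-validation
#' with the c standard-error rule ([cv_curve()], [select_c_se()]), and
#' tests the subgrouping defined by the pruned tree with the
#' between-subgroups Q-statistic against a chi-squared distribution with
#' `J - 1` degrees of freedom.  A pruned tree with no splits is a
#' "trivial" tree: no moderator effect detected, and no test is performed.
#'
#' @param formula either a formula `d ~ x1 + x2 + ...` with the effect
#'   size on the left and moderators on the right (evaluated in `data`),
#'   or an [effect_size_set()] (in which case `vi` and `data` are ignored).
#' @param vi within-study sampling variances (evaluated in `data`).
#' @param data a data frame holding the formula variables.
#' @param model `"RE"` (default) for the random-effects tree with pooled
#'   DerSimonian-Laird residual heterogeneity, or `"FE"` for the
#'   fixed-effect tree.
#' @param c pruning parameter of the c*SE rule.  The default depends on
#'   the number of studies K: for FE trees `c = 1` if `K < 80`, else 0.5;
#'   for RE trees `c = 1` if `K < 120`, else 0.5.  Larger `c` prunes more.
#' @param folds number of cross-validation folds (default 10).
#' @param min_node_size minimum studies per terminal node (default 2).
#' @param max_terminal cap on terminal nodes of the initial tree
#'   (default 10).
#' @param alpha significance level of the Q_B test (default 0.05).
#' @param level confidence level for subgroup intervals (default 0.95).
#' @param seed optional integer seed for the fold assignment.
#' @param types optional moderator type tags, see [effect_size_set()].
#'
#' @return An object of class `"metatree"` with components `tree` (the
#'   pruned `"meta_tree"`), `fit` (the `"subgroup_fit"` on its terminal
#'   nodes, `NULL` for a trivial tree... see Details), `cv`, `size`, `c`,
#'   `model` and `call`.  Methods: `print`, `summary`, `coef`, `predict`,
#'   `residuals`, `plot`, `simulate`.
#'
#' @examples
#' set.seed(7)
#' sim <- gen_dataset(sim_design(model = "B", K = 60, deltaI = 0.8,
#'                               type = "binary", M = 5))
#' fit <- metatree(sim$data, model = "FE", seed = 1)
#' print(fit)
#' @export
metatree <- function(formula, vi = NULL, data = NULL,
                     model = c("RE", "FE"), c = NULL, folds = 10L,
                     min_node_size = 2L, max_terminal = 10L,
                     alpha = 0.05, level = 0.95, seed = NULL, types = NULL) {
  model <- match.arg(model)
  es <- if (inherits(formula, "effect_size_set")) formula
        else es_from_formula(formula, substitute(vi), data, types,
                             parent.frame())
  curve <- metatree_curve(es, model, folds, seed, min_node_size, max_terminal)
  out <- metatree_select(curve, c = c, alpha = alpha, level = level)
  out$call <- match.call()
  out
}

es_from_formula <- function(formula, vi_expr, data, types, env) {
  mf <- model.frame(formula, data = data, na.action = NULL)
  d <- mf[[1L]]
  X <- mf[-1L]
  vi <- eval(vi_expr, data, env)
  if (is.null(vi)) stop("'vi' (sampling variances) is required")
  effect_size_set(d, vi, X, types = types)
}

#' Grow a tree and compute its cross-validation curve (no size selected)
#'
#' The expensive half of [metatree()]: master growth plus the k-fold
#' cross-validation curve.  Useful when the same grown tree is to be
#' pruned under several values of the pruning parameter; pass the result
#' to [metatree_select()] once per `c`.
#'
#' @inheritParams metatree
#' @param es an [effect_size_set()].
#' @return An object of class `"metatree_curve"` with the master tree,
#'   its nested family and the `"cv_curve"`.
#' @export
metatree_curve <- function(es, model = c("RE", "FE"), folds = 10L,
                           seed = NULL, min_node_size = 2L,
                           max_terminal = 10L) {
  model <- match.arg(model)
  stopifnot(inherits(es, "effect_size_set"))
  master <- grow_tree(es, model, min_node_size, max_terminal)
  curve <- cv_curve(es, model, folds = folds, seed = seed,
                    min_node_size = min_node_size,
                    max_terminal = max_terminal, master = master)
  structure(list(es = es, model = model, master = master,
                 family = nested_sequence(master), cv = curve),
            class = "metatree_curve")
}

#' Prune a grown tree at a given c and test the subgrouping
#'
#' @param curve a `"metatree_curve"` from [metatree_curve()].
#' @inheritParams metatree
#' @return A `"metatree"` object.
#' @export
metatree_select <- function(curve, c = NULL, alpha = 0.05, level = 0.95) {
  stopifnot(inherits(curve, "metatree_curve"))
  K <- curve$es$K
  if (is.null(c)) c <- recommended_c(curve$model, K)
  size <- select_c_se(curve$cv, c)
  keep <- curve$family$splits[[match(size, curve$family$sizes)]]
  pruned <- prune_to_splits(curve$master, keep)
  fit <- if (curve$model == "RE") re_partition_fit(curve$es, pruned$term)
         else fe_partition_fit(curve$es, pruned$term)
  fit$ci <- subgroup_ci(fit, level)
  structure(list(tree = pruned, fit = fit, cv = curve$cv, size = size,
                 c = c, alpha = alpha, level = level, model = curve$model,
                 es = curve$es, trivial = size == 1L, call = NULL),
            class = "metatree")
}

#' @export
print.metatree <- function(x, digits = 3, ...) {
  cat(sprintf("%s meta-analytic regression tree (K = %d, c = %g)\n\n",
              x$model, x$es$K, x$c))
  if (x$trivial) {
    cat("Trivial tree: no moderator effect detected.\n")
    cat(sprintf("Overall summary effect: %.3f [%.3f, %.3f]",
                x$fit$est, x$fit$ci[1], x$fit$ci[2]))
    if (x$model == "RE") cat(sprintf("  (tau2 = %.4f)", x$fit$tau2))
    cat("\n")
  } else {
    print_tree_structure(x$tree)
    cat("\n")
    qlab <- if (x$model == "RE") "Q*_B" else "Q_B"
    cat(sprintf("%s = %.*f on %d df, p = %.4g", qlab, digits,
                x$fit$Q_B, x$fit$df, x$fit$pvalue))
    if (x$model == "RE") cat(sprintf(";  tau2 = %.4f", x$fit$tau2))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.metatree <- function(object, ...) {
  x <- object
  print(x)
  if (!x$trivial) {
    cat("\nSubgroups (terminal nodes):\n")
    tids <- sort(unique(x$tree$term))
    tab <- data.frame(node = tids, k = x$fit$k,
                      estimate = round(x$fit$est, 3),
                      lower = round(x$fit$ci[, 1], 3),
                      upper = round(x$fit$ci[, 2], 3))
    print(tab, row.names = FALSE)
  }
  cat("\nCross-validation curve:\n")
  print(x$cv)
  invisible(x)
}

#' @export
coef.metatree <- function(object, ...) {
  tids <- sort(unique(object$tree$term))
  setNames(object$fit$est, paste0("node", tids))
}

#' Predict subgroup membership or summary effect for new studies
#'
#' Routes new moderator rows down the pruned tree.
#'
#' @param object a `"metatree"`.
#' @param newdata data frame of moderators (defaults to training data).
#' @param type `"effect"` for the subgroup summary effect a study falls
#'   into, `"node"` for the terminal node id.
#' @param ... unused.
#' @export
predict.metatree <- function(object, newdata = NULL,
                             type = c("effect", "node"), ...) {
  type <- match.arg(type)
  Xn <- if (is.null(newdata)) object$tree$enc$X
        else encode_new(object$es, newdata)
  lab <- route_tree(object$tree, Xn)
  if (type == "node") return(lab)
  tids <- sort(unique(object$tree$term))
  object$fit$est[match(lab, tids)]
}

encode_new <- function(es, newdata) {
  newdata <- as.data.frame(newdata)
  es2 <- es
  miss <- setdiff(names(es$X), names(newdata))
  if (length(miss) > 0L)
    stop("newdata lacks moderator columns: ", paste(miss, collapse = ", "))
  # re-encode with the training factor levels
  combined <- rbind(es$X, newdata[names(es$X)])
  es2$X <- combined
  es2$d <- c(es$d, rep(0, nrow(newdata)))
  es2$vi <- c(es$vi, rep(1, nrow(newdata)))
  es2$K <- nrow(combined)
  enc <- encode_moderators(es2)
  enc$X[seq(es$K + 1L, nrow(combined)), , drop = FALSE]
}

#' @export
residuals.metatree <- function(object, ...) {
  object$es$d - predict(object)
}

#' @export
fitted.metatree <- function(object, ...) predict(object)

#' Simulate effect sizes from a fitted meta-analytic tree
#'
#' Draws new observed effect sizes from the fitted subgroup model:
#' `d_k ~ N(dhat_k, vi_k + tau2)` with `dhat_k` the summary effect of the
#' subgroup study `k` falls into (for FE fits `tau2 = 0`).
#'
#' @param object a `"metatree"`.
#' @param nsim number of simulated data sets.
#' @param seed optional seed.
#' @param ... unused.
#' @return A data frame with `nsim` columns of simulated effect sizes.
#' @export
simulate.metatree <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  sdv <- sqrt(object$es$vi + object$fit$tau2)
  out <- as.data.frame(replicate(nsim, rnorm(length(mu), mu, sdv)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted meta-analytic tree
#'
#' Minimal base-graphics rendering of the pruned tree: internal nodes show
#' the split rule, terminal nodes the subgroup summary effect and size.
#'
#' @param x a `"metatree"`.
#' @param ... passed to [plot.default()].
#' @export
plot.metatree <- function(x, ...) {
  tree <- x$tree
  ids <- sort(unique(c(1L, 2L * tree$splits$node, 2L * tree$splits$node + 1L)))
  # layout: terminals evenly spaced, internals centered over their children
  tids <- sort(unique(tree$term))
  xpos <- setNames(rep(NA_real_, length(ids)), ids)
  xpos[as.character(tids)] <- seq_along(tids)
  repeat {
    filled <- FALSE
    for (id in rev(ids)) {
      key <- as.character(id)
      if (is.na(xpos[key]) && !is.na(xpos[as.character(2 * id)]) &&
          !is.na(xpos[as.character(2 * id + 1)])) {
        xpos[key] <- (xpos[as.character(2 * id)] +
                      xpos[as.character(2 * id + 1)]) / 2
        filled <- TRUE
      }
    }
    if (!filled) break
  }
  ypos <- -floor(log2(ids)); names(ypos) <- ids
  graphics::plot(NA, xlim = range(xpos, na.rm = TRUE) + c(-0.5, 0.5),
                 ylim = range(ypos) + c(-0.5, 0.5), axes = FALSE,
                 xlab = "", ylab = "", ...)
  for (s in seq_len(nrow(tree$splits))) {
    nd <- tree$splits$node[s]
    for (ch in c(2L * nd, 2L * nd + 1L))
      graphics::segments(xpos[as.character(nd)], ypos[as.character(nd)],
                         xpos[as.character(ch)], ypos[as.character(ch)])
    graphics::text(xpos[as.character(nd)], ypos[as.character(nd)] + 0.18,
                   format_rule(tree, s, "left"), cex = 0.8)
  }
  est <- setNames(x$fit$est, tids)
  for (t in tids) {
    k <- as.character(t)
    graphics::points(xpos[k], ypos[k], pch = 22, bg = "grey90", cex = 3)
    graphics::text(xpos[k], ypos[k] - 0.25,
                   sprintf("%.2f\n(n=%d)", est[[as.character(t)]],
                           sum(tree$term == t)), cex = 0.75)
  }
  invisible(x)
}
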