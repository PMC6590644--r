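# Tree-size selection: nested subtree families, 10-fold cross-validation,
# and the c*SE rule.

#' Nested family of subtrees of a grown tree
#'
#' For fixed-effect trees, the CART cost-complexity (weakest-link) sequence
#' on the inverse-variance weighted node sums of squares: repeatedly
#' collapse the internal node(s) with the smallest per-split impurity
#' reduction `(Q_node - sum Q_leaves) / (leaves - 1)`.  For random-effects
#' trees, the prefixes of the recorded split order, which is the natural
#' nested family of a sequentially grown tree.  Either way the family is
#' nested, starts at the root-only tree, and ends at the grown tree.
#'
#' @param tree a `"meta_tree"`.
#' @return A list with `sizes` (number of terminal nodes, strictly
#'   increasing from 1) and `splits` (for each size, the integer rows of
#'   `tree$splits` retained).
#' @export
nested_sequence <- function(tree) {
  stopifnot(inherits(tree, "meta_tree"))
  S <- nrow(tree$splits)
  if (tree$model == "RE") {
    keep <- lapply(0:S, function(s) seq_len(s))
    alpha <- NULL
  } else {
    wl <- weakest_link_sequence(tree)
    keep <- wl$splits
    alpha <- wl$alpha
  }
  sizes <- vapply(keep, function(k) length(k) + 1L, integer(1))
  o <- order(sizes)
  list(sizes = sizes[o], splits = keep[o],
       alpha = if (is.null(alpha)) NULL else alpha[o])
}

# Weakest-link cost-complexity pruning.  Also records, per family member,
# the complexity parameter at which it becomes optimal (normalized by the
# root impurity, the CART cp convention): 0 for the full tree, then the
# successive minima of the per-split impurity reduction.
weakest_link_sequence <- function(tree) {
  S <- nrow(tree$splits)
  rootQ <- tree$nodes$Q[tree$nodes$id == 1L]
  if (S == 0L) return(list(splits = list(integer(0)), alpha = 0))
  nodeQ <- setNames(tree$nodes$Q, tree$nodes$id)
  fam <- list(seq_len(S))
  alpha <- 0
  cur <- seq_len(S)
  while (length(cur) > 0L) {
    snodes <- tree$splits$node[cur]
    terms <- terminal_ids(snodes)
    # per internal node: risk of its leaves and leaf count within `cur`
    g <- vapply(snodes, function(nd) {
      desc_t <- terms[is_descendant(terms, nd)]
      leafQ <- sum(nodeQ[as.character(desc_t)])
      (nodeQ[[as.character(nd)]] - leafQ) / (length(desc_t) - 1L)
    }, numeric(1))
    weakest <- snodes[g <= min(g) + 1e-12]
    drop <- cur[vapply(snodes, function(nd)
      any(nd == weakest) || any(is_descendant(nd, weakest)), logical(1))]
    cur <- setdiff(cur, drop)
    fam[[length(fam) + 1L]] <- cur
    alpha <- c(alpha, min(g) / max(rootQ, .Machine$double.eps))
  }
  list(splits = fam, alpha = cummax(alpha))
}

# is `x` a (non-strict descendant excluded) descendant of any node in `anc`?
is_descendant <- function(x, anc) {
  vapply(x, function(id) {
    id <- id %/% 2L
    while (id >= 1L) {
      if (any(id == anc)) return(TRUE)
      id <- id %/% 2L
    }
    FALSE
  }, logical(1))
}

# Restrict a grown tree to a subset of its splits (a member of the nested
# family), recomputing memberships and dropping orphaned nodes.
prune_to_splits <- function(tree, keep) {
  sub <- tree
  sub$splits <- tree$splits[keep, , drop = FALSE]
  sub$left_levels <- tree$left_levels[keep]
  sub$right_levels <- tree$right_levels[keep]
  sub$term <- route_tree(sub, tree$enc$X)
  live <- c(1L, 2L * sub$splits$node, 2L * sub$splits$node + 1L)
  sub$nodes <- tree$nodes[tree$nodes$id %in% live, , drop = FALSE]
  sub$memb <- NULL
  sub$pruned_from <- n_terminal(tree)
  sub
}

route_tree <- function(tree, Xnum, keep = seq_len(nrow(tree$splits))) {
  cpp_route(tree$splits$node[keep], tree$splits$var[keep],
            tree$splits$kind[keep], tree$splits$threshold[keep],
            tree$left_levels[keep], tree$right_levels[keep],
            tree$splits$n_left[keep], tree$splits$n_right[keep], Xnum)
}

#' Cross-validated error curve for tree-size selection
#'
#' Splits the studies into `folds` random folds.  For each fold a tree is
#' grown on the training studies only (same model, same growth settings)
#' and its nested family computed; every held-out study is then routed down
#' the training subtree of each candidate size and its prediction error
#' recorded as `(d - dhat)^2 / vi`, where `dhat` is the training node
#' summary it lands in (for RE trees, the node mean under RE weights with
#' the heterogeneity pooled on the training partition) and `vi` its
#' sampling variance.  The error weight is deliberately the fixed
#' inverse sampling variance for both models: weighting by the
#' size-specific `1/(vi + tau2)` would let the re-estimated heterogeneity
#' absorb exactly the lack of fit the curve is meant to expose, leaving
#' the curve flat.  Candidate sizes are the sizes of the master tree's nested
#' family; the fold subtree used at size `s` is the largest member of the
#' fold's own family with at most `s` terminal nodes.  The standard error
#' of each point is the standard error of the per-study error
#' contributions.
#'
#' @param data an [effect_size_set()].
#' @param model `"FE"` or `"RE"`.
#' @param folds number of cross-validation folds (default 10).
#' @param seed optional integer seed for the fold assignment.
#' @param min_node_size,max_terminal growth settings, as in [grow_fe()].
#' @param master optionally, an already-grown master tree.
#' @return An object of class `"cv_curve"`: `sizes`, `error`, `se`,
#'   `folds`, `fold_assign`, `seed`.
#' @export
cv_curve <- function(data, model = c("FE", "RE"), folds = 10L, seed = NULL,
                     min_node_size = 2L, max_terminal = 10L, master = NULL) {
  model <- match.arg(model)
  if (is.null(master))
    master <- grow_tree(data, model, min_node_size, max_terminal)
  fam <- nested_sequence(master)
  K <- data$K
  if (length(fam$sizes) == 1L) {
    e <- cv_leaf_error(data, model)
    se <- if (K > 1L) sd(e) / sqrt(K) else 0
    curve <- list(sizes = 1L, error = mean(e), se = se,
                  folds = 0L, fold_assign = rep(1L, K), seed = seed)
    return(structure(curve, class = "cv_curve"))
  }
  if (K < folds) stop("need at least as many studies as folds")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  fold <- sample(rep_len(seq_len(folds), K))
  errmat <- matrix(NA_real_, K, length(fam$sizes))
  # FE candidate sizes are matched to fold subtrees on the
  # cost-complexity scale (the fold subtree optimal at the geometric mean
  # of the master's cp interval, the CART convention), so only comparably
  # strong fold splits enter the curve; raw size matching would let every
  # fold's overfit splits in and inflate its noise.  The RE prefix family
  # carries no cost-complexity sequence; fold prefixes are matched by
  # size, mirroring the sequential growth order.
  beta <- NULL
  if (model == "FE") {
    a_upper <- c(Inf, head(fam$alpha, -1L))
    beta <- sqrt(fam$alpha * a_upper) # Inf for root, 0 for the full tree
    beta[1L] <- Inf
    beta[is.nan(beta)] <- 0
  }
  for (f in seq_len(folds)) {
    tr <- which(fold != f)
    va <- which(fold == f)
    es_tr <- data[tr]
    ftree <- grow_tree(es_tr, model, min_node_size, max_terminal)
    ffam <- nested_sequence(ftree)
    Xva <- master$enc$X[va, , drop = FALSE]
    fis <- vapply(seq_along(fam$sizes), function(si) {
      if (model == "FE") min(which(ffam$alpha <= beta[si]))
      else max(which(ffam$sizes <= fam$sizes[si]))
    }, integer(1))
    for (fi in unique(fis)) {
      keep <- ffam$splits[[fi]]
      lab_tr <- if (length(keep) > 0L) route_tree(ftree, ftree$enc$X, keep)
                else rep(1L, length(tr))
      tau2 <- if (model == "RE") pooled_dl_tau2(es_tr, lab_tr) else 0
      w_tr <- 1 / (es_tr$vi + tau2)
      tids <- sort(unique(lab_tr))
      g <- match(lab_tr, tids)
      est <- rowsum_vec(w_tr * es_tr$d, g) / rowsum_vec(w_tr, g)
      lab_va <- if (length(keep) > 0L) route_tree(ftree, Xva, keep)
                else rep(1L, length(va))
      pred <- est[match(lab_va, tids)]
      errmat[va, fis == fi] <- (data$d[va] - pred)^2 / data$vi[va]
    }
  }
  structure(list(sizes = fam$sizes, error = colMeans(errmat),
                 se = apply(errmat, 2, sd) / sqrt(K),
                 folds = folds, fold_assign = fold, seed = seed),
            class = "cv_curve")
}

# degenerate curve for a tree that cannot be grown: in-sample root error
cv_leaf_error <- function(data, model) {
  tau2 <- if (model == "RE") pooled_dl_tau2(data) else 0
  w <- 1 / (data$vi + tau2)
  (data$d - sum(w * data$d) / sum(w))^2 / data$vi
}

#' @export
print.cv_curve <- function(x, digits = 4, ...) {
  cat("Cross-validated error curve (", x$folds, "folds )\n")
  print(data.frame(size = x$sizes, error = round(x$error, digits),
                   se = round(x$se, digits)), row.names = FALSE)
  invisible(x)
}

#' Select a tree size with the c standard-error rule
#'
#' Returns the smallest candidate size whose cross-validated error is
#' within `c` standard errors of the minimum: `error <= min(error) +
#' c * se[argmin]`.  With `c = 0` this is the error-minimizing size
#' (smallest such size on ties); the selection is non-increasing in `c`.
#'
#' @param curve a `"cv_curve"`.
#' @param c non-negative pruning parameter.
#' @return The chosen number of terminal nodes.
#' @examples
#' curve <- structure(list(sizes = 1:3, error = c(10, 4, 4.5),
#'                         se = c(1, 1, 1)), class = "cv_curve")
#' select_c_se(curve, 1)  # 2
#' @export
select_c_se <- function(curve, c = 1) {
  if (!is.numeric(c) || length(c) != 1L || c < 0)
    stop("'c' must be a single non-negative number")
  i0 <- which.min(curve$error)
  thr <- curve$error[i0] + c * curve$se[i0]
  if (!is.finite(thr)) thr <- curve$error[i0]
  curve$sizes[min(which(curve$error <= thr))]
}

# Recommended pruning parameter: stricter pruning (c = 1) for smaller
# meta-analyses, where spurious splits survive cross-validation more often.
recommended_c <- function(model, K) {
  if (model == "FE") { if (K < 80) 1 else 0.5 }
  else { if (K < 120) 1 else 0.5 }
}
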