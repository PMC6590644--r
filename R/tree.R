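# Tree growth.  The fast path is the compiled grower in src/growtree.cpp;
# candidate_splits(), best_split_fe(), score_split_re() and best_split_re()
# are the plain-R reference implementations of the same search, kept
# deliberately simple (exhaustive enumeration) so they can serve as an
# independent check of the compiled code.

grow_tree <- function(data, model, min_node_size = 2L, max_terminal = 10L) {
  stopifnot(inherits(data, "effect_size_set"))
  if (min_node_size < 1L) stop("'min_node_size' must be at least 1")
  if (max_terminal < 1L) stop("'max_terminal' must be at least 1")
  enc <- encode_moderators(data)
  out <- cpp_grow(data$d, data$vi, enc$X, enc$kind,
                  as.integer(min_node_size), as.integer(max_terminal),
                  identical(model, "RE"))
  S <- length(out$split_node)
  splits <- data.frame(
    node = out$split_node, var = out$split_var,
    kind = out$split_kind, threshold = out$split_thresh,
    n_left = out$split_nl, n_right = out$split_nr,
    score = out$split_score, tau2 = out$split_tau2)
  nodes <- data.frame(
    id = out$node_id, parent = out$node_parent, n = out$node_n,
    Q = out$node_Q, mean = out$node_mean, wsum = out$node_sw)
  structure(list(
    model = model, splits = splits,
    left_levels = out$split_left, right_levels = out$split_right,
    nodes = nodes, memb = out$memb,
    term = if (S > 0) out$memb[, S + 1L] else rep(1L, data$K),
    data = data, enc = enc,
    min_node_size = as.integer(min_node_size),
    max_terminal = as.integer(max_terminal)),
    class = "meta_tree")
}

#' Grow a fixed-effect meta-analytic regression tree
#'
#' Recursive binary partitioning of the studies with inverse-variance
#' weights.  Among all admissible splits of all current terminal nodes, the
#' one with the largest local between-subgroups Q-statistic (equivalently,
#' the smallest sum of offspring within-node Q) is made first, so the
#' recorded split order is the greedy order.  Growth stops when no node can
#' be split into children of at least `min_node_size` studies, or when the
#' tree reaches `max_terminal` terminal nodes.  Zero-gain splits are
#' permitted; pruning removes them.
#'
#' @param data an [effect_size_set()].
#' @param min_node_size minimum number of studies in a terminal node
#'   (default 2).
#' @param max_terminal cap on the number of terminal nodes of the grown
#'   tree (default 10).
#' @return An object of class `"meta_tree"`: split table (node, moderator,
#'   rule, local Q_B), node table (id, parent, size, weighted mean, within
#'   Q), and per-study memberships after each split.
#' @seealso [grow_re()], [metatree()]
#' @export
grow_fe <- function(data, min_node_size = 2L, max_terminal = 10L) {
  grow_tree(data, "FE", min_node_size, max_terminal)
}

#' Grow a random-effects meta-analytic tree by sequential partitioning
#'
#' At every step all current terminal nodes are candidate parents.  Each
#' candidate split is scored by the between-subgroups Q*-statistic of the
#' *whole* resulting partition, after re-estimating the pooled
#' DerSimonian-Laird residual heterogeneity for that partition; the
#' highest-scoring split is made.  Because the heterogeneity estimate is
#' global, a split in one node changes the summaries of all others, so the
#' recorded split order matters: it defines the nested family used in
#' pruning.  Per-step `tau2` and `Q*_B` are stored in the split table.
#'
#' @inheritParams grow_fe
#' @return A `"meta_tree"` object; `splits$tau2` and `splits$score` hold
#'   the pooled heterogeneity and whole-tree Q*_B after each split.
#' @seealso [grow_fe()], [metatree()]
#' @export
grow_re <- function(data, min_node_size = 2L, max_terminal = 10L) {
  grow_tree(data, "RE", min_node_size, max_terminal)
}

n_terminal <- function(tree) nrow(tree$splits) + 1L

terminal_ids <- function(splits_node) {
  if (length(splits_node) == 0L) return(1L)
  kids <- c(2L * splits_node, 2L * splits_node + 1L)
  sort(setdiff(kids, splits_node))
}

#' @export
print.meta_tree <- function(x, ...) {
  cat(sprintf("%s meta-analytic tree: %d terminal nodes (%d splits)\n",
              x$model, n_terminal(x), nrow(x$splits)))
  if (nrow(x$splits) > 0L) print_tree_structure(x)
  invisible(x)
}

format_rule <- function(tree, s, side = c("left", "right")) {
  side <- match.arg(side)
  sp <- tree$splits[s, ]
  vn <- tree$enc$varnames[sp$var]
  if (sp$kind == 0L) {
    sprintf("%s %s %.4g", vn, if (side == "left") "<=" else ">", sp$threshold)
  } else {
    codes <- if (side == "left") tree$left_levels[[s]] else tree$right_levels[[s]]
    labs <- tree$enc$levels[[sp$var]]
    vals <- if (!is.null(labs)) labs[codes] else codes
    sprintf("%s in {%s}", vn, paste(vals, collapse = ","))
  }
}

print_tree_structure <- function(tree) {
  recurse <- function(node, depth) {
    s <- match(node, tree$splits$node)
    ind <- paste(rep("  ", depth), collapse = "")
    nd <- tree$nodes[tree$nodes$id == node, ]
    if (is.na(s)) {
      cat(sprintf("%s[%d] n=%d, d+=%.3f*\n", ind, node, nd$n, nd$mean))
    } else {
      cat(sprintf("%s[%d] n=%d, d+=%.3f; split: %s\n",
                  ind, node, nd$n, nd$mean, format_rule(tree, s, "left")))
      recurse(2L * node, depth + 1L)
      recurse(2L * node + 1L, depth + 1L)
    }
  }
  recurse(1L, 0L)
  invisible(tree)
}

# ---- R reference paths (exhaustive search oracles) ------------------------

#' Enumerate the candidate split rules for one moderator in a node
#'
#' Continuous and ordinal moderators yield a threshold rule at every
#' midpoint between consecutive distinct observed values ("<= t" goes
#' left); a binary moderator yields its single dichotomy; a nominal
#' moderator with L observed levels yields all `2^(L-1) - 1` proper
#' bipartitions.  A moderator that is constant within the node yields an
#' empty list.
#'
#' @param data an [effect_size_set()].
#' @param members integer indices of the studies in the node.
#' @param moderator column index of the moderator.
#' @return A list of rules; each rule is a list with `var`, `kind`
#'   (`"threshold"` or `"subset"`), and `threshold` or `left_levels` /
#'   `right_levels` (integer level codes).
#' @export
candidate_splits <- function(data, members = seq_len(data$K), moderator) {
  enc <- encode_moderators(data)
  x <- enc$X[members, moderator]
  if (enc$kind[moderator] == 0L) {
    u <- sort(unique(x))
    if (length(u) < 2L) return(list())
    mid <- (u[-length(u)] + u[-1L]) / 2
    lapply(mid, function(t)
      list(var = moderator, kind = "threshold", threshold = t))
  } else {
    pres <- sort(unique(x))
    L <- length(pres)
    if (L < 2L) return(list())
    out <- list()
    for (sub in 0:(2^(L - 1L) - 2L)) {
      left <- pres[1L]
      for (j in seq_len(L - 1L))
        if (bitwAnd(sub, bitwShiftL(1L, j - 1L)) > 0L)
          left <- c(left, pres[j + 1L])
      out[[length(out) + 1L]] <-
        list(var = moderator, kind = "subset",
             left_levels = left, right_levels = setdiff(pres, left))
    }
    out
  }
}

rule_goes_left <- function(rule, xv) {
  if (rule$kind == "threshold") xv <= rule$threshold
  else xv %in% rule$left_levels
}

#' Exhaustive fixed-effect split search in one node (reference path)
#'
#' Scores every candidate rule of every moderator by the sum of the
#' offspring within-node Q-statistics and returns the admissible rule
#' minimizing it (equivalently, maximizing the local between-subgroups Q).
#' Ties are broken deterministically: lowest moderator index, then lowest
#' threshold / earliest subset.  This is the plain-R oracle for the
#' compiled grower used by [grow_fe()].
#'
#' @inheritParams candidate_splits
#' @param min_node_size minimum child size for a rule to be admissible.
#' @return A list with `rule`, `child_q` (Q_left + Q_right) and `qb`
#'   (the local between-subgroups Q-statistic), or `NULL` if no admissible
#'   rule exists.
#' @export
best_split_fe <- function(data, members = seq_len(data$K),
                          min_node_size = 2L) {
  enc <- encode_moderators(data)
  d <- data$d[members]; vi <- data$vi[members]
  best <- NULL
  for (m in seq_along(enc$kind)) {
    xv <- enc$X[members, m]
    for (rule in candidate_splits(data, members, m)) {
      lf <- rule_goes_left(rule, xv)
      if (sum(lf) < min_node_size || sum(!lf) < min_node_size) next
      cq <- within_q_fe(d[lf], vi[lf]) + within_q_fe(d[!lf], vi[!lf])
      if (is.null(best) || cq < best$child_q)
        best <- list(rule = rule, child_q = cq,
                     qb = within_q_fe(d, vi) - cq)
    }
  }
  best
}

labels_of <- function(tree_or_labels, K) {
  if (inherits(tree_or_labels, "meta_tree")) tree_or_labels$term
  else {
    lab <- as.integer(tree_or_labels)
    if (length(lab) != K) stop("label vector has wrong length")
    lab
  }
}

#' Score one candidate split of a random-effects tree (reference path)
#'
#' Forms the partition consisting of the current terminal nodes with
#' `parent` replaced by the two children induced by `rule`, and returns the
#' between-subgroups Q*-statistic of [re_partition_fit()] on it (residual
#' heterogeneity re-pooled for the whole candidate partition).  Free of
#' side effects.
#'
#' @param data an [effect_size_set()].
#' @param tree a `"meta_tree"` or an integer vector of current terminal
#'   node labels, one per study.
#' @param parent terminal node id to split.
#' @param rule a rule as produced by [candidate_splits()].
#' @param min_node_size minimum child size; an inadmissible rule is an error.
#' @return The whole-tree Q*_B of the candidate partition.
#' @export
score_split_re <- function(data, tree = rep(1L, data$K), parent = 1L, rule,
                           min_node_size = 2L) {
  lab <- labels_of(tree, data$K)
  mem <- which(lab == parent)
  if (length(mem) == 0L) stop("'parent' is not a terminal node of the tree")
  enc <- encode_moderators(data)
  lf <- rule_goes_left(rule, enc$X[mem, rule$var])
  if (sum(lf) < min_node_size || sum(!lf) < min_node_size)
    stop("rule is inadmissible under the minimum node size")
  lab2 <- lab
  lab2[mem[lf]] <- 2L * parent
  lab2[mem[!lf]] <- 2L * parent + 1L
  re_partition_fit(data, lab2)$Q_B
}

#' Exhaustive random-effects split search over a tree (reference path)
#'
#' For every candidate parent (each current terminal node) finds the
#' (moderator, rule) pair maximizing the whole-tree Q*-statistic, then
#' picks the parent with the highest such score; deterministic tie-breaks
#' as in [best_split_fe()] with parent node id first.  This enumerates
#' exactly what the compiled sequential grower of [grow_re()] searches.
#'
#' @inheritParams score_split_re
#' @return A list with `node`, `rule` and `qb`, or `NULL` when no
#'   admissible split exists.
#' @export
best_split_re <- function(data, tree = rep(1L, data$K), min_node_size = 2L) {
  lab <- labels_of(tree, data$K)
  enc <- encode_moderators(data)
  best <- NULL
  for (p in sort(unique(lab))) {
    mem <- which(lab == p)
    if (length(mem) < 2L * min_node_size) next
    for (m in seq_along(enc$kind)) {
      for (rule in candidate_splits(data, mem, m)) {
        lf <- rule_goes_left(rule, enc$X[mem, m])
        if (sum(lf) < min_node_size || sum(!lf) < min_node_size) next
        qb <- score_split_re(data, lab, p, rule, min_node_size)
        if (is.null(best) || qb > best$qb)
          best <- list(node = p, rule = rule, qb = qb)
      }
    }
  }
  best
}
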