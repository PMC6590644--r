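#' Construct a meta-analytic data set of effect sizes and moderators
#'
#' Bundles per-study observed effect sizes (standardized mean differences),
#' their within-study sampling variances, and a typed moderator matrix into
#' the unit consumed by all tree and subgroup-analysis functions.
#'
#' @param d numeric vector of observed effect sizes, one per study.
#' @param vi numeric vector of within-study sampling variances, strictly
#'   positive, same length as `d`.
#' @param X moderators: a data frame (or object coercible to one) with one
#'   row per study.  May be `NULL` for a moderator-free set.
#' @param types character vector giving the type of each moderator column,
#'   each one of `"binary"`, `"nominal"`, `"ordinal"`, `"continuous"`.
#'   If `NULL`, types are inferred: factors are nominal, ordered factors
#'   ordinal, logicals and two-valued numerics binary, other numerics
#'   continuous.
#' @param ids optional study labels.
#'
#' @return An object of class `"effect_size_set"`: a list with elements
#'   `d`, `vi`, `X`, `types`, `ids` and `K` (the number of studies).
#' @examples
#' es <- effect_size_set(d = c(0.2, 0.5, 0.8), vi = rep(0.04, 3),
#'                       X = data.frame(x1 = c(0, 1, 1)))
#' es$K
#' @export
effect_size_set <- function(d, vi, X = NULL, types = NULL, ids = NULL) {
  d <- as.numeric(d)
  vi <- as.numeric(vi)
  if (length(d) < 1L) stop("need at least one study")
  if (length(d) != length(vi))
    stop("'d' and 'vi' must have the same length")
  if (anyNA(d) || anyNA(vi)) {
    bad <- which(is.na(d) | is.na(vi))
    stop("missing effect size or variance in rows: ",
         paste(bad, collapse = ", "))
  }
  if (any(vi <= 0)) {
    bad <- which(vi <= 0)
    stop("non-positive sampling variance in rows: ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(X)) {
    X <- as.data.frame(X)
    if (nrow(X) != length(d))
      stop("moderator matrix must have one row per study")
    if (is.null(types)) {
      types <- vapply(X, infer_mod_type, character(1))
    } else {
      types <- rep_len(types, ncol(X))
      ok <- types %in% c("binary", "nominal", "ordinal", "continuous")
      if (!all(ok))
        stop("unknown moderator type tag: ",
             paste(unique(types[!ok]), collapse = ", "))
    }
    names(types) <- names(X)
  } else {
    X <- data.frame(row.names = seq_along(d))
    types <- character(0)
  }
  if (is.null(ids)) ids <- paste0("study_", seq_along(d))
  structure(list(d = d, vi = vi, X = X, types = types,
                 ids = as.character(ids), K = length(d)),
            class = "effect_size_set")
}

infer_mod_type <- function(col) {
  if (is.ordered(col)) return("ordinal")
  if (is.factor(col) || is.character(col)) return("nominal")
  if (is.logical(col)) return("binary")
  u <- unique(col[!is.na(col)])
  if (length(u) <= 2L) return("binary")
  "continuous"
}

#' @export
print.effect_size_set <- function(x, ...) {
  cat("Meta-analytic data set:", x$K, "studies,",
      ncol(x$X), "moderators\n")
  if (ncol(x$X) > 0L) {
    cat("  moderators:",
        paste0(names(x$X), " (", x$types, ")", collapse = ", "), "\n")
  }
  cat(sprintf("  effect sizes: mean %.3f, range [%.3f, %.3f]\n",
              mean(x$d), min(x$d), max(x$d)))
  invisible(x)
}

#' @export
`[.effect_size_set` <- function(x, i, ...) {
  effect_size_set(x$d[i], x$vi[i], x$X[i, , drop = FALSE],
                  types = unname(x$types), ids = x$ids[i])
}

# Encode the moderator columns into the numeric matrix consumed by the C++
# growers.  kind 0 = ordered values (threshold splits), kind 1 = nominal
# (integer level codes 1..L, subset splits).
encode_moderators <- function(es) {
  M <- ncol(es$X)
  if (M == 0L) {
    return(list(X = matrix(0, es$K, 0), kind = integer(0),
                levels = vector("list", 0), varnames = character(0)))
  }
  Xn <- matrix(0, es$K, M)
  kind <- integer(M)
  levs <- vector("list", M)
  for (m in seq_len(M)) {
    col <- es$X[[m]]
    type <- es$types[[m]]
    if (type == "nominal") {
      # keep the declared level set: subsets of the data must encode
      # levels identically to the full set
      f <- if (is.factor(col)) col else factor(as.character(col))
      if (nlevels(f) > 12L)
        stop("nominal moderator '", names(es$X)[m],
             "' has more than 12 levels; subset enumeration not supported")
      Xn[, m] <- as.integer(f)
      kind[m] <- 1L
      levs[[m]] <- levels(f)
    } else if (type == "ordinal") {
      if (is.ordered(col)) {
        Xn[, m] <- as.integer(col)
        levs[[m]] <- levels(col)
      } else Xn[, m] <- as.numeric(col)
      kind[m] <- 0L
    } else { # binary or continuous
      if (is.factor(col)) {
        Xn[, m] <- as.integer(col) - 1L
        levs[[m]] <- levels(col)
      } else Xn[, m] <- as.numeric(col)
      kind[m] <- 0L
    }
  }
  colnames(Xn) <- names(es$X)
  list(X = Xn, kind = kind, levels = levs, varnames = names(es$X))
}
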