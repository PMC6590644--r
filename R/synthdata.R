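# Synthetic moderated meta-analytic data.  A design cell fixes the number
# of studies K, the average within-study sample size, the residual
# heterogeneity, the effective-subgroup mean effect, the number and type of
# moderators, their correlation structure, and one of five true tree
# structures of increasing complexity (A..E).  Observed standardized mean
# differences are drawn through the noncentral-t sampling distribution of
# the two-sample SMD.

#' Describe one cell of the simulation design
#'
#' @param K number of studies (>= 4).
#' @param nbar average within-study sample size (>= 10); per-study sizes
#'   are drawn from N(nbar, (nbar/3)^2).
#' @param tau2 residual between-study heterogeneity (>= 0).
#' @param deltaI mean effect size in the effective subgroup(s); ineffective
#'   subgroups have mean 0.
#' @param M number of candidate moderators (at least the number the true
#'   model uses).
#' @param type moderator type: `"binary"`, `"nominal"`, `"ordinal"` or
#'   `"continuous"`.
#' @param correlated if `TRUE`, moderators are generated from a random
#'   positive-definite correlation matrix with off-diagonal entries
#'   roughly in \[-0.40, 0.40\]; otherwise independently.
#' @param model true tree structure: `"A"` (no moderator effect), `"B"`
#'   (main effect of x1), `"C"` (two-way interaction x1:x2), `"D"` (two
#'   two-way interactions on x1, x2, x3), `"E"` (three-way interaction
#'   x1:x2:x3).
#' @param hedges apply the small-sample (Hedges) correction to the
#'   simulated effect sizes (default `TRUE`).
#' @return A `"sim_design"` list.
#' @export
sim_design <- function(K = 80L, nbar = 80, tau2 = 0, deltaI = 0.5,
                       M = 10L, type = c("binary", "nominal", "ordinal",
                                         "continuous"),
                       correlated = FALSE, model = c("C", "A", "B", "D", "E"),
                       hedges = TRUE) {
  type <- match.arg(type)
  model <- match.arg(model)
  stopifnot(K >= 4L, nbar >= 10, tau2 >= 0, deltaI >= 0)
  need <- n_true_moderators(model)
  if (M < need)
    stop("model ", model, " needs at least ", need, " moderators")
  structure(list(K = as.integer(K), nbar = nbar, tau2 = tau2,
                 deltaI = deltaI, M = as.integer(M), type = type,
                 correlated = correlated, model = model, hedges = hedges),
            class = "sim_design")
}

n_true_moderators <- function(model) {
  switch(model, A = 0L, B = 1L, C = 2L, D = 3L, E = 3L)
}

#' Definition of a true tree model
#'
#' Encodes which moderators carry the effect and the predicate defining
#' the effective subgroup(s): a study is "effective" (mean effect
#' `deltaI`) exactly when the predicate holds, otherwise its mean effect
#' is 0.  Effective levels by type: binary, level 1; ordinal, levels 2-3;
#' nominal, labels B or C; continuous, value above 20 (the population
#' mean).
#' Model predicates: B, x1 effective; C, x1 and x2 both effective; D,
#' (x1 and x2 effective) or (x1 ineffective and x3 effective); E, x1, x2
#' and x3 all effective; A, never.
#'
#' @param model `"A"`..`"E"`.
#' @param type moderator type, as in [sim_design()].
#' @return A `"true_model"` list with `model`, `type` and `vars` (indices
#'   of the true moderators).
#' @export
true_model <- function(model = c("A", "B", "C", "D", "E"),
                       type = c("binary", "nominal", "ordinal",
                                "continuous")) {
  model <- match.arg(model)
  type <- match.arg(type)
  structure(list(model = model, type = type,
                 vars = seq_len(n_true_moderators(model))),
            class = "true_model")
}

# Effectiveness indicator of one moderator column (on the generated scale).
# Each true split separates roughly comparable mass: binary, the upper
# half; ordinal, the upper two of three levels; nominal, two of the three
# labels; continuous, values above the population mean.  For the
# three-level types this matches the subgroup sizes implied by the
# reported subgroup-estimate dispersion in the canonical interaction cell
# (an effective subgroup of ~4/9 of the studies under a two-way
# interaction).
effective_level <- function(x, type) {
  switch(type,
         binary = x == 1,
         ordinal = as.integer(x) >= 2L,
         nominal = as.character(x) %in% c("B", "C"),
         continuous = x > 20)
}

#' Per-study true subgroup means under a tree model
#'
#' @param truth a [true_model()].
#' @param X moderator data frame containing the true moderator columns.
#' @param deltaI effective-subgroup mean effect.
#' @return Numeric vector: `deltaI` for effective studies, 0 otherwise.
#' @export
true_subgroup_means <- function(truth, X, deltaI) {
  stopifnot(inherits(truth, "true_model"))
  if (ncol(X) < length(truth$vars))
    stop("moderator matrix lacks the true moderator columns")
  e <- lapply(truth$vars, function(j) effective_level(X[[j]], truth$type))
  eff <- switch(truth$model,
                A = rep(FALSE, nrow(X)),
                B = e[[1L]],
                C = e[[1L]] & e[[2L]],
                D = (e[[1L]] & e[[2L]]) | (!e[[1L]] & e[[3L]]),
                E = e[[1L]] & e[[2L]] & e[[3L]])
  ifelse(eff, deltaI, 0)
}

#' Draw a random moderator correlation matrix
#'
#' Sample correlation matrix of `3 * max(M, 20)` standard-normal rows:
#' positive definite with unit diagonal and off-diagonal entries
#' concentrated in roughly \[-0.40, 0.40\].  Draws whose largest absolute
#' off-diagonal exceeds 0.5 are rejected and redrawn (bounded retries).
#'
#' @param M dimension.
#' @return An `M` x `M` correlation matrix.
#' @export
random_cor_matrix <- function(M) {
  n0 <- 3L * max(M, 20L)
  for (i in 1:50) {
    R <- stats::cor(matrix(rnorm(n0 * M), n0, M))
    if (M == 1L || max(abs(R[upper.tri(R)])) <= 0.5) return(R)
  }
  stop("failed to draw an admissible correlation matrix")
}

#' Generate a typed moderator matrix
#'
#' Latent variables are multivariate normal (correlation identity or a
#' random draw from [random_cor_matrix()]).  Continuous moderators use
#' mean 20 and standard deviation 10, rounded to one decimal to allow
#' duplicate values.  Binary moderators dichotomize the latent normal at
#' its population mean (levels 0/1).  Nominal and ordinal moderators cut
#' at the population 1/3 and 2/3 quantiles; ordinal keeps the interval
#' order (levels 1 < 2 < 3), nominal assigns labels A/B/C to the
#' intervals in random order per moderator.
#'
#' @param design a [sim_design()].
#' @param seed optional integer seed.
#' @return A data frame of `design$M` moderators `x1..xM`.
#' @export
gen_moderators <- function(design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- design$M; K <- design$K
  R <- if (design$correlated) random_cor_matrix(M) else diag(M)
  Z <- matrix(rnorm(K * M), K, M) %*% chol(R)
  X <- switch(design$type,
    continuous = as.data.frame(round(20 + 10 * Z, 1)),
    binary = as.data.frame(1L * (Z > 0)),
    ordinal = {
      cuts <- qnorm(c(1, 2) / 3)
      as.data.frame(lapply(seq_len(M), function(m)
        findInterval(Z[, m], cuts) + 1L))
    },
    nominal = {
      cuts <- qnorm(c(1, 2) / 3)
      as.data.frame(lapply(seq_len(M), function(m) {
        iv <- findInterval(Z[, m], cuts) + 1L
        labs <- sample(c("A", "B", "C"))
        factor(labs[iv], levels = c("A", "B", "C"))
      }))
    })
  names(X) <- paste0("x", seq_len(M))
  X
}

#' Sample within-study sample sizes
#'
#' Per-study totals are drawn from N(nbar, (nbar/3)^2), rounded to the
#' nearest even integer (two equal arms) and clamped below at 10.
#'
#' @param K number of studies.
#' @param nbar average sample size.
#' @param seed optional seed.
#' @return Integer vector of even study sizes >= 10.
#' @export
sample_study_sizes <- function(K, nbar, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- rnorm(K, nbar, nbar / 3)
  n <- 2L * as.integer(round(n / 2))
  pmax(n, 10L)
}

#' Sample observed effect sizes through the noncentral-t distribution
#'
#' True per-study effects are `delta_k ~ N(Delta_k, tau2)`.  For a
#' two-arm study of total size `n_k` with equal allocation, the t-statistic
#' is noncentral t with `n_k - 2` degrees of freedom and noncentrality
#' `delta_k * sqrt(n_k) / 2`; the observed standardized mean difference is
#' `d_k = t * 2 / sqrt(n_k)`, optionally times the Hedges small-sample
#' factor `1 - 3 / (4 (n_k - 2) - 1)`.  Sampling variances use the
#' standard large-sample SMD formula `4 / n_k + d_k^2 / (2 n_k)`.
#'
#' @param Delta per-study true subgroup means.
#' @param tau2 residual heterogeneity variance.
#' @param n per-study total sample sizes (even, >= 4).
#' @param seed optional seed.
#' @param hedges apply the small-sample correction (default `TRUE`).
#' @return A list with `d` (observed effects), `vi` (sampling variances)
#'   and `delta` (the latent true effects).
#' @export
sample_effects <- function(Delta, tau2, n, seed = NULL, hedges = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(Delta)
  stopifnot(length(n) == K, all(n >= 4))
  delta <- rnorm(K, Delta, sqrt(tau2))
  tstat <- rt(K, df = n - 2, ncp = delta * sqrt(n) / 2)
  d <- tstat * 2 / sqrt(n)
  if (hedges) d <- d * (1 - 3 / (4 * (n - 2) - 1))
  vi <- 4 / n + d^2 / (2 * n)
  list(d = d, vi = vi, delta = delta)
}

#' Generate one synthetic meta-analytic data set
#'
#' Composes [gen_moderators()], [true_subgroup_means()],
#' [sample_study_sizes()] and [sample_effects()] for a design cell.
#' Deterministic given `seed`.
#'
#' @param design a [sim_design()].
#' @param seed optional integer seed.
#' @return A list with `data` (an [effect_size_set()]), `truth` (the
#'   [true_model()]), `Delta` (per-study subgroup means), `delta` (latent
#'   true effects) and `n` (study sizes).
#' @export
gen_dataset <- function(design, seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.null(seed)) set.seed(seed)
  X <- gen_moderators(design)
  truth <- true_model(design$model, design$type)
  Delta <- true_subgroup_means(truth, X, design$deltaI)
  n <- sample_study_sizes(design$K, design$nbar)
  eff <- sample_effects(Delta, design$tau2, n, hedges = design$hedges)
  types <- rep(design$type, design$M)
  es <- effect_size_set(eff$d, eff$vi, X, types = types)
  list(data = es, truth = truth, Delta = Delta, delta = eff$delta, n = n,
       design = design)
}
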