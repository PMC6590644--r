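# Subgroup meta-analysis arithmetic: FE/RE weighted summaries, within-,
# between- and total Q-statistics, pooled DerSimonian-Laird residual
# heterogeneity, and the chi-squared test of a subgrouping.

check_dv <- function(d, vi) {
  if (length(d) < 1L) stop("empty effect-size vector")
  if (length(d) != length(vi)) stop("'d' and 'vi' lengths differ")
  if (any(!is.finite(vi)) || any(vi <= 0))
    stop("sampling variances must be strictly positive")
  invisible(TRUE)
}

#' Fixed-effect summary effect size
#'
#' Inverse-variance weighted mean of the observed effect sizes,
#' `sum(d/vi) / sum(1/vi)`.  For the members of a tree node this equals the
#' node's weighted mean, i.e. the FE summary effect in that node.
#'
#' @param d numeric vector of effect sizes.
#' @param vi numeric vector of within-study sampling variances (> 0).
#' @return The FE summary effect (length-1 numeric).
#' @examples
#' fe_summary(c(0.2, 0.5, 0.8), rep(0.04, 3)) # 0.5
#' @export
fe_summary <- function(d, vi) {
  check_dv(d, vi)
  w <- 1 / vi
  sum(w * d) / sum(w)
}

#' Within-subgroup Q-statistic under the fixed-effect model
#'
#' `Q = sum((d - d_plus)^2 / vi)` with `d_plus` the FE summary effect.
#' This is also the impurity of a tree node under FE weighting.
#'
#' @inheritParams fe_summary
#' @return The Q-statistic (non-negative).
#' @examples
#' within_q_fe(c(0, 1), c(0.04, 0.04)) # 12.5
#' @export
within_q_fe <- function(d, vi) {
  check_dv(d, vi)
  dp <- fe_summary(d, vi)
  max(0, sum((d - dp)^2 / vi))
}

# Normalize a partition specification to an integer vector 1..J.
as_partition <- function(part, K) {
  if (is.list(part) && !is.null(part$assignment)) part <- part$assignment
  g <- as.integer(factor(part))
  if (length(g) != K) stop("partition length must equal the number of studies")
  if (anyNA(g)) stop("partition contains missing assignments")
  g
}

#' Chi-squared test of the between-subgroups Q-statistic
#'
#' Upper-tail probability of a chi-squared distribution with `J - 1`
#' degrees of freedom, the reference distribution for the between-subgroups
#' Q-statistic of a `J`-subgroup partition.
#'
#' @param qb between-subgroups Q-statistic (>= 0).
#' @param J number of subgroups (>= 2).
#' @return The p-value.
#' @examples
#' qb_test(6.25, 2) # about 0.0124
#' @export
qb_test <- function(qb, J) {
  if (J < 2) stop("the Q_B test needs at least two subgroups")
  if (!is.finite(qb) || qb < 0) stop("'qb' must be a non-negative number")
  pchisq(qb, df = J - 1, lower.tail = FALSE)
}

#' Pooled DerSimonian-Laird estimate of residual heterogeneity
#'
#' Moment estimator of the residual between-study variance pooled across
#' the subgroups of a partition:
#' `tau2 = max(0, (sum(Q_j) - sum(df_j)) / sum(C_j))` with
#' `df_j = K_j - 1` and `C_j = sum(w) - sum(w^2)/sum(w)` computed from the
#' FE weights `w = 1/vi` within subgroup `j`.  The estimate is truncated
#' at zero.  A partition in which every subgroup is a singleton carries no
#' information about residual heterogeneity; it returns 0 with a warning.
#'
#' @param data an [effect_size_set()], or any list with elements `d`, `vi`.
#' @param part subgroup assignment: integer/factor vector with one entry
#'   per study (defaults to a single subgroup).
#' @return The pooled residual heterogeneity estimate (>= 0).
#' @examples
#' es <- effect_size_set(c(0, 1), c(0.04, 0.04))
#' pooled_dl_tau2(es) # (12.5 - 1) / 25 = 0.46
#' @export
pooled_dl_tau2 <- function(data, part = rep(1L, length(data$d))) {
  d <- data$d; vi <- data$vi
  check_dv(d, vi)
  g <- as_partition(part, length(d))
  w <- 1 / vi
  sw <- rowsum_vec(w, g)
  sw2 <- rowsum_vec(w^2, g)
  swd <- rowsum_vec(w * d, g)
  swd2 <- rowsum_vec(w * d^2, g)
  Kj <- tabulate(g)
  Qj <- pmax(0, swd2 - swd^2 / sw)
  Cj <- sw - sw2 / sw
  Csum <- sum(Cj)
  if (Csum <= 0) {
    if (all(Kj == 1L))
      warning("all subgroups are singletons; residual heterogeneity set to 0")
    return(0)
  }
  max(0, (sum(Qj) - sum(Kj - 1L)) / Csum)
}

rowsum_vec <- function(x, g) {
  as.vector(rowsum(x, g, reorder = TRUE))
}

partition_fit <- function(data, part, tau2) {
  d <- data$d; vi <- data$vi
  check_dv(d, vi)
  g <- as_partition(part, length(d))
  Kj <- tabulate(g)
  if (any(Kj == 0L)) stop("empty subgroup in partition")
  w <- 1 / (vi + tau2)
  sw <- rowsum_vec(w, g)
  swd <- rowsum_vec(w * d, g)
  swd2 <- rowsum_vec(w * d^2, g)
  est <- swd / sw
  grand <- sum(swd) / sum(sw)
  Qj <- pmax(0, swd2 - swd^2 / sw)
  QT <- max(0, sum(swd2) - sum(swd)^2 / sum(sw))
  QB <- max(0, QT - sum(Qj))
  J <- length(Kj)
  fit <- structure(list(
    model = if (tau2 > 0 || attr(tau2, "re") %||% FALSE) "RE" else "FE",
    J = J, k = Kj, est = est, grand = grand,
    Q_j = Qj, Q_B = QB, Q_T = QT, tau2 = as.numeric(tau2),
    wsum = sw, df = J - 1L,
    pvalue = if (J >= 2) qb_test(QB, J) else NA_real_,
    assignment = g), class = "subgroup_fit")
  fit$ci <- subgroup_ci(fit)
  fit
}

#' Fixed-effect subgroup meta-analysis of a partition
#'
#' Computes per-subgroup FE summary effects and within-subgroup
#' Q-statistics, the grand FE mean, and the between-subgroups and total
#' Q-statistics.  The additive decomposition `Q_T = sum(Q_j) + Q_B` holds
#' to numerical tolerance.
#'
#' @inheritParams pooled_dl_tau2
#' @return An object of class `"subgroup_fit"` with elements `model`
#'   (`"FE"`), `J`, `k` (subgroup sizes), `est` (subgroup summaries),
#'   `grand`, `Q_j`, `Q_B`, `Q_T`, `tau2` (0), `df`, `pvalue` and `ci`
#'   (per-subgroup 95% Wald bounds).
#' @examples
#' es <- effect_size_set(c(0.1, 0.2, 0.6, 0.7), rep(0.04, 4))
#' fit <- fe_partition_fit(es, c(1, 1, 2, 2))
#' fit$Q_B # 6.25
#' @export
fe_partition_fit <- function(data, part) {
  partition_fit(data, part, tau2 = 0)
}

#' Random-effects subgroup meta-analysis of a partition
#'
#' Pools the DerSimonian-Laird residual heterogeneity across subgroups
#' ([pooled_dl_tau2()]), forms RE weights `1/(vi + tau2)`, and computes the
#' RE subgroup summaries and Q*-statistics, with
#' `Q*_B = Q*_T - sum(Q*_j)`.  When the heterogeneity estimate is exactly
#' zero the fit coincides with [fe_partition_fit()].
#'
#' @inheritParams pooled_dl_tau2
#' @return A `"subgroup_fit"` object as in [fe_partition_fit()], with
#'   `model = "RE"` and `tau2` the pooled estimate.
#' @export
re_partition_fit <- function(data, part) {
  tau2 <- pooled_dl_tau2(data, part)
  attr(tau2, "re") <- TRUE
  fit <- partition_fit(data, part, tau2 = tau2)
  fit$model <- "RE"
  fit
}

#' Wald confidence intervals for subgroup summary effects
#'
#' Normal-theory intervals `est_j +/- z * sqrt(1 / W_j)` where `W_j` is the
#' sum of the weights used by the fit (FE weights for FE fits, RE weights
#' with the pooled heterogeneity for RE fits).
#'
#' @param fit a `"subgroup_fit"` object.
#' @param level confidence level in (0, 1).
#' @return A matrix with columns `lower` and `upper`, one row per subgroup.
#' @export
subgroup_ci <- function(fit, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("'level' must be a single number strictly between 0 and 1")
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / fit$wsum)
  cbind(lower = fit$est - z * se, upper = fit$est + z * se)
}

#' @export
print.subgroup_fit <- function(x, digits = 3, ...) {
  cat(sprintf("%s subgroup meta-analysis: J = %d subgroups\n", x$model, x$J))
  tab <- data.frame(k = x$k, estimate = round(x$est, digits),
                    Q_within = round(x$Q_j, digits),
                    lower = round(x$ci[, 1], digits),
                    upper = round(x$ci[, 2], digits))
  print(tab, row.names = paste0("  subgroup ", seq_len(x$J)))
  cat(sprintf("tau2 = %.4f;  Q_B = %.3f on %d df", x$tau2, x$Q_B, x$df))
  if (!is.na(x$pvalue)) cat(sprintf(", p = %.4g", x$pvalue))
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
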