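# Shared fixtures, built in code.

# four studies, equal variances, one clean binary signal and one noise column
toy4 <- function() {
  effect_size_set(d = c(0.1, 0.2, 0.6, 0.7), vi = rep(0.04, 4),
                  X = data.frame(x1 = c(0, 0, 1, 1), x2 = c(1, 0, 1, 0)),
                  types = c("binary", "binary"))
}

# small random data set with mixed moderator types, for oracle comparisons
random_es <- function(K = 12, M = 3, seed = 1) {
  set.seed(seed)
  X <- data.frame(x1 = round(rnorm(K, 20, 10), 1),
                  x2 = factor(sample(c("A", "B", "C"), K, replace = TRUE)),
                  x3 = sample(0:1, K, replace = TRUE))[, seq_len(M),
                                                       drop = FALSE]
  effect_size_set(d = rnorm(K, 0, 0.5), vi = runif(K, 0.02, 0.2), X = X,
                  types = c("continuous", "nominal", "binary")[seq_len(M)])
}

# Strong, nearly noiseless realisation of the two-way interaction
# structure.  `x1_edge` adds a small main effect of x1 so that the greedy
# first split deterministically picks x1 (the two moderators are otherwise
# exchangeable).
strong_c_es <- function(K = 64, deltaI = 1, eps = 1e-3, seed = 1,
                        x1_edge = 0) {
  set.seed(seed)
  x1 <- rep(0:1, each = K / 2)
  x2 <- rep(rep(0:1, each = K / 4), 2)
  mu <- ifelse(x1 == 1 & x2 == 1, deltaI, 0) + x1_edge * x1
  effect_size_set(d = mu + eps * rnorm(K), vi = rep(0.05, K),
                  X = data.frame(x1 = x1, x2 = x2,
                                 x3 = sample(0:1, K, TRUE)),
                  types = rep("binary", 3))
}

expect_proportion_close <- function(p, target, n, label,
                                    extra_sd = 0, nsd = 3) {
  tol <- nsd * sqrt(p * (1 - p) / n + extra_sd^2)
  expect_lt(abs(p - target), max(tol, 1e-8), label = label)
}
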