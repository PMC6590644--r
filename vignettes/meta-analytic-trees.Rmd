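---
title: "Meta-analytic regression trees: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-analytic regression trees: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metatree)
```

## The problem

A meta-analysis collects one effect size per study — here standardized
mean differences $d_k$ with known within-study sampling variances
$\sigma^2_{\varepsilon k}$ — together with study-level covariates
(*moderators*): treatment components, population features, design
attributes.  When several moderators are available their effects are
rarely additive, and classical meta-regression struggles to discover
*which combination* of moderators separates effective from ineffective
studies, especially when the relevant interaction is not specified in
advance.  metatree approaches this as a recursive-partitioning problem:
find the binary tree over moderators whose terminal nodes (subgroups)
explain the heterogeneity of the effect sizes.

## Models

Under the **fixed-effect (FE)** view, all variation beyond sampling error
is attributed to subgroup membership.  With weights
$w_k = 1/\sigma^2_{\varepsilon k}$, the subgroup summary is the weighted
mean $d_{j+}$, and the within-subgroup heterogeneity statistic is
$Q_j = \sum_k w_k (d_k - d_{j+})^2$.  For any partition into $J$
subgroups the total statistic decomposes additively,
$Q_T = \sum_j Q_j + Q_B$, exactly as the sum of squares decomposes in
ANOVA.  $Q_B$, the between-subgroups statistic, is referred to a
$\chi^2_{J-1}$ distribution to test the subgrouping.

Under the **random-effects (RE)** view, a residual between-study variance
$\tau^2$ remains even within subgroups.  metatree pools a
DerSimonian–Laird moment estimate across subgroups,
$$\hat\tau^2 = \max\!\left(0,\;
  \frac{\sum_j Q_j - \sum_j (K_j - 1)}{\sum_j C_j}\right),\qquad
  C_j = \sum_k w_{jk} - \frac{\sum_k w_{jk}^2}{\sum_k w_{jk}},$$
so a single $\hat\tau^2$ is shared by all studies, and weights become
$w^*_k = 1/(\sigma^2_{\varepsilon k} + \hat\tau^2)$.  The starred
statistics $Q^*_j$, $Q^*_T$ and $Q^*_B = Q^*_T - \sum_j Q^*_j$ are the RE
analogues.  When $\hat\tau^2 = 0$ every RE quantity coincides with its FE
counterpart; the package tests this degeneracy exactly.

## Tree growth

**FE trees** are grown by recursive partitioning with FE weights.  The
weighted node impurity *is* the within-node $Q$, so the split minimizing
the offspring impurity sum is identical to the split maximizing the local
between-subgroups $Q_B$.  Growth is best-first: among all current
terminal nodes, the split with the largest $Q_B$ gain is made first, so
the recorded split order is the greedy order.  Splits with zero gain are
allowed during growth; pruning removes them.

**RE trees** cannot be grown recursively, because $\hat\tau^2$ is pooled
over the *whole* partition: splitting one node changes the weights — and
therefore the summaries — of every other node.  Growth is sequential: at
each step, every terminal node is a candidate parent, every admissible
(moderator, split point) pair is scored by the whole-tree $Q^*_B$ after
re-pooling $\hat\tau^2$ for the candidate partition, and the best
candidate is accepted.  The split *order* is part of the fitted object;
it defines the nested subtree family used in pruning, and the per-step
$\hat\tau^2$ and $Q^*_B$ are recorded.

Candidate splits are thresholds at midpoints of consecutive observed
values (continuous, ordinal, binary moderators) and all proper
bipartitions of observed levels (nominal moderators, enumerated
exhaustively; the package refuses more than 12 levels).  Ties are broken
deterministically: better score, then lower node id, lower moderator
index, lower threshold or earlier subset.  Two runs on the same data give
identical trees; there is no randomness in growth.

## Pruning: cross-validation with the c·SE rule

The grown tree intentionally overfits.  Final size is chosen by 10-fold
cross-validation: folds are assigned uniformly at random over studies
(seeded), a tree is grown on each training set, and each held-out study
is routed down the training subtree to a node whose training summary
serves as its prediction.  The error contribution of study $k$ is
$(d_k - \hat d_k)^2 / \sigma^2_{\varepsilon k}$; the curve's standard
error at each size is the standard error of these per-study
contributions.  The **c·SE rule** then selects the smallest size whose
error is within $c$ standard errors of the curve minimum; $c = 0$ picks
the argmin, larger $c$ prunes harder.

Two design choices here deserve emphasis, because both were decided by
measurement against the method's published operating characteristics:

* **Error weights are fixed at $1/\sigma^2_{\varepsilon k}$ for both
  models.**  Weighting RE validation errors by
  $1/(\sigma^2_{\varepsilon k} + \hat\tau^2_{\text{train}})$ looks
  natural but is self-defeating: the re-pooled $\hat\tau^2$ absorbs
  exactly the misfit the curve is supposed to expose, the curve flattens
  at $\approx 1$ for every size, and the method loses essentially all
  power.  RE predictions still use the RE node means with the training
  $\hat\tau^2$; only the error scale is fixed.
* **Fold subtrees are matched on strength, not size (FE).**  The FE
  nested family is the CART weakest-link (cost-complexity) sequence, and
  the fold tree evaluated at a candidate size is the fold's own
  cost-complexity subtree at the geometric mean of the master's cp
  interval.  Matching folds by raw size instead lets every fold's
  overfit splits into the curve, inflating its noise — measurably
  inflating the Type I error at $c = 0.5$ and masking real dips.  The RE
  prefix family carries no cost-complexity sequence; RE folds are matched
  by size (the same strength-matching idea, transplanted to the weakest
  retained $Q^*_B$ increment, over-prunes: it roughly halves the null
  rejection rate below the published level and costs a third of the
  canonical-cell retrievals, so it was rejected).

Unseen nominal levels during validation routing go to the child with
more training studies (ties left).  The recommended default $c$ follows
the published operating guideline and depends on the model and the
number of studies: FE, $c = 1$ if $K < 80$, else $0.5$; RE, $c = 1$ if
$K < 120$, else $0.5$; both overridable.

The pruned tree's subgrouping is tested by $Q_B$ (or $Q^*_B$) against
$\chi^2_{J-1}$ at $\alpha = 0.05$.  A tree pruned to the root is a
*trivial tree*: no moderator effect detected, no test performed.  The
test is conditional on a data-driven search, so it is anti-conservative
by construction; Type I error control comes from pruning, and the method
should be read as hypothesis-generating.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `model` | `"RE"` | weighting and splitting criterion (FE or RE) |
| `c` | by K | pruning severity of the c·SE rule (unitless) |
| `folds` | 10 | cross-validation folds |
| `min_node_size` | 2 | minimum studies per terminal node |
| `max_terminal` | 10 | cap on terminal nodes of the grown tree |
| `alpha` | 0.05 | level of the Q_B test |
| `level` | 0.95 | confidence level of subgroup intervals |

`min_node_size = 2` grows trees until terminal nodes hold one or two
studies, the convention of the method.  `max_terminal = 10` bounds the
initial tree; meta-analytic subgroupings of interest have a handful of
terminal nodes, the cross-validation minimum on realistic data sits far
below ten, and the cap keeps the sequential RE search (which rescores
the entire tree at every candidate split) affordable.  Confidence
intervals are normal-theory Wald intervals on the weighted subgroup
means, with the fit's own weights; under FE they ignore residual
heterogeneity, which is precisely the undercoverage the coverage study
reproduces.

## The synthetic-data generator

`sim_design()` / `gen_dataset()` emulate a factorial Monte-Carlo design
over moderated meta-analytic data:

* **Moderators**: latent multivariate normal, either independent or with
  a random positive-definite correlation matrix whose off-diagonals lie
  roughly in $[-0.40, 0.40]$ (drawn as a sample correlation matrix of
  standard normals, dimension-matched; redrawn if any $|r| > 0.5$).
  Continuous moderators are $N(20, 10^2)$ rounded to one decimal; binary
  moderators dichotomize at the population mean; nominal and ordinal
  moderators cut at the population terciles, nominal labels assigned to
  intervals at random, ordinal keeping order.  Polytomization attenuates
  the realized correlations, as it should.
* **True structures**: five tree models of increasing complexity — no
  effect (A), one main effect (B), one two-way interaction (C), two
  two-way interactions (D: effective when $x_1$ and $x_2$ are high *or*
  $x_1$ low and $x_3$ high), one three-way interaction (E).  Effective
  sides per type: binary, the upper level; ordinal, the upper two of
  three levels; nominal, two of the three labels; continuous, values
  above the population mean.  The three-level conventions follow from
  the published subgroup sizes in the canonical interaction cell, whose
  reported estimate dispersions imply an effective subgroup of about
  $(2/3)^2$ of the studies; a single-top-level convention would make the
  effective subgroup one study in nine and is inconsistent with those
  dispersions.
* **Effects**: per-study true effects $\delta_k \sim N(\Delta_k,
  \sigma^2_\tau)$ with $\Delta_k \in \{0, \delta_I\}$; study sizes
  $n_k \sim N(\bar n, (\bar n/3)^2)$ rounded to even integers and
  clamped at 10 (two equal arms); observed effects through the exact
  small-sample route $t \sim t_{n_k-2}(\delta_k \sqrt{n_k}/2)$,
  $d_k = 2t/\sqrt{n_k}$, with the Hedges correction
  $1 - 3/(4(n_k-2)-1)$ applied by default, and variances by the standard
  large-sample formula $4/n_k + d_k^2/(2n_k)$.

What the generator does *not* emulate: publication bias, dependent
effect sizes within studies, missing moderators, measurement error in
moderators, unequal arms, and mixed moderator types within one data set
(the API accepts mixed types; the factorial design does not vary them).
Tests passing on these data certify the algorithmic behaviour of the
estimator under its own assumptions, not robustness to such violations.

## The experiments harness

`run_cell()` streams generate–fit–score over replications of one design
cell, sharing each grown tree across several values of $c$.  Per
replication it scores *detection* (a nontrivial pruned tree with a
significant $Q_B$ — Type I error on model-A data, power otherwise) and
*recovery* (the tree's moderator set equals the true set exactly; by
design this does not additionally require significance, though a switch
exists).  `mc_type1_error()`, `mc_recovery()` and `mc_coverage_cell()`
aggregate cells into the shapes of the published summary tables, with
binomial Monte-Carlo standard errors; a balanced stratified sample of
cells stands in for the full factorial (each factor level appears
equally often, pairings randomized by seed).  The coverage study scores
only replications whose pruned tree is *exactly* the canonical
interaction shape (first split on $x_1$ isolating its effective side,
second on $x_2$ inside the effective child), making subgroups comparable
across replications.  `metareg_recovery()` is the idealized comparator:
a weighted meta-regression (via metafor) with one indicator per true
effective-subgroup predicate term, scored as all true terms significant.

Problem sizes in the shipped tests and the acceptance script: 24
stratified cells × 100 replications per Type-I-error setting, 500–1000
replications of the coverage cell, 24 cells × 50–100 replications for
recovery.  At these scales the binomial Monte-Carlo standard errors are
a few thousandths, comparable to the between-cell sampling error, and
the comparisons in the tests combine both.

## Numerical choices and degenerate inputs

* Within-node $Q$ and the DL numerator are truncated at zero; $Q^*_B$ is
  non-negative by construction but clamped against roundoff.
* An all-singleton partition carries no information about $\tau^2$; it
  yields 0 with a warning rather than an error, so growth to minimum
  node size 2 never aborts.
* A data set too small to split (or a single study) produces a trivial
  tree with `pvalue = NA` — reported as "no test".
* Tie-breaks everywhere are deterministic (see above); two runs differ
  only through the cross-validation fold seed.
* The compiled growers use exact enumeration; the package also ships
  plain-R exhaustive reference implementations (`best_split_fe()`,
  `best_split_re()`, `score_split_re()`) used as oracles in the tests.

## Known limitations

* The greedy search finds local optima; a two-split look-ahead can find
  strictly better trees on the same data.  Not implemented.
* Moderators with many distinct values enjoy more candidate splits and
  therefore a selection advantage; unbiased-selection schemes (GUIDE)
  are out of scope.
* The $Q_B$ test after search is a pseudo-test; only its non-significant
  outcomes are directly interpretable.
* RE pruning rests on the split-order prefix family, which is natural
  for a sequential tree but has no cost-complexity theory behind it; its
  liberal-pruning ($c = 0.5$) null rejection rate runs somewhat above
  the published value at $K = 120$ in our reproduction, while the
  strict rule ($c = 1$) matches.
* Linear effects of continuous moderators are approximated by step
  functions; residual-adjusted hybrid fits are out of scope.
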