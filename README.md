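# metatree

Meta-analytic regression trees for discovering moderator interaction
effects in meta-analysis, for meta-analysts who have many study-level
moderators and no prespecified interaction structure.

A meta-analysis supplies one observed effect size per study (here,
standardized mean differences `d_k`) with known sampling variances
`v_k`, plus moderator columns of mixed type (binary, nominal, ordinal,
continuous). metatree partitions the studies into subgroups by a binary
tree over the moderators, so that combinations of moderators — not just
main effects — explain the heterogeneity:

* **Fixed-effect (FE) trees** grow by recursive partitioning with
  inverse-variance weights `w_k = 1/v_k`. The weighted node impurity
  equals the within-subgroup heterogeneity statistic
  `Q_j = Σ w_k (d_k − d_j+)²`, so each split maximizes the local
  between-subgroups statistic `Q_B` (with `Q_T = Σ_j Q_j + Q_B`).
* **Random-effects (RE) trees** add a residual between-study variance
  τ², pooled across subgroups by the DerSimonian–Laird moment estimator
  `τ² = max(0, (Σ Q_j − Σ(K_j − 1)) / Σ C_j)`, giving weights
  `1/(v_k + τ²)`. Because τ² is re-estimated for the whole partition at
  every candidate split, growth is *sequential* rather than recursive:
  all terminal nodes compete at each step, scored by the whole-tree
  `Q*_B`.
* Tree size is selected by 10-fold cross-validation with the **c·SE
  rule** (smallest tree within `c` standard errors of the minimum
  cross-validated error; default `c` depends on the model and number of
  studies), and the final subgrouping is tested by `Q_B` against a
  χ² distribution with `J − 1` degrees of freedom.

The package also ships a synthetic-data generator for moderated
meta-analytic data sets (five true tree structures of increasing
complexity, four moderator types, correlated or independent moderators,
noncentral-t sampling of observed SMDs) and a Monte-Carlo harness that
measures the method's Type I error, power, moderator recovery and
confidence-interval coverage at configurable scale.

## A worked example

```r
library(metatree)
set.seed(7)
sim <- gen_dataset(sim_design(model = "C", K = 80, nbar = 80, tau2 = 0.025,
                              deltaI = 0.5, M = 10, type = "ordinal",
                              correlated = TRUE), seed = 101)
fit <- metatree(sim$data, model = "RE", seed = 1)
summary(fit)
```

```
RE meta-analytic regression tree (K = 80, c = 1)

[1] n=80, d+=0.153; split: x2 <= 1.5
  [2] n=28, d+=-0.077*
  [3] n=52, d+=0.286; split: x1 <= 1.5
    [6] n=16, d+=-0.108*
    [7] n=36, d+=0.452*

Q*_B = 76.234 on 2 df, p = 2.792e-17;  tau2 = 0.0243

Subgroups (terminal nodes):
 node  k estimate  lower upper
    2 28   -0.080 -0.180 0.019
    6 16   -0.101 -0.238 0.037
    7 36    0.448  0.359 0.538
```

The data were generated with a two-way interaction: studies are
effective (true mean 0.5) only when both `x1` and `x2` sit in their
upper levels. The fitted tree recovers exactly that structure — a first
split on `x2`, a second on `x1` inside its upper branch — and isolates
an effective subgroup of 36 studies with summary effect 0.448
(95% CI 0.359–0.538) against two null subgroups near zero. The pooled
residual heterogeneity (τ² = 0.024) matches the generating value 0.025,
and `Q*_B = 76.2` on 2 df rejects homogeneity of the three subgroups.
Because the tree was found and tested on the same data, the test is
anti-conservative: read significant results as hypotheses, not
confirmations.

`metatree()` also accepts a formula interface
(`metatree(d ~ x1 + x2, vi = v, data = dat)`), and the fitted object
supports `print`, `summary`, `coef`, `predict`, `residuals`, `plot` and
`simulate`. `write_tree()` serializes a fit to JSON. A thin command-line
front end lives at `inst/cli/metatree.R` (subcommands `fit`, `simulate`,
`experiment`).

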