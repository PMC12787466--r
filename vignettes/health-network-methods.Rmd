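---
title: "Partial-correlation health networks: model, conventions and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial-correlation health networks: model, conventions and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcnet)
```

## The model

`pcnet` analyses a cohort of N participants measured on 17 mixed-type
variables — sociodemographics (sex, age, marital status, social position),
three factor-analytic nutritional-pattern scores (NP1 minerals/vitamins, NP2
carbohydrates, NP3 fat/sodium), physical/metabolic markers (BMI,
hypertension, glucose, insulin, total cholesterol, triacylglycerol, HOMA-IR)
and psychological scales (depression, anxiety, stress) — as a Gaussian
graphical model. Each variable is a node; the edge weight between nodes $i$
and $j$ is their partial correlation

$$R_{p,ij} \;=\; -\,\frac{\Omega_{ij}}{\sqrt{\Omega_{ii}\,\Omega_{jj}}},$$

where $\Omega = S^{-1}$ is the inverse of the sample covariance matrix
($n-1$ denominator). This is algebraically identical to correlating the
residuals of $i$ and $j$ after regressing each on the other 15 variables,
and the package's tests verify that identity against a regression-based
oracle to $10^{-8}$.

Categorical variables (sex, marital status, social position, hypertension)
enter as their numeric codes, giving a single mixed Pearson-based matrix.
Polychoric/polyserial refinements are deliberately out of scope: the
analysis this package implements treats the mixed matrix as one correlation
structure, and the simulation design below is consistent with that choice.

**Edge significance.** For each pair the two-sided p-value comes from the
standard t-transform for partial correlations,
$t = r\sqrt{\mathrm{df}/(1-r^2)}$ with $\mathrm{df} = n - 2 - k$ and
$k = 15$ conditioning variables (df $= 171$ at $n = 188$). Counting the
conditioning set in the degrees of freedom is a convention choice; with
df this large the practical difference from df $= n - 2$ is negligible, but
the convention is recorded in every run log. Under global independence this
test is exact for Gaussian data, and a 1000-replicate simulation in the
test suite confirms that the screen `p < 0.25` retains 25% ± 2% of the 136
candidate edges — the calibration that justifies interpreting the
threshold as a retention rate.

**Edge selection.** Edges with $p < \alpha$ (strictly below; default
$\alpha = 0.25$) are retained with their signed $R_p$ as weight. This is a
deliberately liberal screen intended to prune only near-zero associations;
**no multiple-testing correction is applied**, so retained edges must be
read as "not negligible", not as significant discoveries. All 17 nodes stay
in the graph even when isolated.

## Graph statistics and their conventions

Published per-node tables from Gephi-based analyses pin down several
conventions that generic libraries implement differently. `pcnet` fixes
them as follows; the first two are forced by arithmetic (the fixtures in
the test suite reproduce the published values exactly):

* **Unweighted path metrics.** Closeness, harmonic closeness, betweenness,
  diameter and average path length all use hop distances, not weighted
  distances. A 17-node configuration with 9 neighbours and 7 nodes at
  distance 2 gives closeness $16/23 = 0.6957$ and harmonic closeness
  $12.5/16 = 0.7813$ — exactly the published pairing, which only unit
  distances can produce.
* **Closeness** is $(n-1)/\sum_t d(v,t)$ over reachable targets (isolated
  nodes score 0); **harmonic closeness** is $\frac{1}{n-1}\sum_t 1/d(v,t)$
  with $1/\infty = 0$, so it degrades gracefully on disconnected graphs.
* **Betweenness** is the raw Brandes accumulation over unordered pairs with
  fractional credit for tied shortest paths — no normalisation (a 17-node
  star centre scores $\binom{16}{2} = 120$).
* **Eigenvector centrality** is the leading eigenvector of the
  absolute-weight adjacency matrix, normalised so the maximum score is 1.
  Absolute weights keep the matrix non-negative, which Perron–Frobenius
  requires; a `weights = "unit"` flag gives the purely topological variant.
* **HITS authority/hub** run on the same absolute-weight matrix with unit
  L2 normalisation (the published Authority column has Euclidean norm 1,
  which identifies the convention). On undirected graphs hub = authority
  entrywise.
* **Local clustering** is $2T/(k(k-1))$ with $T$ the edges among a node's
  $k$ neighbours; degree-below-2 nodes score 0.
* **Modularity** is $Q = \sum_c \left[e_c/m - \gamma\,(d_c/2m)^2\right]$ on
  absolute weights, and **Louvain** is the standard two-phase
  local-moving/aggregation algorithm with resolution $\gamma = 1$ (the
  Gephi default) and a seed-shuffled visiting order. Community ids are
  renumbered by descending size so output is stable given the seed.

### Numerical choices

Power iterations (eigenvector, HITS) run on $A + I$ rather than $A$: the
spectral shift leaves eigenvectors unchanged but makes the leading
eigenvalue strictly dominant, so bipartite structures (trees, stars) cannot
oscillate. Tolerance is $10^{-10}$ with a 10,000-iteration cap that errors
rather than returning a stale vector. Louvain accepts a move only when the
modularity gain exceeds $10^{-10}$, which protects the termination proof
against floating-point noise. Report tables round half away from zero
(`round_report()`), matching the published tables' convention rather than
IEEE half-to-even. Degenerate inputs fail loudly and by name: constant
columns, collinear columns, $n \le p + 2$, non-positive-definite latent
correlation targets.

## The synthetic cohort generator

No participant-level data are released for the study cohort, so the
generator stands in for them. It emulates exactly three things:

1. **Marginals** — the reported means/SDs for continuous variables and the
   exact count frequencies for categorical ones (81/188 women, 148/35/5
   marital statuses, 71/62/55 social positions, 48/188 hypertensive).
2. **Block structure** — a latent Gaussian copula whose correlation matrix
   has `within_block_rho` inside the three empirically reported clusters
   ({insulin, glucose, HOMA}, {cholesterol, TAG}, {everything else}) and
   `between_block_rho` across them. Positive definiteness is checked
   before sampling, not assumed. Binary/ordinal columns arise by
   thresholding the latent normal at the quantiles of the cumulative
   category probabilities; continuous columns by the affine map
   $\mu + \sigma z$.
3. **The HOMA-IR identity** — with `homa_mode = "formula"` (the default)
   the HOMA column is recomputed row-wise as insulin × glucose / 405, so
   the table is internally consistent the way a real laboratory table
   would be.

**The HOMA inconsistency.** The reported insulin mean (2.54 µIU/mL) and
glucose mean (147.80 mg/dL) imply HOMA-IR ≈ 0.93 under the index's own
formula, not the reported mean of 10.69 (SD 2.62) — most plausibly a units
discrepancy in the insulin column. The package does not adjudicate:
`homa_mode = "formula"` is internally consistent but misses the reported
HOMA moments; `homa_mode = "sampled"` reproduces the reported moments
(treating HOMA as just another correlated marginal) but breaks the formula.
Both are first-class options.

**Default correlation levels.** The analysis does not report its latent
correlations, so the defaults — `within_block_rho = 0.45`,
`between_block_rho = 0.10` — were fixed once at what a cohort of this kind
plausibly exhibits: strong but not deterministic coherence inside the
glycemic and lipid clusters, weak background dependence everywhere else.
At $n = 188$ and $\alpha = 0.25$ this regime yields connected networks of
roughly 40–60 edges with three Louvain communities, i.e. the same order of
sparsity and modular structure as the published network (50 edges, density
0.368, $Q = 0.40$). Strictly positive biomarkers are floored at 1% of
their mean instead of resampled, which keeps seeded generation
deterministic at the cost of a slight atom near zero (at the default
parameters fewer than 0.5% of draws are floored).

**What the generator does not emulate.** Real pairwise correlations beyond
the block pattern (e.g. the specific BMI–HTN association), skewness and
heavy tails of biomarker distributions, measurement error structure, and —
importantly — the study's exact 50-edge topology and centrality profile.
The published bridge-node finding (stress topping all three centralities)
is a property of the unreleased data, not of the block design; in synthetic
cohorts the strongest-weighted block (the glycemic triad, amplified by the
deterministic HOMA formula) dominates the spectral centralities instead.
Passing tests therefore demonstrate that the *machinery* is correct —
moment recovery, calibration of the screen, planted-community recovery,
convention-exact statistics — not that the synthetic world reproduces the
study's substantive conclusions.

## Problem sizes used in validation

Marginal-recovery checks use $n = 10^5$ draws (2% relative tolerance on
means/SDs, 0.01 absolute on frequencies); cross-block partial-correlation
nulls use $n = 10^4$; screen calibration uses 1000 replicates at the study
size $n = 188$; planted-structure recovery uses 50 seeds at $n = 5000$ with
`within_block_rho = 0.7, between_block_rho = 0`, requiring the glycemic and
lipid blocks each to land in a single community in at least 95% of seeds.
Exhaustive oracles (all set partitions for modularity, full shortest-path
enumeration for betweenness) are run on graphs of up to 8 and 10 nodes
respectively, where enumeration is cheap and exact.

## Limitations

* Pearson-based partial correlations on coded categories are a linear
  approximation; ordinal effects that are non-monotone in the coding are
  invisible.
* The `p < 0.25` screen controls nothing family-wise; downstream metrics
  inherit the noise edges it admits (about a quarter of all null pairs).
* Centrality and community structure are estimated without stability
  intervals; bootstrap assessment is a natural extension but outside the
  current scope.
* With the formula-derived HOMA column, insulin–glucose–HOMA partial
  correlations are near-deterministic; that is faithful to how the index
  is constructed but means the glycemic block's weights are structurally
  larger than anything the rest of the network can produce.
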