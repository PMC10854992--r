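---
title: "Differential co-expression networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential co-expression networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffcornet)
```

## The question the method answers

Two biological conditions — in the motivating use case, a
trastuzumab-resistant (BT474R, "R") and a trastuzumab-sensitive (BT474,
"S") HER2+ breast-cancer cell line profiled over a matched time course —
can differ not only in which genes change *level*, but in which genes
change *together*. Differential co-expression asks, for every gene pair,
whether the correlation between the two genes differs between conditions.
Pairs that do are assembled into a differential network, the network is
clustered into modules, and within each module the genes carrying the most
differential co-expression (hubs) are ranked.

## The statistic

For each condition $c \in \{R, S\}$, the Pearson correlation $r_c$ of each
gene pair is computed across that condition's $n_c$ samples, pooling
replicates and time points, and variance-stabilized by Fisher's transform

$$ z_c = \tfrac{1}{2}\,\log\frac{1 + r_c}{1 - r_c}, $$

under which $z_c$ is approximately normal with variance $1/(n_c - 3)$.
The per-pair difference statistic is

$$ \delta = \frac{z_R - z_S}{\sqrt{\dfrac{1}{n_R - 3} + \dfrac{1}{n_S - 3}}}, $$

approximately standard normal for a null pair. $\delta > 0$ means the pair
is more strongly correlated in condition R; the statistic is antisymmetric
under swapping the conditions. Both sample counts must exceed 3 or the
variance term is undefined — with the study design of 2 replicates × 3
time points, $n_R = n_S = 6$ and the denominator is $\sqrt{2/3}$.

Two-sided normal p-values are reported alongside, but edge selection uses
the **local false discovery rate**: the posterior probability that a pair
is null given its statistic, estimated from the two-group mixture
$f(x) = \eta_0 f_0(x) + (1 - \eta_0) f_1(x)$ on the magnitude scale
$x = |\delta|$. The components are estimated as follows:

* $f$, the marginal density of $|\delta|$, by the Grenander estimator —
  the slopes of the least concave majorant of the empirical CDF, the
  maximum-likelihood monotone-decreasing density. It is tail-robust:
  no bandwidth, no parametric tail.
* $f_0$, the null density, as a half-normal whose scale is fit by
  truncated maximum likelihood on the central portion of the data (below
  the 0.75 quantile of $|\delta|$). Fitting the null scale empirically,
  rather than pinning it at 1, keeps the procedure calibrated when the
  theoretical variance $1/(n-3)$ is only approximate — which it is at
  $n = 6$.
* $\eta_0$, the null proportion, as the fraction of statistics in the
  central region divided by the null probability of that region, capped
  at 1.

The ratio $\eta_0 f_0 / f$ is clipped to $[0, 1]$ and made monotone
non-increasing in $|\delta|$ by least-squares isotonic adjustment, so more
extreme statistics never receive a larger lfdr. Edges with
$\mathrm{lfdr} < 0.05$ (strict) are significant. A p-value input mode
(uniform null on $[0,1]$) is available behind the `lfdr_input` flag; the
statistic-input mode is the default because the empirical null then also
absorbs scale misspecification. If every $\delta$ is identical (e.g. the
two conditions received the same matrix) there is no evidence anywhere and
every lfdr is set to 1 rather than fitting a degenerate mixture.

## From edges to modules and hubs

The full $|\delta|$ matrix is scaled to $[0,1]$ by its maximum
(diagonal forced to 0) — the adjacency on which the **topological overlap
measure** is computed:

$$ \mathrm{TOM}_{ij} = \frac{\sum_u A_{iu} A_{uj} + A_{ij}}
   {\min(k_i, k_j) + 1 - A_{ij}}, \qquad k_i = \sum_u A_{iu}, $$

with $\mathrm{TOM}_{ii} = 1$: a pair's similarity includes the weight of
its shared neighbours, which makes the clustering robust to single noisy
edges. Genes are clustered by average-linkage hierarchical clustering of
$1 - \mathrm{TOM}$. The default cut slices the dendrogram at the 0.99
quantile of its merge heights — a hybrid-style branch cut that separates
the few high merges joining genuinely distinct branches from the many low
within-branch merges — and clusters smaller than `min_module_size`
(default 20) are left unassigned (label 0). A fixed-$k$ cut is available
via `method = "fixed_k"`. Genes with zero total overlap are unassigned
before clustering, and the pipeline additionally unassigns any cluster
containing no significant intramodular edge: a module of a *differential*
network must carry differential signal. Modules are renumbered by
decreasing size (ties by lowest gene index), so module 1 — "turquoise" in
the size-rank colour convention — is always the largest.

Hubs are ranked by **signed intramodular connectivity**: with edge weights
$w \in [-1, 1]$ (by default the signed scaled statistic
$\mathrm{sign}(\delta)\,|\delta|/\max|\delta|$; optionally the clipped raw
correlation difference $r_R - r_S$ via `weight_mode = "r_diff"`), a node
$u$ in module $M$ scores

$$ \mathrm{kWithin}(u) = \mathrm{conn}^+(u) - \mathrm{conn}^-(u), $$

the sum of its positive significant intramodular edge weights minus the
absolute sum of its negative ones. This is a degree-like quantity for
weighted signed networks (soft connectivity at power 1): a high kWithin
marks a gene whose module-mates co-vary with it much more tightly in
condition R than in S.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` plants correlation modules with a single-factor
Gaussian design: within module $m$ in condition $c$, gene $g$'s expression
is

$$ x_g = \mu + \sigma\left(\sqrt{\rho_{c,m}}\, f_m +
   \sqrt{1 - \rho_{c,m}}\,\varepsilon_g\right), $$

with $f_m$ and $\varepsilon_g$ independent standard normals, so the
expected within-module correlation is exactly $\rho_{c,m}$ — an
analytically known truth that recovery tests can score against (we verify
the realized mean within-module correlation lands within ±0.05 of its
target at $n = 200$). Background genes are independent noise. Defaults
mirror the study design: 6 samples per condition (2 replicates × 3 time
points, treated as exchangeable — the method itself pools across time, so
the generator does not model temporal autocorrelation), values on a
variance-stabilized-like scale (mean 8, sd 1; the scale is irrelevant to
Pearson correlation). The generator does **not** emulate the
negative-binomial count layer or a vst fit, mean–variance coupling,
heavy-tailed expression, or overlapping modules. Passing the recovery
tests therefore demonstrates that the machinery is correct under its own
assumptions, not that real RNAseq data satisfy those assumptions.

Two sample-size regimes are deliberately distinguished. *Calibration*
runs use the study's $n = 6$: with 200 independent genes per condition,
the median fraction of significant edges across 25 replicates is at most
0.01 (empirically ~1.5×10⁻⁴) and the estimated null proportion is ≥ 0.95.
*Recovery* runs use $n = 50$: at $n = 6$ a correlation estimate has too
much sampling noise for any method to recover modules deterministically,
so method correctness and study power are tested separately. The planted
design used throughout (3 modules × 40 genes, $\rho_R = 0.8$,
$\rho_S = 0$, no background, 10 seeds) is recovered with adjusted Rand
index 1 in 10/10 seeds, with every significant edge carrying sign +1
(higher correlation in R), as planted.

## Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `lfdr_threshold` | 0.05 | strict cutoff on the posterior null probability per edge |
| `min_module_size` | 20 | smallest cluster reported as a module; conventional for co-expression modules |
| `cut_quantile` | 0.99 | dendrogram cut at this quantile of merge heights |
| `weight_mode` | `"scaled_delta"` | kWithin edge weights; `"r_diff"` uses $r_R - r_S$ clipped to $[-1,1]$ |
| `lfdr_input` | `"delta"` | feed statistics (empirical half-normal null) or p-values (uniform null) to the lfdr |
| `cluster_all_genes` | `TRUE` | cluster every analyzed gene, or only the nodes carrying a significant edge |
| `min_confidence` | 0.85 | strict lower bound for interaction-network edges (0–1000 scores auto-rescaled) |

## Numerical and design choices

* **Pearson, not Spearman**: the Fisher-z normal theory underlying
  $\delta$ is exact for Pearson correlation of Gaussian data.
* **Clipping**: $|r| \ge 1$ (duplicate genes, float overshoot) is clipped
  to magnitude $1 - 10^{-15}$ before the transform, with a warning, never
  an error; zero-variance genes are rejected earlier, by name.
* **lfdr on statistics, not p-values, by default**: the estimator admits
  both conventions; statistic input lets the empirical null absorb
  variance misspecification at small $n$. Both modes are exposed.
* **Clustering all analyzed genes** (not only significant-edge nodes) is
  the default, since TOM is defined on the full scaled matrix; the
  reported node count still refers to genes with ≥ 1 significant edge.
  `cluster_all_genes = FALSE` gives the other ordering.
* **Determinism everywhere**: one seed drives all generation; clustering,
  labelling and exports break ties by fixed rules (lexicographic gene
  order, lowest member index, size rank), so a rerun of the same
  configuration is byte-identical, and table floats are written at 6
  significant digits to keep files stable.
* **"At least half"** in the count filter is a non-strict comparison:
  a gene present in exactly half the samples is retained.
* **Marker matching** is exact string matching after uppercasing and
  trimming; duplicate identifiers are an error rather than silently
  collapsed.
* **Test problem sizes**: oracle suites run exhaustively on all weighted
  graphs with ≤ 4 nodes and weights in {0, 0.5, 1} plus a fixed-seed
  subsample of 5-node graphs; calibration uses 200 genes × 25 seeds;
  recovery 120 genes × 10 seeds — sizes chosen so the full suite runs in
  well under a minute-scale budget while keeping every estimate stable.

## Known limitations

* With $n = 6$ per condition the method has limited power per edge; the
  lfdr machinery is calibrated there, but recovering planted structure
  reliably needs larger $n$ (or, on real data, strong effects across many
  pairs).
* The normal reference for $\delta$ assumes approximately Gaussian
  expression within condition; heavy tails inflate the empirical null
  scale and cost power (by design, rather than costing calibration).
* The Grenander marginal density is monotone on the magnitude scale; a
  bimodal alternative far from zero is handled, but structure *below* the
  null scale is invisible.
* Modules are hard partitions; no eigengenes, module preservation
  statistics or enrichment are computed here.
* The quantile-based branch cut is a deliberate simplification of full
  dynamic tree cutting; `method = "fixed_k"` is the escape hatch when the
  dendrogram's height profile is unusual.

## A compact worked example

```{r example}
spec <- synthetic_spec(120, module_sizes = c(40, 40, 40),
                       rho_R = c(0.8, 0.8, 0.8), rho_S = c(0, 0, 0),
                       n_samples_R = 50, n_samples_S = 50, seed = 11)
sim <- generate_expression_pair(spec)
edges <- build_edge_table(correlation_matrix(sim$expr_R, "R"),
                          correlation_matrix(sim$expr_S, "S"))
net <- differential_network(edges)
net
assignment <- detect_modules(topological_overlap(net$adjacency))
assignment <- signed_connectivity(edges, assignment)
table(assignment$module)
hub_nodes(assignment, 5, module = 1)
```
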