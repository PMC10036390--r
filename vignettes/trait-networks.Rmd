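---
title: "Trait networks from significance-thresholded correlations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait networks from significance-thresholded correlations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitnet)
library(dplyr)
```

## The model

A plant trait network (PTN) treats functional traits as nodes and
statistically supported pairwise trait correlations as edges.  Given a
matrix of individuals by traits within one population (here: one water
body), every pair of traits gets a Pearson product-moment correlation $r$
and a two-sided p-value from

$$ t = r\sqrt{\frac{n-2}{1-r^2}} \quad \text{on } n-2 \text{ df,} $$

where $n$ is the number of pairwise-complete individuals.  The adjacency
rule is deliberately crude: $a_{ij} = 1$ if $p_{ij} < \alpha$ (default
$\alpha = 0.05$), else 0.  Sign and magnitude of $r$ are discarded — the
network records only the presence or absence of a supported correlation,
so a strong negative trade-off and a strong positive co-optimization are
both edges.  Under a null of mutually independent traits, the expected
edge density equals $\alpha$ exactly; this type-I property is what the
acceptance simulation checks.

Node-level descriptors:

* **degree** $k$ — number of neighbours; high-$k$ traits are *hub traits*,
  interpreted as central to whole-plant phenotypic coordination;
* **closeness** $C$ — the reciprocal of the *mean* shortest-path length
  from the focal trait to the traits it can reach.  Note the convention:
  most graph libraries return the reciprocal of the *sum*, smaller by a
  factor of $n-1$ on a connected graph.  `node_metrics()` follows the
  reciprocal-mean definition; the test suite pins the conversion against
  igraph.  Isolated nodes get $C = 0$;
* **betweenness** $B$ — the number of shortest paths between other trait
  pairs passing through the focal trait, with fractional credit when
  several shortest paths tie and endpoints excluded (Brandes'
  accumulation).  High-$B$ traits are *mediator traits*, bridging
  otherwise separate trait modules.

Network-level descriptors: edge density $ED = 2|E|/(n(n-1))$; average path
length $AL$, the mean shortest-path length over connected unordered pairs;
average clustering coefficient $AC$, the mean over nodes of
$2T_i/(k_i(k_i-1))$ with 0 for $k_i < 2$; and modularity

$$ Q = \sum_c \left( \frac{e_c}{m} - \left(\frac{d_c}{2m}\right)^2 \right) $$

of the detected module partition ($e_c$ edges inside module $c$, $d_c$ its
total degree, $m$ all edges).  $Q$ of the everything-in-one-module
partition is exactly 0, which makes 0 the natural reference when asking
whether detected structure is real.

## Numerical and algorithmic choices

* **Thresholding** uses a strict inequality $p < \alpha$; ties at exactly
  $\alpha$ are measure-zero for continuous data.  No multiple-testing
  correction is applied by default because the method binarizes raw
  p-values; `build_network(adjust = "BH")` and friends are available, and
  the suite checks a correction can only remove edges.
* **Missing data** are handled pairwise-complete: each correlation uses
  the rows complete for that pair, and its p-value uses that pair's own
  $n$.  Pairs with a constant trait or $n < 3$ are flagged undefined and
  never become edges.
* **Disconnected graphs**: $AL$ averages over connected pairs only (the
  convention is recorded here because sparse thresholded networks do
  disconnect); closeness is computed within components; an empty network
  reports $ED = 0$, $AL$ undefined (`NA`), $AC = 0$, $Q = 0$ with one
  module per node.
* **Shortest paths** are breadth-first (edges are unweighted by
  construction); betweenness uses Brandes' exact algorithm.  Both are
  validated to 1e-9 against exhaustive brute-force oracles
  (Floyd–Warshall, full simple-path enumeration) on hundreds of random
  graphs with $n \le 8$, and against igraph.
* **Community detection** defaults to a deterministic greedy agglomerative
  modularity maximisation written in this package: start from singleton
  modules, repeatedly merge the connected pair of modules with the
  largest $\Delta Q$ (ties broken by smallest module index), and keep the
  partition with the highest $Q$ along the merge path.  Merging
  disconnected modules can never increase $Q$, so those merges are
  skipped.  Leading-eigenvector and Louvain (fixed seed) are available
  via igraph for sensitivity analysis; detected module *counts* are
  algorithm-dependent and are always reported next to $Q$ rather than
  asserted.
* **Hub/mediator ranking**: hubs by $(k, C)$ descending, mediators by $B$
  descending, ties broken alphabetically and flagged.  The mediator role
  follows the betweenness definition (bridging), not degree.

## Trait variability

The coefficient of variation is the sample standard deviation ($n-1$
denominator) over the mean, reported as a dimensionless ratio, not a
percentage — rankings are unaffected by the convention.  CVs with zero
mean or fewer than two values are flagged and excluded from group means
with a warning, never silently zeroed.  Two ranking conventions exist
because pooling is ambiguous when groups differ in location: the default
ranks traits by the mean of their per-group CVs; `mode = "pooled"`
recomputes CVs on all individuals pooled.  CV and correlations are
computed on untransformed trait values; log/sqrt transforms matter for
ANOVA normality, which is outside this package's scope.

The light extinction coefficient $K = (1/d)\,\ln(I_0/I_d)$ (per metre) is
provided for PAR profiles; it assumes exponential attenuation, under
which $K$ over stacked layers is the depth-weighted mean of per-layer
coefficients (a property the suite asserts).

## Linking topology to trait variability and environment

Simple linear regressions relate node metrics to per-trait CV and global
topology metrics to group mean CV; slopes with $p \ge 0.05$ are flagged
nonsignificant (the dashed-line convention).  Environmental screening
computes Pearson $r$ with two-sided p-values between each topology metric
and each environmental variable across water bodies and selects variables
at $\alpha$; `backward_regression()` then fits OLS on the selected set
and repeatedly drops the predictor with the largest p-value above
`p_remove` (default 0.10, configurable) until all survivors are below it
or one predictor remains — the univariate case collapses to simple
regression.  Elimination is by coefficient p-value (equivalent to
F-to-remove for a single term); the full elimination trace is kept so a
variable that screened as significant but fell out of the multiple model
remains visible.  With seven water bodies and two predictors the fits are
honest but fragile; the package warns below five observations per
predictor rather than refusing, matching field practice.

Choosing `p_remove` matters when the candidate set contains irrelevant
variables: a pure-noise predictor survives elimination with probability
roughly `p_remove` regardless of how small the residual noise is, so a
model-recovery experiment that requires *all* decoys gone in at least
95% of replicates must use a threshold with `k * p_remove` well under
0.05.  The recovery experiment in the test suite therefore runs at
`p_remove = 0.001` with two decoys; the package default stays at 0.10
for exploratory use.

## What the synthetic generator emulates — and what it does not

`synthetic_config()`/`generate()` emulate the sampling design the
pipeline targets: 7 water bodies, 30 individuals each, 18 traits (the
standard abbreviations H, SB, ..., LMF).  Within each water body,
individuals are drawn from a multivariate normal with a block correlation
matrix: $\rho_{in}$ within planted modules (default 3 balanced modules)
and $\rho_{out}$ between (default 0.05).  The environmental table carries
a TP-like gradient spanning 0.014–0.055 mg/L — the range typical of the
mesotrophic impounded-lake systems this analysis is aimed at — and a DO
gradient from 12 down to 6 mg/L, each with per-group scatter (`tp_sd` =
0.004, `do_sd` = 0.5 mg/L) so the two variables are correlated but not
collinear.  When `rho_in` is not given explicitly it is an exact linear
function of the realised TP (0.35 at the low end to 0.75 at the high
end), so tight-versus-loose network topology is linked to the environment
by construction and the screening/regression stage has a recoverable
truth.  Per-trait CVs are hit by shifting means at fixed unit variance
($\mu_j = 1/\text{CV}_j$), which leaves all correlations untouched; the
default targets span 0.9 down to 0.15, ordered so that stem-branch and
organ-mass traits are the most variable and leaf width the least, the
ordering observed in field populations of *Potamogeton crispus*.  Block
positive-semi-definiteness is validated before sampling, and every draw
is reproducible from the mandatory seed.

Deliberate simplifications: trait marginals are Gaussian (field traits
are often right-skewed; Pearson r is what the analysis consumes, so the
copula does not matter for the network stage); within-module correlation
is compound-symmetric rather than a richer factor structure; environments
are independent across groups with no spatial autocorrelation; no
ontogenetic or within-site structure.  Consequently, passing tests show
the *pipeline* is correct and the *statistical properties* (type-I edge
rate, module recovery, regression recovery, monotone tightening with
$\rho_{in}$) hold under the stated generative model — they do not certify
behaviour under skewed marginals, outliers or spatially structured
sampling.

One consequence of compound symmetry worth knowing: at $\rho_{in} = 0.9$
each module behaves almost like a single latent factor, so all
between-module sample correlations rise and fall together with the two
factors' sample correlation.  In roughly the fraction $\alpha$ of
30-individual replicates that factor correlation crosses the significance
threshold and the whole bipartite edge set appears at once, giving a
near-complete network whose maximum-modularity partition is genuinely the
single module with $Q = 0$.  Community detection recovering "no
structure" there is correct behaviour, not failure.

## Problem sizes used in the shipped checks

The test suite validates graph metrics on 200+ random graphs with up to 8
nodes against brute-force oracles, runs 500 null replicates of the 18 ×
30 type-I simulation, 100 module-recovery replicates, 100 regression
recovery replicates, and a 7-level $\rho_{in}$ grid with 8 seeds per
level; these sizes give binomial standard errors comfortably inside the
asserted tolerances while the whole suite runs in well under a minute on
a laptop core.

## Known limitations

* Raw p-value thresholding makes edge count grow with sample size; dense
  networks from large $n$ are a feature of the method, not of the biology.
* Greedy modularity maximisation has the usual resolution limit; module
  counts should be read comparatively, not absolutely.
* With 7 groups, screening and regression p-values are fragile; treat the
  selected-variable set as descriptive.
* The pipeline assumes one network per group label; finer structure
  (e.g. sites within water bodies) must be encoded in the group column by
  the user.
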