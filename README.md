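# traitnet

Plant trait networks (PTNs) for population ecology: from a matrix of
individual plants × functional traits, grouped by water body (or any
population label), **traitnet** builds significance-thresholded
correlation networks, computes their topology, identifies hub and
mediator traits, quantifies trait variability, and links network
topology to environmental drivers.

The core object is an undirected binary graph whose nodes are traits and
whose edges mark supported pairwise correlations: for each trait pair,
Pearson's *r* and a two-sided p-value from *t* = *r*·√((*n*−2)/(1−*r*²))
on *n*−2 df; the adjacency is *a₍ᵢⱼ₎* = 1 iff *p* < α (default 0.05),
with sign and magnitude discarded. On that graph the package computes,
from first principles, degree *k*, closeness *C* (reciprocal of the
**mean** shortest path — not the reciprocal-sum convention of most graph
libraries), betweenness *B* (Brandes, fractional credit across tied
paths), edge density *ED*, average path length *AL*, average clustering
coefficient *AC*, and Newman modularity *Q* under deterministic greedy
community detection. High-(*k*, *C*) traits are hubs; high-*B* traits are
mediators. Trait variability is summarised as the coefficient of
variation (sd/mean), and topology metrics are regressed on environmental
variables via Pearson screening followed by backward multiple regression
(p-value elimination, default `p_remove = 0.10`).

A seeded synthetic-data module generates trait matrices with planted
correlation modules on an environmental gradient (TP-like and DO-like
variables), so the whole pipeline is testable end-to-end without field
data.

## Worked example

```r
library(traitnet)
library(dplyr)

ds   <- generate(synthetic_config(seed = 42))   # 7 water bodies x 30 x 18
nets <- networks_by_group(ds$traits, "group", alpha = 0.05)
topo <- topology_by_group(nets)
topo %>% select(group, n_edges, edge_density, avg_path_length,
                avg_clustering, modularity, n_modules)
#> # A tibble: 7 × 7
#>   group n_edges edge_density avg_path_length avg_clustering modularity n_modules
#> 1 WB1        38        0.248            2.48          0.696      0.575         3
#> 2 WB2        37        0.242            2.90          0.544      0.464         3
#> 3 WB3        51        0.333            2.04          0.750      0.488         3
#> 4 WB4        48        0.314            2.42          0.811      0.562         3
#> 5 WB5        44        0.288            1.02          0.978      0.666         3
#> 6 WB6        60        0.392            1.91          0.788      0.395         3
#> 7 WB7        63        0.412            2.03          0.888      0.375         3
```

Edge density rises and networks tighten along the planted
total-phosphorus gradient (WB1 low TP → WB7 high TP). Hub and mediator
traits for one water body:

```r
identify_hubs(node_metrics(nets[["WB7"]]), top_n = 3)
#>   role      rank trait degree closeness betweenness tied
#> 1 hub          1 LA        11     0.630        14.7 TRUE
#> 2 hub          2 ND        11     0.630        14.7 TRUE
#> 3 hub          3 NN        11     0.630        14.7 TRUE
#> 4 mediator     1 LW         9     0.68         66   FALSE
#> 5 mediator     2 DSW        6     0.531        24   TRUE
#> 6 mediator     3 SMF        6     0.531        24   TRUE
```

Screening the topology metrics against the environmental table and
fitting a backward multiple regression:

```r
scr <- screen_environment(topo, ds$env)
filter(scr, selected)
#>   metric         variable      r        p     n selected
#> 1 edge_density   TP        0.877 0.00945      7 TRUE
#> 2 edge_density   DO       -0.954 0.000850     7 TRUE
#> 3 avg_clustering TP        0.770 0.0429       7 TRUE

fit <- backward_regression(inner_join(topo, ds$env, by = "group"),
                           "edge_density", c("TP", "DO"))
equation_text(fit)
#> "edge_density = 0.557 - 0.0258 DO (R2 = 0.91; F = 50.64; P = 0.00085)"
```

So across the seven synthetic water bodies, edge density correlates
positively with TP and negatively with DO, and backward elimination
keeps DO as the stronger predictor — the screening → elimination → final
equation workflow in one pass. `run_pipeline(pipeline_config(...))`
executes all stages (CV tables, per-group networks with edge-list /
adjacency / GraphML exports, node and topology metrics, CV and
environmental regressions) and writes a JSON manifest with checksums; a
thin command-line wrapper with `simulate` / `build-networks` / `metrics`
/ `regress` / `run-all` subcommands ships in `inst/cli/traitnet.R`.

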