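# pathcolor

Signaling-pathway detection in protein–protein interaction (PPI) networks
by topology-aware color-coding and a bounded A\* search.

Candidate linear signaling pathways — simple paths from a membrane
receptor toward a nuclear transcription factor — are modelled as
minimum-weight simple paths of fixed length *l* in a PPI network whose
edges are weighted by gene co-expression:

```
w(u, v) = −log max(|r(u, v)|, ε)
```

where *r* is the Pearson correlation of the two genes' (KNN-imputed)
log2 expression profiles, so strongly co-expressed interactions become
cheap. Finding a minimum-weight *simple* path is NP-hard; color-coding
makes it tractable by assigning each node one of *k = l* colors and
searching only *colorful* paths (all colors pairwise distinct), repeating
over independent colorings until the miss probability is as small as
desired. A fixed *l*-path is colorful with probability *l!/l^l > e^(−l)*
under uniform coloring, so

```
t = ⌈ ln(failure_cap) / ln(1 − e^(−l)) ⌉
```

colorings cap the overall failure rate (8929 colorings for *l* = 8 at a
5% cap). Two ideas sharpen the classic scheme:

* **Topology-aware coloring** — nodes are colored in descending-degree
  order, each avoiding its neighbours' colors; leaves copy their hub's
  color (they can never occupy a path interior), and articulation points
  are recolored to differ from their neighbourhoods. Paths through hubs
  and bottlenecks — exactly where signaling cascades run — stay
  detectable far more often than under uniform coloring.
* **Bounded A\*** — a depth-first branch-and-bound over simple paths
  prunes any partial path whose `f = g + w_min·(l − depth)` exceeds a
  bound `(w_avg + α·w_STD)·l` calibrated from randomly sampled simple
  paths. The heuristic is admissible (no edge weighs less than `w_min`),
  so the search stays exact whenever the bound covers the optimum.
  An optional cellular-location constraint keeps compartment ranks
  (membrane → cytoplasm → nucleus) non-decreasing along the path.

The package is aimed at systems-biology analyses that integrate a PPI
edge list with a gene-expression matrix; everything needed to exercise it
without external databases — scale-free networks, planted
high-correlation paths, location tags — ships in the synthetic-data
generator.

## Worked example

```r
library(pathcolor)

# a 60-node scale-free network with a planted 7-protein pathway:
# co-expression |r| ≈ 0.9 along the path, noise elsewhere
inst <- synthetic_instance(n = 60, l = 7, seed = 42)

stats <- sample_path_stats(inst$net, l = 7, n_samples = 1000, seed = 1)
stats
#> <pc_path_stats> l = 7, n = 1000: w_min = 0.09146, w_avg = 3.197, w_std = 1.379

cfg <- search_config(l = 7, d = 3, alpha = 0.5)
res <- search_with_restarts(inst$net, s = inst$path[1], t = inst$path[7],
                            config = cfg, n_colorings = 500, seed = 7,
                            locations = inst$locations, stats = stats)
tidy(res)
#> # A tibble: 2 × 6
#>    rank weight length colorful location_valid path
#>   <int>  <dbl>  <int> <lgl>    <lgl>          <chr>
#> 1     1  0.622      7 TRUE     TRUE           P056 -> P008 -> P013 -> P049 -> P042 -> P017 -> P018
#> 2     2 18.1        7 TRUE     TRUE           P056 -> P019 -> P001 -> P015 -> P005 -> P039 -> P018

precision_recall_f(unique(unlist(res$nodes)), inst$path)
#> # A tibble: 1 × 6
#>   precision recall f_measure n_detected n_reference n_hit
#>       <dbl>  <dbl>     <dbl>      <int>       <int> <int>
#> 1     0.583      1     0.737         12           7     7
```

The rank-1 path (weight 0.622, the sum of its −log |r| edge weights) is
exactly the planted pathway: its edges carry |r| ≈ 0.9, so each
contributes only ≈ 0.1, while paths through noise genes cost an order of
magnitude more. Recall 1 means every planted protein was recovered; the
second-ranked path drags precision below 1 by adding noise proteins.

`run_pipeline("config.yml")` drives the same chain — expression
filtering/imputation, network weighting, coloring, search, evaluation —
from a YAML config and writes TSV results plus a JSON manifest;
`inst/cli/pathcolor.R` wraps it for the shell. Small synthetic demo
inputs live in `inst/extdata/` (all generated by the package's own
generator).

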