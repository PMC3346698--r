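---
title: "Pathway detection by topology-aware color-coding and bounded A* search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway detection by topology-aware color-coding and bounded A* search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcolor)
```

## The model

A linear signaling pathway is modelled as a simple path of fixed length
*l* (counted in nodes) in an undirected PPI network, running from a
start protein (typically membrane-located) to an end protein (typically
nuclear). Each edge carries weight

$$w(u,v) = -\log\max(|r_{uv}|, \varepsilon),$$

with $r_{uv}$ the Pearson correlation of the two genes' log2 expression
ratios over the samples. The absolute value treats strong inhibition as
evidence of interaction on par with strong activation; the negative
logarithm makes path weight additive, so the most co-expressed chain of
interactions is the minimum-weight path. The working assumption is the
standard co-expression argument: proteins acting in one cascade tend to
be transcribed together, so true pathway edges are systematically
cheaper than background edges. Where that assumption fails (e.g.
post-translationally regulated steps), the corresponding edge is
penalised like any other uncorrelated interaction.

Finding a minimum-weight *simple* path of length *l* is NP-hard.
Color-coding randomises the problem: color every node with one of
$k = l$ colors and search only *colorful* paths (all colors distinct),
which are necessarily simple. A fixed $l$-path is colorful under uniform
coloring with probability $l!/l^l > e^{-l}$, so

$$t = \left\lceil \frac{\ln(\text{failure cap})}{\ln(1 - e^{-l})} \right\rceil$$

independent colorings bound the overall miss probability;
`required_repetitions(8, 0.05)` gives 8929.

## Expression preprocessing

Genes with a missing-value fraction of 0.2 or more are removed (the
threshold is strict: a gene missing exactly 20% of entries is dropped).
Remaining holes are filled by K-nearest-neighbour imputation: candidate
neighbours are ranked by mean squared difference over mutually observed
samples (normalising by the shared-sample count keeps genes with
different overlap comparable — the classic KNN-impute papers leave this
open and we prefer comparability), and the missing cell becomes the
unweighted mean of the `k` nearest genes observed at that sample. The
default `k = 15` sits where the deletion-experiment RMSE curve
(`imputation_rmse_curve()`) typically bottoms out on matrices with
roughly 20% missingness; a distance-weighted mean exists behind the
`weighted` flag but is off by default, since with small `k` the weights
mostly add variance. Ties in neighbour distance break by gene id so the
imputation is fully deterministic.

The over/under expression call compares the summed magnitude of positive
log2 ratios against the summed magnitude of negative ones. The raw
counts of up/down samples are an alternative reading; magnitude sums are
robust to many small opposite-sign fluctuations around zero, which
two-channel ratios produce in abundance, so that is the default and only
mode. Ties fall to "under".

## Network weighting choices

* **Log base.** Natural log by default. The base rescales every weight
  by the same factor and cannot change any argmin path; base 10 is
  available for readers who prefer those units.
* **Correlation floor.** $\varepsilon = 10^{-4}$ caps the weight of
  uncorrelated or undefined pairs at $-\ln\varepsilon \approx 9.21$.
  Without a floor, a single $r = 0$ edge would get infinite weight and
  silently delete itself from the search.
* **Edges without expression support** keep the cap weight rather than
  being deleted. Deleting them would change the articulation structure
  the coloring relies on; the cap already makes them maximally
  unattractive. A `drop_unmatched` flag provides the deletion variant.
* **Undefined correlations** (fewer than 3 shared samples, zero
  variance) are reported as `NA` — an explicit signal distinct from 0 —
  and weighted at the cap.

## The search length

`longest_shortest_path()` returns the hop diameter of the largest
connected component — edge weights are deliberately ignored, since the
quantity bounds path length in *hops*. It is the default search length
and color count: in a small-world network no pair sits farther apart, so
no longer search is ever needed. On disconnected networks the largest
component decides; including infinite cross-component distances would
make the quantity undefined, and searches never cross components anyway.

## Topology-aware coloring

Nodes are processed in descending-degree order (ties broken by node id):
each receives a color drawn uniformly among those unused by its
already-colored neighbours, falling back to a uniform draw over all *k*
when the neighbourhood exhausts the palette. Two refinements encode the
biology of scale-free networks:

* **Leaves** (degree 1) copy their neighbour's color. A leaf can only
  ever be a path endpoint, never an interior node, so spending a color
  on it is wasted budget. A `strict_leaf` mode forces leaves to differ
  instead, for users who want uniform-style guarantees; the copying mode
  is the default.
* **Articulation points** are recolored after the main pass whenever
  they collide with a neighbour and a free color exists. Every path
  between the components they separate must pass through them, so a
  collision there blocks whole families of paths. In the default
  leaf-copying mode this collision check ignores degree-1 neighbours —
  leaves intentionally share their hub's color, and a hub with leaves is
  automatically an articulation point, so checking leaves would undo the
  leaf rule.

The recoloring pass runs exactly once, after all nodes are colored.
`coloring_report()` counts residual hub/articulation collisions; with
$k$ exceeding an articulation point's degree the pass always finds a
free color, so its violation count is zero. The practical effect is
measured by `success_rate()`: on Barabási–Albert graphs the
topology-aware colorful-path success rate dominates uniform coloring's
(in the test suite: 500 paired colorings, $n = 300$, $l \in \{7, 8\}$;
both rates share start/end draws and coloring seeds trial-by-trial, and
existence is decided exactly by a subset dynamic program rather than by
the weighted search).

## Bound calibration and the A* search

`sample_path_stats()` draws random simple $l$-node paths by self-avoiding
random walk (restarting on dead ends, with an attempt cap) in the
*uncolored* network and pools the traversed edge weights into a mean
$w_{avg}$ and standard deviation $w_{STD}$; the global minimum edge
weight $w_{min}$ comes from the network itself, not the sample, so the
heuristic below is exactly admissible. The pruning bound is

$$\text{Bound} = (w_{avg} + \alpha\, w_{STD}) \cdot l .$$

Multiplying by $l$ (nodes) rather than $l - 1$ (edges) follows the
method's published form; it only loosens the bound, never unsoundly, and
a `per_edge` flag provides the tighter variant. $\alpha$ (default 0.5)
widens the net: larger values admit more suboptimal-but-plausible paths
at higher search cost.

The search itself is depth-first branch-and-bound (implemented in C++):
a partial path of depth $n$ extends only to unvisited neighbours whose
color is unused and whose location rank does not decrease; beyond the
pre-traverse depth $d$ (default 3) a branch dies when
$f = g + w_{min}(l - \text{depth})$ exceeds the bound. Below depth $d$
pruning is off, so short prefixes are explored exhaustively — cheap, and
it protects the search from a bound that is accidentally tight near the
start. Since no edge weighs less than $w_{min}$, $h$ never overestimates
the remaining cost and $f$ never decreases along an expansion; with the
bound at or above the optimum, the returned path is exactly the
brute-force minimum (the test suite checks this equivalence on 100
random graphs). The end node is only admitted at depth $l$, the best
weight found so far tightens the effective bound, and weight ties
resolve to the lexicographically smallest node sequence, making every
search deterministic given the coloring.

Location ranks are membrane = 1, cytoplasm = 2, nucleus = 3;
"intracellular" and unannotated proteins are wildcards compatible with
any rank (the four published compartments carry no total order that
includes "intracellular", so treating it as a constraint would invent
information). The monotonicity check tracks the last non-wildcard rank.

`search_with_restarts()` repeats coloring + search with seeds derived
from one master seed; its default repetition count is
`required_repetitions(l, 0.05)` — the uniform-coloring guarantee, which
the topology-aware scheme only improves on. Path statistics are sampled
once per network and length and passed in, rather than per query: the
statistics depend only on $(G, l)$, and resampling per query would just
add variance.

## The synthetic generator

`synthetic_instance()` builds the study conditions end to end: a
connected preferential-attachment network (`sample_pa`, attachment 2 —
the sparse regime typical of curated PPI subnetworks), a planted
$l$-node path tagged membrane → cytoplasm → nucleus, and an expression
matrix in which planted genes load on one shared latent factor with
loading $\lambda$ solving $\lambda^2 / (\lambda^2 + \sigma^2) = r_{on}$
(default $r_{on} = 0.9$, 200 samples), while all other genes are
independent noise of equal marginal variance.

One generator subtlety matters: under the latent-factor model *every*
planted pair correlates at $r_{on}$, not just consecutive ones, so a
chord between planted nodes would create alternative orderings of the
same node set at nearly equal weight. `plant_path()` therefore samples
candidate node sets until the chosen set has no pre-existing internal
edges (with a retry cap, then fewest-chords). With that in place the
planted path is the unique minimum-weight $l$-path with high
probability, which underwrites the recovery tests: 20 independent
instances ($n = 60$, $l = 7$, $r_{on} = 0.9$) are searched with the
prescribed `required_repetitions(7, 0.05) = 3285` colorings each, and
the planted path must rank first in at least 90% of them.

What the generator does *not* emulate: microarray dye bias, batch
effects, heavy-tailed noise, correlated missingness, or the
database-integration noise of real PPI compendia. Passing tests
demonstrate algorithmic correctness and the statistical behaviour of the
method under its own model assumptions — not performance on any real
organism's data.

## Problem sizes and numerical choices

The test suite runs at desk scale, chosen so each property is decisive
but cheap: oracle-equivalence sweeps use 100 random graphs of at most 12
nodes (where exhaustive enumeration is exact), recovery uses
$n = 60$ / 20 instances, the coloring comparison uses $n = 300$ with 500
paired colorings, and the colorful-law check uses 10,000 colorings of a
7-path. Floating-point ties in the search compare within $10^{-9}$;
seeds derived from a master seed stay below $2^{31}$. Degenerate inputs
follow explicit conventions documented on each function: empty filter
results warn rather than error, a gene with no observed values is an
error, zero-variance correlations are `NA`, and an empty result list
from the search is a valid outcome.

## Known limitations

* Enrichment scoring is the plain term-by-term hypergeometric test with
  Bonferroni correction. Parent–child-style corrections need the GO DAG,
  which is out of scope; export the gene sets and run a dedicated
  enrichment tool for publication-grade statistics.
* Paths are linear only; tree-shaped queries and edge orientation are
  not modelled.
* The bound is calibrated from sampled paths between arbitrary
  endpoints; for very atypical start/end pairs a larger $\alpha$ may be
  needed before the optimum falls under the bound.
* Uniform-coloring repetition counts are conservative for the
  topology-aware scheme; there is no closed form for its (higher)
  per-trial success probability, so the guarantee is inherited from the
  uniform bound.
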