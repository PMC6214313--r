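---
title: "Ranking critical habitat patches by cut-node analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking critical habitat patches by cut-node analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corridorcut)
```

## The problem

Ecological landscape networks connect nature-protection areas through
corridors of habitat patches, so that populations of protected species can
migrate and mix their genetic pools. When each homogeneous land patch is a
node and spatial adjacency is an edge, a corridor set becomes an undirected
graph, and the patches whose loss would interrupt a corridor are exactly the
graph's *cut nodes* (articulation points): nodes whose removal splits their
connected component.

Cut-node detection alone is not a useful priority list. Corridor graphs are
chains by construction, so cut nodes are abundant (in the case-study network
shipped with this package, 569 of 6995 patches, about 8.13%), and land-cover
maps contain many *enclaves* — patches topologically surrounded by another
patch, which appear as leaf nodes and turn every surrounding patch into a
cut node even though no corridor is interrupted. `corridorcut` implements a
ranking method that separates the important cut nodes from this noise.

## Fragmentation metrics

For a cut node $v$ in a connected component $G' = (V', E')$, removal splits
$G'$ into $n \ge 2$ components $G'_k = (V'_k, E'_k)$, indexed so that
$|V'_0| \ge |V'_1| \ge \dots \ge |V'_{n-1}|$. Two attributes summarise the
damage:

* the **additional component count** $C_A(v) = n - 1$, the number of
  components added to the graph total; and
* the **second-size** $C_S(v) = |V'_1|$, the size of the second-largest
  piece.

$C_S = 1$ means the removal only detaches leaf nodes: under the enclave
interpretation these cut nodes are likely data artifacts, and the ranking
can optionally drop them (`drop_noise = TRUE`; off by default, because a
genuine one-patch stepping stone would be dropped too).

`simulate_removal()` computes one split (the graph is never mutated);
`removal_metrics()` tabulates all cut nodes. Both satisfy the conservation
law $\sum_k |V'_k| = |V'| - 1$, which the test suite checks on every
simulated removal.

## Betweenness comparison

The betweenness centrality
$C_B(v) = \sum_{s \ne v \ne t} \sigma_{st}(v) / \sigma_{st}$ (unweighted,
unordered pairs) is normalised to $[0, 1]$ by the pair count
$(N-1)(N-2)/2$. The graphs this package analyses are disconnected by
construction — one component per candidate corridor — and no shortest path
crosses components, so by default $N$ is the size of the node's *own*
component: the score measures centrality within the corridor. With $N$ taken
from the whole graph, the achievable maximum in a 300-node component of a
7000-node graph would be smaller by roughly three orders of magnitude,
compressing every value toward zero and making the column useless for
comparison; `scope = "global"` is nevertheless available as a sensitivity
check. Components with fewer than three nodes have no eligible pair and
score 0.

Betweenness is deliberately a *comparison* column, not a default component
of the combined score: the package reports the Pearson and Spearman
correlation between the two (`correlation_report()`) so users can verify on
their own data that the composite ranking is not betweenness in disguise.

## Strictly-less percentile scores and the combined score

The raw metrics live on incomparable scales (counts, patch counts, metres),
so a plain sum would be dominated by whichever metric has the largest range.
Each metric is instead converted to a percentile score over the pooled
population of all cut nodes:

$$\mathrm{score}(x) = 100 \cdot
  \frac{\#\{\text{population values} < x\}}{\text{population size}}.$$

The *strictly less* convention matters: the minimum value scores exactly 0
and therefore contributes nothing to the combined score, equal raw values
always get equal scores, and no value reaches 100. Extreme values are
compressed — the largest and second-largest observations differ by at most
one population share — which suits the goal of flagging abnormally high
values without rewarding their magnitude.

The population is pooled across all components, not per component, so that
scores of patches in different corridors are comparable on one map. The
combined score is the sum of the percentile scores of the configured
metrics — by default $C_A$, $C_S$ and the minimum boundary distance $D(v)$
to a protected site — and is computed from *unrounded* percentiles, with
rounding applied only in reports. (Summing percentiles rounded to two
decimals can differ from the rounded exact sum by a unit in the last place;
the shipped case-study table contains such a row.) Ranking is by descending
combined score; exact ties share the better rank position and are ordered by
higher normalised betweenness, then smaller id, so the emitted priority list
is total and deterministic.

```{r worked}
tabs <- cagliari_tables()
d <- metric_distribution(histogram = tabs$component_count_hist)
percentile_score(d, c(1, 2, 5, 35))
```

## Site distances and the spatial front end

$D(v) = \min_{s \in S} d(s, v)$ is the Euclidean distance between patch and
site *boundaries* on projected planar coordinates (a patch touching or
overlapping a site scores 0). Geodesic corrections are out of scope: at
regional scale the projection distortion is negligible relative to patch
size.

The spatial front end derives everything the ranking needs from polygon
layers:

* `overlay_intersection()` intersects corridor cells with land-cover
  patches so patches become homogeneous in land use. Clipping is
  Sutherland–Hodgman, exact when at least one polygon of each intersecting
  pair is convex (either side may play the convex role); two non-convex
  polygons are rejected rather than clipped approximately.
* `polygons_to_graph()` links patches that share a boundary segment of
  positive length (**rook** rule, the default) or any boundary point
  (**queen**). Rook is the default because the source maps never state
  whether corner-touching patches were linked, and a single shared point is
  a spurious corridor: no organism-relevant contiguity passes through a
  corner. The queen edge set always contains the rook edge set.
* `min_site_distance()` computes $D(v)$ by exact segment-to-segment
  distance with containment checks.

Numerical choices: geometry predicates use an absolute coordinate tolerance
of $10^{-9}$ (appropriate for metric CRS units at regional scale), overlay
pieces below $10^{-12}$ area are discarded as degenerate, and a
configurable `min_area` threshold can additionally suppress slivers, which
are a known source of enclave noise in overlaid land-cover data. Geometries
are repaired (consecutive duplicate vertices removed) and validated
(self-intersection, zero area) at layer construction; failures name the
offending feature ids.

GeoJSON is the supported polygon format, read and written with exterior
rings only. The derived graph exports to edge-list CSV and GraphML, and the
ranking joins back onto the layer as GeoJSON properties for map styling.

## The synthetic landscape generator

`generate_corridor_graph()` emulates the topology that corridor
identification produces, so the whole pipeline is testable without GIS
data. Each component is a *backbone* chain of corridor patches with an
*anchor clique* at either end (the patches bordering a protected site;
cliques of at least three nodes are internally biconnected, so articulation
happens at the corridor, not inside the site — mirroring the motivating
landscape). Enclave leaves attach with a fixed probability both to backbone
patches and to non-junction clique members; the latter is essential, because
an enclave whose host also separates the backbone never shows the pure
$C_S = 1$ noise signature — only a host inside a biconnected neighbourhood
does. A per-component *redundant edge* closes the backbone into a cycle,
destroying the articulation of every backbone patch that hosts no enclave.

The generator's defaults (3 components, backbone 8, cliques of 3, enclave
probability 0.25, no redundancy) give cut-node shares and $C_A$/$C_S$
distributions of the same shape as real corridor graphs: $C_A$ mass
concentrated at 1, a long thin tail, and a majority of small second-sizes.
Ground truth (every cut node with its exact $C_A$ and $C_S$) is derived
from the construction arithmetic, not from any graph algorithm, and the
test suite verifies that detection recovers it exactly — with equality, not
mere containment, since the bookkeeping also covers the redundant-edge
case. A single integer seed drives one RNG stream (leaf draws in component
order, then the redundancy draw), so the same spec always reproduces the
same landscape; the caller's RNG state is saved and restored.

`generate_grid_landscape()` produces the polygon analogue: unit-square
corridors between two rectangular sites, with declared rook adjacency and
exact boundary distances, used to validate the spatial adapter end to end.

What the generator does **not** emulate: resistance surfaces, realistic
patch shapes and sizes, spatially autocorrelated land use, or multi-site
topologies with more than two anchors per corridor. Passing tests on
synthetic landscapes therefore demonstrate algorithmic correctness on
corridor-like topologies, not ecological validity of any particular ranking
on real maps.

## Pipeline, determinism and problem sizes

`run_rank()` executes the five stages — build graph, identify components,
find cut nodes and site distances, simulate removals, score and rank — from
a validated `run_config()` (or YAML file; unknown keys are rejected before
any computation, and a requested distance metric without a distance source
fails fast). Reports (`write_reports()`) have fixed column order and
rounding, so identical inputs give byte-identical outputs. The test suite
exercises graphs up to a few hundred nodes and oracle comparisons on 200
random graphs of up to 60 nodes (betweenness up to 40), sizes at which the
independent brute-force oracles stay exact and the whole suite runs in
about a minute.

## Known limitations

* Single-node removal only; the joint effect of removing several cut nodes
  is not modelled.
* Unweighted, undirected adjacency; no functional-connectivity weights.
* Overlay requires one convex polygon per intersecting pair; holes in
  GeoJSON polygons are dropped.
* The distance metric needs a projected CRS; no geodesic mode.
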