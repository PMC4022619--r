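---
title: "Waterhole network connectivity under drought: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Waterhole network connectivity under drought: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aguadas)
```

## The problem

In a karstic upland forest with no rivers, dry-season water exists only in
superficial waterholes. Large mammals — tapirs, white-lipped peccaries,
jaguars — depend on reaching one within their movement range. As drought
removes waterholes in increasing order of size (small ones dry first), the
spatial network of reachable water can collapse abruptly, in a
percolation-like fashion, long before most of the water *area* is gone.
`aguadas` quantifies that collapse. The analysis is deliberately a model of
*potential* connectivity: nodes are waterhole centroids, links are
straight-line distances, and the forested matrix between waterholes is
treated as uniformly traversable (no resistance surface), so results are an
upper bound on realized connectivity.

## The network model

A waterhole layer is a table of centroids (projected metres) with surface
areas `a_i` (m²). All geometry is planar: over a ~30 km extent, geodesic
corrections are far below every other source of error, and the data
originate in a projected GIS. The complete graph links every pair at its
Euclidean centroid distance; a species-specific network keeps links with
`d_ij <= d_max`. A link exactly at `d_max` is *within* the species' movement
ability and is kept — the deletion rule removes links *longer than* the
threshold. Distances are computed once on the complete graph and reused by
every pruning, so sweeps over thresholds are cheap and exactly consistent.

Structural summaries follow the field's conventions: link density
`L = m / (n(n-1)/2)` on the network's own node set (`L = 0` for a single
node), components by transitive closure, and "clusters" counting only
components with at least two waterholes. Isolated nodes remain network
members: they still carry water area (PC self-terms) and habitat.

One reporting subtlety matters when reading scenario trajectories. `L` is
normalized per scenario, so deleting small, peripheral waterholes can
*raise* `L` even as the network collapses — the survivors are fewer but
mutually closer. The drought collapse is therefore carried by the absolute
link count (equivalently, link counts normalized by the *base* scenario),
which is how the sweep results should be compared across scenarios. The
package reports both `n_links` and per-scenario `link_density` in every
sweep record.

## Drought scenarios

The base scenario A keeps waterholes strictly larger than 700 m² (smaller
ones are unreliable and were excluded from the reference model after ground
truthing). Scenarios B–K then remove all waterholes with area less than or
equal to 1,000; 2,500; 5,625; 10,000; 15,625; 22,500; 30,600; 40,000;
50,600; 62,500 m². Boundary conventions are deliberate and tested: the base
filter is strict (`> 700`), the scenario filter inclusive (`<= T` removed);
a waterhole at exactly 40,000 m² is removed by scenario I. Scenario
filtering and distance pruning commute, which the suite asserts on random
instances.

## Connectivity: kernel, max-product paths, PC, dPC

Link dispersal probabilities come from a negative exponential kernel
`p(d) = exp(-k d)`, calibrated per distance threshold by the tail rule: the
probability of moving beyond `d_max` is `tail_prob` (default 0.05), so
`k = -ln(tail_prob)/d_max`, `p(0) = 1`, `p(d_max) = tail_prob`. Probabilities
are only assigned to pruned networks, hence lie in `[tail_prob, 1]`.

Pairwise connection probabilities `p*_ij` are the maximum over paths of the
product of link probabilities, computed exactly as single-source shortest
paths on `-log p` weights (no all-pairs matrix above a few thousand nodes
would be needed; here n is a few hundred). Because the kernel is
multiplicative over summed lengths, `p*_ij = exp(-k * graph-distance(i, j))`
— an identity the tests assert on random instances, and the strongest
internal oracle of the module. Disconnected pairs get 0, the diagonal 1.

The probability-of-connectivity numerator is
`PC = Σ_i Σ_j a_i a_j p*_ij` over ordered pairs (units m⁴). The
landscape-area denominator of the full PC index is omitted deliberately:
with a fixed study area it is a constant rescaling, and raw numerators
compare scenarios directly. Self-pairs (`i = j`, `p* = 1`) are included,
following the standard Conefor-style definition; `include_self = FALSE`
provides the variant without them for sensitivity checks. The source
analysis's verbal definition mentions only component co-membership, so a
component-indicator variant (`p* = 1` within a component) is available via
`mode = "component"`; the max-product definition is the default because it
is the standard one and reduces to the indicator as probabilities approach
1.

Node importance uses patch removal: `dPC_k = 100 (PC - PC_{-k})/PC`,
recomputed from scratch for each removed node (O(n) shortest-path sweeps per
node — exact, and fast at n ≤ a few hundred). Removal can only lose terms,
so `dPC ∈ [0, 100]`; floating-point negatives within 1e-9 are clamped to
zero. Ranks break ties by larger area, then id, so output is deterministic.
`aggregate_importance()` sums dPC across the distance thresholds spanning
the species' movement ranges and re-ranks, mirroring pooled node-importance
maps. Importantly, dPC is *not* monotone in area: a modest waterhole
bridging sub-networks can outrank a much larger, isolated one (the package's
tests construct such a counter-example), which is precisely why the ranking
is computed rather than read off the size distribution.

## Suitable habitat

Habitat is the union of fixed-radius buffers (defaults 1,000 and 2,000 m —
daily-movement scales, below every species' 3 km minimum travel distance)
around each waterhole footprint, clipped to the study boundary before
percentages are computed. When only centroid + area are available, the
footprint is a regular 128-gon circle of radius `sqrt(a/pi)`; at 128
segments the area error is below 0.1%, and the discretization is
configurable. Buffering uses round joins with an arc tolerance of 0.2% of
the radius; polygon unions, intersections and offsets are exact
integer-clipping operations (Clipper via `polyclip`), so union areas are
order-invariant to well below 1e-6 relative. Patch counts are the number of
outer rings of the clipped union; buffers that merely touch merge into one
patch, matching the connectivity reading of overlapping habitat. Tests
validate union areas against Monte-Carlo point sampling (1% tolerance) and
patch counts against an independent disc-overlap graph.

## The synthetic landscape generator

The reference coordinates are unpublished, so the generator emulates the
documented structure of the landscape; all defaults are the study's stated
conditions or, where unstated, fixed choices justified here.

- **Extent and reserve.** 30 km x 25 km = 750 km², with the reserve as a
  western strip covering 35% of the extent (the documented share is 30–40%).
- **Sizes.** Truncated Pareto on [700, 172,500] m². The exponent is solved
  at run time (`calibrate_size_exponent()`, alpha ≈ 0.727) so that
  `P(area <= 2500) = 115/187`, the documented small-waterhole share. The
  size-frequency histogram then falls as a power law on log-log axes
  (median R² > 0.5 across seeds, matching the reported R² = 0.64
  qualitatively).
- **Placement.** A Thomas-style parent–offspring process: 15 uniform
  parents, isotropic Gaussian offspring (sd 2,500 m), rejection-resampled
  into the extent. The dispersion was fixed against the study's reported
  reference values before any acceptance checks: with it, the base-scenario
  1-km habitat union covers ~48% of the study area (reported: 52%), the base
  network is a single component at 5 km and above but fragments at 3 km
  (reported pattern), and scenario F retains under 2% of base links.
- **Size–position coupling.** Sizes are matched to positions through a
  ranking score mixing an easting percentile (weight `large_east_bias`,
  default 0.6 — large waterholes aggregate outside the western reserve), a
  local-sparsity percentile (weight `size_sparsity_bias`, default 0.5 — the
  biggest waterholes are scattered, while dense clumps are dominated by
  small ones, which the reported post-deletion link collapse implies), and
  residual noise. At bias 0 size and easting are uncorrelated; at bias 1 the
  Spearman correlation exceeds 0.5 by a wide margin.
- **Determinism.** One root seed drives per-stage substreams; identical
  configs yield bit-identical landscapes.

What the generator does *not* emulate: the true boundary shape (a
rectangle stands in), the actual reserve geometry, hydrological or temporal
drying dynamics, and any fine-scale spatial covariance of the real layer.
Consequently the printed link counts of the reference analysis (17,391 is
combinatorial and reproduced exactly; 7,424, 209, 94 are layout-dependent
and are not) cannot and should not be matched by synthetic landscapes;
tests assert the qualitative pattern — the percolation-style collapse, its
early onset by scenario C, and the dominance of large extra-reserve
waterholes in aggregate importance — rather than those coordinates'
numbers.

## Numerical choices and degenerate inputs

- Point-in-polygon counts boundary points as inside (reserve tagging is
  therefore deterministic at the strip edge); the tests pin this.
- Polygon footprints, when supplied, must agree with the canonical
  centroid + area representation (0.5% area, 1 m centroid) or validation
  fails loudly.
- Empty scenario results are legal (severe drought): sweeps record zero
  nodes/links/PC, habitat summaries report zero area and patches.
- A single-node network has `L = 0`, `PC = a²`, and `dPC = 100` for its one
  node.
- All randomness is seed-controlled; sweep and report outputs are
  byte-identical across runs with the same config and seed.

## Problem sizes

The default study conditions (187 waterholes, 11 scenarios, 5 distances)
run in seconds: the sweep is 55 metric evaluations on graphs of at most 187
nodes, and a full patch-removal importance analysis at 5 distances is a few
hundred shortest-path sweeps. Property-based tests use 8–50 node instances
so that their independent oracles (exhaustive path enumeration, union-find,
Monte-Carlo geometry) stay exact and fast; the qualitative drought-collapse
check runs the full default landscape across 20 seeds.

## Known limitations

- Planar coordinates only; inputs must already be in a projected metric CRS.
- Euclidean distances; no least-cost or resistance-surface movement (the
  reference analysis found its conclusions insensitive to matrix
  resistance).
- The PC numerator is reported raw (m⁴); cross-landscape comparisons need
  the usual normalization by squared landscape area, offered only as a
  ratio the user computes.
- GeoJSON i/o covers Points and Polygons with an `area_m2` convention; no
  shapefiles, no CRS transformations, no raster processing.
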