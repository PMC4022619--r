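# aguadas

Connectivity analysis of seasonal waterhole ("aguada") networks under
drought.

In karstic tropical forests such as the Greater Calakmul Region of the
Yucatan Peninsula, superficial waterholes are the only dry-season water
source for large mammals (Baird's tapir, white-lipped peccary, jaguar). As
droughts intensify, the smallest waterholes dry first, and the remaining
water bodies may fall beyond the species' movement range. `aguadas` models a
waterhole layer as a spatial graph and quantifies how its connectivity and
the habitat around it degrade as waterholes are deleted in increasing order
of surface area.

## What it computes

Waterholes are nodes with surface area `a_i` (m²) and projected centroids;
every pair within a species' maximum movement distance `d_max` is connected
by a link of Euclidean length `d_ij`. On these networks the package
computes:

- **Link density** `L = m / (n(n-1)/2)`, components, and clusters
  (components with ≥ 2 waterholes).
- **Dispersal probabilities** from a negative exponential kernel
  `p(d) = exp(-k d)` calibrated so the probability of exceeding `d_max` is a
  stated tail probability (default 0.05): `k = -ln(0.05) / d_max`.
- **Probability-of-connectivity (PC) numerator**
  `PC = Σ_i Σ_j a_i a_j p*_ij`, where `p*_ij` is the maximum, over all
  paths, of the product of link probabilities (computed as shortest paths on
  `-log p` weights); self-pairs enter with `p*_ii = 1`.
- **Node importance** by patch removal:
  `dPC_k = 100 (PC - PC_{-k}) / PC`, with ranks aggregated across the
  species' range of movement distances.
- **Drought scenarios A–K**: the base network keeps waterholes > 700 m²;
  scenarios B–K delete all waterholes ≤ 1,000 … 62,500 m², emulating
  size-ordered drying.
- **Suitable habitat**: the union of 1 km / 2 km buffers around each
  waterhole footprint, clipped to the study area — total area, percent
  coverage, and the number of disjoint habitat patches.

Because the study's field coordinates are unpublished, the package includes
a synthetic landscape generator (`generate_landscape()`) reproducing the
documented structure: 187 waterholes over 750 km², a truncated power-law
size distribution (700–172,500 m², ~61.5% at or below 2,500 m²), Thomas-style
spatial clustering, larger waterholes biased east of a western reserve strip
covering 35% of the extent.

## Worked example

```r
library(aguadas)

land <- generate_landscape(synthetic_config(seed = 1))
land$waterholes
#> Waterhole table: 187 waterholes, total water area 1.018 km2
#>   in reserve: 73 / 187

sweep <- run_sweep(land$waterholes)   # scenarios A-K x {3,5,10,13,16} km
head(subset(sweep, distance == 13000), 6)
#>  scenario n_nodes n_links link_density n_clusters pc_numerator
#>         A     187    8981    0.5164165          1 191838685435
#>         B     137    5270    0.5656934          1 187733127229
#>         C      65    1722    0.8278846          1 162882307042
#>         D      39     636    0.8582996          1 135193600820
#>         E      25     247    0.8233333          1 102645814511
#>         F      16      85    0.7083333          1  75261010933
```

At 13 km the base network carries 8,981 links; deleting every waterhole
≤ 15,625 m² (scenario F) leaves 85 — more than 99% of the base links are
gone, the size-ordered percolation collapse the analysis is built to
expose. (`link_density` here is relative to each scenario's own complete
graph, so it can rise as the survivors grow mutually closer; the collapse
is carried by `n_links` and `pc_numerator`.)

```r
sub <- apply_scenario(land$waterholes, default_scenarios()[5, ])  # scenario E
imp <- node_importance(prune_by_distance(build_complete_network(sub), 13000),
                       calibrate_kernel(13000))
head(imp[order(imp$rank), ], 3)
#>     id  area_m2      dPC rank
#>  wh008 88289.20 26.48033    1
#>  wh042 55452.03 18.22443    2
#>  wh148 50164.18 15.03629    3

buffered_habitat(apply_scenario(land$waterholes, default_scenarios()[1, ]),
                 1000, land$area)
#> Habitat summary (buffer 1000 m): 327.66 km2 = 43.7% of study area, 13 patch(es)
```

Removing the top-ranked waterhole (`wh008`, 8.8 ha) would cut the
probability-of-connectivity numerator by 26.5%; the 1-km buffer union around
the 187 base-scenario waterholes covers 43.7% of the 750 km² study area in
13 disjoint patches.

A shell entry point wrapping the same functions is installed at
`inst/cli/aguadas` (`simulate | sweep | importance | habitat | report`, with
`--config`, `--seed`, `--distances`, `--out`). `pipeline_report()` writes a
JSON manifest with the resolved config, its hash, and every computed record.

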