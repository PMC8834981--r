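---
title: "Modelling older-adult walkability as a weighted overlay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling older-adult walkability as a weighted overlay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agewalk)
```

## The model

`agewalk` estimates the *potential accessibility* (PA) of every 5 m cell of
a neighbourhood for older-adult pedestrians as a weighted linear combination
of ordinal layers:

$$PA = \sum_{i} w_i \, r_i, \qquad \sum_i w_i = 1,$$

where each $r_i \in \{1,\dots,5\}$ is a model variable reclassified onto a
common five-level scale (1 = Very Low, …, 5 = Very High) and the weights
$w_i$ encode the priorities of a population profile. The variables are
network proximity to benches, network proximity to services and facilities
(optionally split into health services vs the rest), and terrain slope. The
pedestrian network itself is the impedance substrate for the proximity
variables rather than a weighted layer of its own: the model has no
free-standing "connectivity" score, and all network quality is expressed
through the distances it produces.

Key assumptions:

* pedestrian travel is symmetric, so the graph is undirected and edge
  gradients are unsigned magnitudes $|\Delta z| / L \times 100$;
* accessibility is proximity-to-nearest: the model does not count how many
  amenities are reachable, only how far the closest one is, with the
  distance bands supplying the gravity-like discount;
* levels are equally spaced integers 1–5. The scale's labels are ordinal;
  assigning them the minimal equally spaced numeric codes is what makes the
  weighted sum well defined.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| analysis cell size | 5 | m | fine urban scale; distances within a street block resolved |
| moderate / steep walking speed | 4.3 / 4.0 | km/h | averaged older-adult speed profiles, two regimes |
| speed regime threshold | tan(9°)·100 ≈ 15.84 | % slope | the degree bound is primary; the rounded percent prints (15.8 / 15.9) both fall on the correct side |
| bench distance bands | 100/300/500/700 | m | reclassification to levels 5…1, half-open `[lo, hi)` |
| service distance bands | 100/300/600/800 | m | idem |
| slope bands | 3/5/8/12 | % | upper-closed `(lo, hi]`, honouring two-decimal band edges (5.00 % is High, 5.01 % Moderate); 5 % is also the French statutory obstacle-free limit |
| endpoint merge tolerance | 0.05 | m | with a 5 m grid, sub-decimetre digitization gaps are noise |
| source snap radius | 25 | m | about half a street width: amenities sit beside, not on, the centreline |
| off-network radius | 100 | m | one Very-High band width; cells farther from any network node than this are unreached and score level 1 |

Profile weights (`builtin_profiles()`): healthy `.45/.45/.10`
(benches/services/slope), chronic disease `.30/.40/.10/.20`
(benches/health/other/slope), reduced mobility `.30/.30/.40`. Both the
weights and the band tables can be overridden with a config file
(`load_model_config()`), validated on load: weights must be non-negative
and sum to 1, bands must be contiguous from 0 with strictly decreasing
levels.

## Numerical choices

* **Slope operator.** Horn's 3×3 finite-difference kernel, the de facto
  standard of desktop GIS slope tools, exact on planes at interior cells.
  Border cells use edge-replicated padding so that small rasters keep full
  coverage; any window containing nodata yields nodata.
* **Slope resampling.** The DTM is coarse (25 m in the synthetic
  generator); percent slope is computed at DTM resolution and then
  resampled *bilinearly onto the 5 m grid*. Resampling the slope rather
  than the elevations avoids re-differentiating interpolated surfaces,
  which would manufacture spurious gradients at cell seams.
* **Distance rasterization.** A cell's distance is the field value at the
  *nearest* network node plus the straight-line walk to that node. Using
  the nearest node (not the minimum over all nodes of field + walk) matches
  the service-area semantics of buffering a solved network, and keeps the
  operation deterministic and cheap.
* **Mid-edge sources.** Amenities snapped to the interior of an edge split
  it proportionally in the shortest-path graph, so a bench 300 m along a
  1000 m block contributes distances 300/700 to the two end nodes, not 0 or
  1000.
* **Beyond the last band.** Distances past the last printed band edge
  (≥ 1000 m) and unreached cells take level 1. Extending the worst band is
  the conservative completion of a table that stops at 1000 m.
* **Quantization.** Continuous PA maps back to classes by nearest integer
  with ties (x.5) rounding up. Any rule here is a convention; ties-up keeps
  the Moderate/High boundary symmetric with the band tables' optimistic
  lower edges.
* **Time metric.** The distance bands are meter-denominated, so the default
  pipeline accumulates meters. With `metric = "minutes"` edge costs are
  traversal times under the speed model, and the band edges and off-network
  walk are converted at the moderate speed; on flat terrain the two metrics
  give identical layers, and on sloped terrain the time metric penalizes
  steep detours.
* **Determinism.** No model stage draws random numbers; ties in point
  snapping break by lowest edge id.

## The synthetic generator

The real study areas behind this class of analysis are typically built from
national topographic databases and field surveys that cannot be
redistributed. `generate_neighborhood()` therefore emulates the *structure*
such data have: a connected street graph covering a rectangular extent
(orthogonal grid, or a loop-thinned "suburban" variant that drops ~40 % of
segments while preserving connectivity), amenities placed uniformly along
street length (street-facing placement), and a 25 m DTM that is flat, a
constant-grade ramp, or smooth band-limited noise. All randomness flows
from one seed per call and the global RNG state is restored afterwards, so
outputs are byte-identical across runs.

Two presets encode a contrast between urban forms on a 1 km × 1 km extent:
`a_like` (suburban loops at 150 m spacing, 8 % ramp, 53 benches, 27
facilities: 2/3/8/10/4 across the five groups) and `b_like` (100 m grid,
flat, 169 benches, 45 facilities: 7/7/6/20/5). The bench totals and
facility censuses are the surveyed inventories of two real contrasting
neighbourhoods; the street patterns and terrain are stylized stand-ins.
Across seeds and all three profiles the dense flat preset scores a mean PA
at least as high as the sparse sloped one — the qualitative ordering such a
contrast must produce.

What the generator does *not* emulate: real street-network morphology
(curved alignments, culs-de-sac distributions, crossings), spatial
clustering of amenities into centres, DTM artifacts (vegetation and
embankment noise), and study-area boundary effects. Tests passing on
synthetic neighbourhoods therefore validate the computational pipeline and
its invariants, not any empirical claim about a particular city.

## Verification strategy

The test suite checks the shortest-path engine against an independent
brute-force Bellman–Ford oracle on random graphs (≤ 100 nodes), and the
full overlay against a direct per-cell recomputation (naive nearest-node
loops and if-chain band lookups) on 20×20-cell fixtures, to 1e-9.
Structural invariants are property-tested: area summaries sum to 100 %, PA
is convex-bounded by its input levels, adding a bench never lowers a bench
level, adding an edge never lengthens a shortest path, and a half-weight
health/other split reproduces the unsplit run. Preset-scale runs in the
tests use 10–25 m cells over the 1 km extents (up to 10⁴ cells) to keep the
suite fast; the acceptance script runs the presets at the full 5 m
resolution (4 × 10⁴ cells per neighbourhood).

## Limitations

* Proximity-only: availability (counts of reachable amenities) is not
  scored.
* No edge-effect correction: amenities just outside the analysed extent do
  not exist for the model, so border cells are pessimistic.
* No turn restrictions, crossing penalties, or uphill/downhill asymmetry.
* The DTM is consumed as-is; artifacts (trees, embankments) propagate into
  the slope layer.
* Raster I/O is Esri ASCII grid; vector I/O is GeoJSON in planar metric
  coordinates. Inputs in geographic degrees are rejected with a
  reprojection hint rather than reprojected.
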