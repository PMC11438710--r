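---
title: "The river restoration priority model and its landscape metrics"
author: "riparify"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The river restoration priority model and its landscape metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riparify)
```

## The problem

Lowland river networks in intensively drained plains — channelized creeks,
ditch grids, engineered tributaries — are restoration targets under water
protection law, but budgets force authorities to rank candidate reaches.
`riparify` implements a transparent multi-criteria priority model for such
networks, together with the vector landscape metrics and riparian-buffer
analyses used to put the ranking into its land-cover context.

The unit of analysis is the **river sequence**: a pre-segmented stretch of
channel carrying the attributes held by the responsible authorities. The
package treats segmentation as given by the input data and does not re-split
sequences; where the segmentation of real state datasets is unknown, the
synthetic generator exposes the segment-length distribution as a parameter.

## The priority model

Each sequence is scored on four criteria, each worth 0–2 points
(restoration *need*, so adverse conditions score high):

| criterion | 0 points | 1 point | 2 points |
|---|---|---|---|
| migration barrier | absent | — | present |
| ecomorphological condition (EC) | natural | semi-natural | artificial |
| national priority species (NPS) | present | absent, isolated | absent, adjacent to an NPS sequence |
| aquatic-diversity hotspot (HDAS) | present | absent, isolated | absent, adjacent to a hotspot sequence |

The barrier criterion deliberately has no intermediate level. The three EC
levels collapse a five-level field vocabulary (high/good → natural,
moderate → semi-natural, poor/bad → artificial), and the reader applies that
mapping automatically (`muhar_ec_mapping`).

**Adjacency** is the model's one non-local rule: an absent-species sequence
earns the full 2 points when it lies within `max_dist` = 500 m of a flagged
sequence, because restoring it extends habitat and spawning grounds next to
existing populations. Distance is measured *along the network* from the
nearest point of the segment, since the rationale is fish migration, not
straight-line proximity; a sequence sharing a node with a flagged sequence
is adjacent at any nonnegative distance. The 500 m default is a minimum
migration distance. Two alternative readings are available behind a switch:
`"euclidean"` (straight-line) and `"node"` (only immediately node-adjacent
sequences). We default to the network-distance reading because it is the
only one that both respects the migration rationale and gives the
"borders directly" case (distance 0) as a special case. Presence dominates
adjacency: a flagged sequence scores 0 even if it also borders another
flagged sequence.

Points are aggregated as

$$\mathrm{score} \;=\; 4\,\frac{\sum_i w_i\,p_i}{\sum_i w_i} \in [0, 8],$$

so that the default equal weights ($w_i = 0.25$) reproduce the raw 0–8
point sum exactly. Weights are a configuration hook for stakeholder
elicitation (AHP/MCDA), which is out of scope here.

**Categories.** A restored sequence is reported as `already_restored`
regardless of its attributes; a sequence with any unknown criterion is
`unknown` ("unknown" is an explicit attribute level, not a missing value —
it encodes that the secondary data did not cover the sequence). All other
sequences fall into five classes. Only the extremes of the published scale
are anchored (8 points = very high; 0–1 points = very low); the middle is
unspecified, so we partition it evenly and make the bin map configurable:

* very_low [0, 1], low (1, 3], moderate (3, 5], high (5, 7], very_high (7, 8].

Non-integer weighted scores are classified by this real-valued map without
rounding.

```{r}
fx <- makeWorkedFixture()
scoreNetwork(fx$network)[, c("segment_id", "p_barrier", "p_ec", "p_nps",
                             "p_hdas", "score", "category")]
```

## Reporting

`lengthByCategory()` sums sequence lengths per category and expresses them
as percentages of the total analyzed length, *including* the unknown and
already-restored lengths in the denominator — the published per-category
percentages sum to ~100 across all seven categories only under that
convention, which fixes the choice. Printed tables round half away from
zero (1 decimal for percentages and km, 2 for km² areas); `roundHalfUp()`
is used instead of base R's round-half-to-even because the latter cannot
reproduce printed report tables reliably.

## Vector landscape metrics

Land-cover mosaics carry one of five classes per polygon (Ecological
Infrastructure, Farmland, Forest, Settlement, Traffic Infrastructure).
`validateLandCover()` enforces the digitizing rules as validation findings:
a 50 m² minimum mapping unit, valid rings, and pairwise interior-disjoint
polygons (boundary contact between neighbors is of course allowed).

Metrics are computed at class level from **patches** — maximal sets of
same-class polygons connected by boundary contact:

* **NP**, number of patches;
* **MPS** (ha), total class area / NP / 10,000;
* **ED** (m/ha), total edge length involving the class / landscape area ×
  10,000;
* **MNND** (m), mean over patches of the nearest edge-to-edge distance to a
  same-class patch, undefined (reported blank) when NP < 2 — not 0, which
  would fake perfect proximity;
* **MSI**, mean of perimeter / $2\sqrt{\pi\,\mathrm{area}}$, the circular
  standard for vector data, so MSI = 1 for a circle and $2/\sqrt\pi \approx
  1.128$ for a square.

Three conventions are genuinely open for vector data and are fixed as
follows, each behind a documented switch:

* **Contiguity**: corner-only contact merges (queen), matching vector union
  semantics where two polygons sharing a point dissolve into one feature;
  `"rook"` requires shared edge length for sensitivity analysis.
* **Landscape boundary**: ED counts full patch perimeters including
  stretches on the study-area boundary, reading "all edge segments
  involving" the class literally; the raster-tool variant that excludes the
  outer boundary is available (`includeBoundary = FALSE`).
* **Holes** count toward perimeter — they are edges of the patch.

Patch dissolution nodes all member edges at each other's vertices (so
T-junctions between differently split neighbor edges are handled) and
cancels pieces traced twice; what survives is the outer shell plus hole
boundaries, which is also the edge set used for MNND distances.

`changeTable()` differences per-class areas between epochs in km² and
percentage points; it accepts either mosaics or published area summaries,
because change arithmetic on printed tables is a legitimate use on its own.

## Riparian buffers

The study area is the union of a 60 m buffer on the main stem and 40 m
buffers on the side network (widths chosen in the source methodology as
most relevant for nutrient runoff and pollutant interception; both are
parameters). `bufferComposition()` buffers each priority category's
sequences at 40 m and reports each land-cover class's share of the buffered
area. Category buffers are computed independently — ground inside two
categories' buffers counts toward both rows, since the published table is
per-category and defines no tie-break. Buffered ground outside the mosaic
is reported as an explicit `uncovered` share, never silently renormalized.
Whether the published buffer table included the main stem at 60 m is not
stated; we buffer the scored side network only, at one width.

### Numerical evaluation of buffer geometry

The R environment this package targets has no polygon-clipping engine, so
buffer areas and intersections are *not* computed from polygonized buffers.
Instead a buffer is represented exactly by its distance field — a point is
inside a round-cap buffer of width $w$ iff its distance to the source
polyline is ≤ $w$ — and areas are evaluated with an adaptive quadtree on
that predicate. Because the signed distance is 1-Lipschitz, a cell of
half-size $h$ whose center distance clears $h\sqrt2$ is wholly inside or
outside; only boundary cells are refined (default finest half-size:
width/128), and at the finest level a cell contributes a linear estimate of
its covered fraction. Cells straddling a land-cover class edge are split
linearly across the nearest edge the same way. For straight boundaries both
estimates are exact up to $O(h^2)$, independent of how the grid aligns with
the geometry; the capsule closed form $2wL + \pi w^2$ is reproduced to
about 0.001%. Flat caps (signed distance to the oriented rectangle) are
available for sensitivity analysis. Round joins/caps are the default since
the source workflow is silent on cap style and round caps are the common
GIS default.

```{r}
net <- buildNetwork(list(rbind(c(0, 0), c(1000, 0))))
sa <- buildStudyArea(net, spec = bufferSpec(sideWidthM = 40))
c(quadtree = areaM2(sa), closed_form = 2 * 40 * 1000 + pi * 40^2)
```

## Synthetic data

The generators define the study conditions under which the package is
exercised; they are first-class, seeded, and deterministic (one seed drives
all randomness; the caller's RNG stream is untouched).

`makeNetwork()` defaults emulate the modeled side-network: 400 sequences
with lengths uniform on 80–340 m (≈ 85 km total), three administrative
states assigned as contiguous west-to-east blocks, barrier probability
0.4, EC mix 0.2/0.3/0.5 natural/semi-natural/artificial (about half of
comparable lowland rivers are in unnatural condition), NPS presence 0.15,
HDAS presence 0.10, 10% restored, and 13% of sequences data-deficient.
Data deficiency is a per-segment property (a sequence either was or was not
covered by the secondary datasets), implemented as one randomly chosen
criterion set to unknown, so the `unknown`-category share tracks the rate
directly. Tree mode grows a connected dendritic network; grid mode lays a
rectangular ditch lattice, the geometry typical of drained plains. Segment
geometries may cross visually without connecting — topology comes from
endpoints only, as in the source data model.

`makeMosaic()` produces an exhaustive grid of 25 m cells (625 m², above the
MMU by construction) whose classes follow a configurable mixture —
defaulting to the farmland-dominated 2019 composition — with a clustering
parameter: a cell copies a previously assigned neighbor with probability
0.4, otherwise draws from the mixture, which clumps same-class cells while
preserving the marginal mixture.

What the generators do *not* emulate: real digitized mosaics have irregular
polygon boundaries, curvilinear channels, spatially correlated attributes
(e.g. barriers clustering near settlements) and epoch-to-epoch coherence.
Tests passing on synthetic data therefore demonstrate the correctness of
the algorithms under the stated conditions, not predictive fidelity for any
particular real landscape.

## Numerical and design notes

* Endpoint snapping tolerance defaults to 1 m (source data are digitized at
  0.1 m or coarser; the workflow is silent on topology tolerance). Snapping
  is transitive within the tolerance; geometry is never moved, so topology
  construction is idempotent and order-independent.
* Coordinates must be planar meters. Files declaring a geographic CRS are
  rejected rather than silently reprojected; coordinates that all fit in
  longitude/latitude ranges trigger a warning.
* Degenerate inputs: zero-length segments and duplicate ids are
  construction errors naming the offender; an all-zero weight vector is an
  error; scores outside [0, 8] are classification errors; an empty class
  dissolves to an empty patch list (NP 0, MPS/MSI undefined, ED 0).
* Problem sizes in the shipped tests were chosen to exercise the algorithms
  at desk scale: exhaustive-oracle comparisons on 100 networks of up to 50
  segments, and one end-to-end run at 10,000 segments.

## Known limitations

* I/O is GeoJSON (+ CSV/YAML); GeoPackage and Shapefile would need a GDAL
  binding, which this package deliberately does not require.
* No rasterized (GeoTIFF) export of priority categories.
* Buffer areas are numerically integrated; their accuracy is controlled by
  the quadtree resolution rather than exact like the closed-form shoelace
  areas used everywhere else.
* Landscape-level (cross-class) aggregate metrics and the wider FRAGSTATS
  catalogue are out of scope.
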