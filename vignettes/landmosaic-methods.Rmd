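---
title: "Landscape pattern metrics: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape pattern metrics: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landmosaic)
```

## The landscape model

landmosaic treats a landscape as a categorical raster: a lattice of
integer land-use/land-cover (LULC) class codes with a cell size in
meters and a nodata code for cells outside the region of interest. A
*patch* is a maximal connected set of same-class cells under a chosen
neighbourhood rule — 8-connectivity by default (sides and corners), the
FRAGSTATS convention, or 4-connectivity (sides only). Everything the
package computes derives from three intermediates:

* the **patch labeling** (connected components per class),
* per-patch **geometry** (cell count, area, exposed-side perimeter),
* the **class adjacency matrix** — counts of cell sides shared between
  every pair of classes, with nodata kept as a pseudo-class, plus
  raster-border side tallies.

These are computed once per landscape and cached inside the object
(which is why a `landscape` must be treated as immutable after
construction); memory grows linearly with patch count. The Euclidean
nearest-neighbour distances, the only expensive quantity, are computed
lazily and *only* when an `euclidean_nearest_neighbor` family metric is
actually requested. `cache_info()` exposes the computation counters so
this contract can be observed.

## Metric conventions

The registry (`list_metrics()`) carries 95 label/level entries: 6 patch
metrics, their 6 distribution statistics at class and landscape level
(72 entries), 8 class aggregates and 9 landscape aggregates. Defaults
follow FRAGSTATS v4 semantics: areas in hectares, shares as
percentages, and landscape boundaries (nodata-facing and raster-border
sides) excluded from edge totals unless `count_boundary = TRUE`.

Conventions worth spelling out:

* **Perimeter** sums exposed cell sides; sides facing nodata or the
  raster border always count. Horizontal sides contribute the cell
  width, vertical sides the cell height, so rectangular cells are
  handled throughout. Metrics defined in *side counts* — `shape_index`
  and `landscape_shape_index`, both normalized by the maximally compact
  reference perimeter `min_perimeter_cells()` — are only defined for
  square cells and return NaN with a warning otherwise.
* **Adjacency** is rook-only (shared sides) regardless of the patch
  connectivity: edge metrics are side-based by definition, while patch
  membership may be queen-based. Each unordered cell pair is counted
  once.
* **Nearest-neighbour distance** is cell-center to cell-center, to the
  closest patch of the same class. A class with a single patch has no
  neighbour: its distance is NaN (undefined, never zero) and is
  excluded from distribution statistics with a warning.
* **Distribution statistics** use the population (`ddof = 0`) standard
  deviation, matching FRAGSTATS — a classic divergence point from
  sample-sd implementations. The area-weighted mean (`_am`) weights by
  patch area; landscape-level statistics pool all patches regardless of
  class. `cv` is reported in percent.
* **Contagion** follows the FRAGSTATS formula
  `[1 + sum P_gk ln P_gk / (2 ln m)] * 100` with
  `P_gk = p_g e_gk / sum_k e_gk` over data classes only. Note its
  behaviour at the extremes: it approaches 100 only as one class comes
  to dominate in large aggregates, and it is exactly 50 (not 0) for a
  strict two-class checkerboard, because the formula's minimum requires
  like and unlike adjacencies to be equally frequent, as in a fine
  random mixture. It is undefined (NaN) for a single class.
* The patch fractal dimension `2 ln(0.25 p) / ln a` uses area in square
  meters. At 100 m resolution a single cell gives exactly 1; at other
  resolutions the raw formula departs slightly from 1 for single cells
  and is returned as-is (the 1 m² patch, where the formula divides by
  zero, yields NaN).

Metric functions themselves are pure (summaries in, scalar out); the
three `compute_*_metrics_df()` builders are the only layer touching the
cache. Requesting a subset of metrics never changes values — it is
exactly a column subset of the full table. Labels valid only at the
other level are silently dropped (Shannon diversity from class tables,
proportion of landscape from landscape tables), mirroring the
behaviour users of the Python ecosystem's equivalent tooling expect,
while genuinely unknown labels or keyword arguments raise validation
errors.

## Multi-landscape analyses

The spatiotemporal, buffer, ring, zonal and spatiotemporal-buffer
drivers all reduce to the same operation: derive one landscape per zone
and/or date, run the single-landscape engine, and stack rows under the
analysis' index columns (`class_val`, `dates`, `buffer_dist`,
`attribute`). Masked-out cells become nodata, so zone borders behave
exactly like the landscape boundary (excluded from edges unless
`count_boundary`). A class absent from one zone or date keeps
`total_area`, `number_of_patches` and `proportion_of_landscape` at 0
and all other metrics NaN — zero area is a fact, a zero shape index
would be an invention.

Rasterization of buffers uses the **cell-center rule**: a cell belongs
to a buffer when its center lies within the buffer distance of the
geometry (boundary-inclusive, `<=`). This is deterministic and makes
consecutive rings — constructed as mask differences, half-open
`(d_{k-1}, d_k]` — an exact partition of the outermost buffer, which an
"all touched" rule would break. Buffering a polygon measures distance
from the polygon (zero inside), so a leading distance of 0 yields the
polygon itself.

Geometries are accepted as coordinates or WKT **in the raster's CRS**;
the package performs no reprojection (planar arithmetic only) and
raises a validation error when the declared CRS strings differ. Dates
are stored as given and used purely as ordered labels — no date
arithmetic is performed.

Patch-level tables are deliberately not offered for multi-landscape
analyses: patches carry no identity across zones or dates, so there is
no common index to assemble them under.

## Synthetic data and oracles

`blocks_landscape()` paints rectangles with closed-form truth (an
isolated `h x w` block has `h*w` cells and `2(h+w)` perimeter sides);
`random_mosaic()` draws i.i.d. categorical cells from a seeded
Mersenne-Twister generator, so a fixed seed reproduces a grid
bit-exactly. `reference_patches_landscape()` reconstructs the three
worked polyominoes with (cells, sides) of (115, 106), (13, 26) and
(2, 6) — a compact core plus a straight tail tuned so that
`4n - 2·(adjacent pairs)` hits the published side counts — enabling
end-to-end raster-in/metrics-out checks rather than formula-only ones.

The shipped oracles (`oracle_segment()`, `oracle_adjacency()`,
`oracle_enn()`) are deliberately naive R implementations — stack-based
flood fill, exhaustive side enumeration, all-pairs cell distances —
independent of the compiled core, and quadratic-ish: keep them to
grids of roughly 10⁴ cells. The test suite checks exact agreement on
dozens of seeded mosaics up to 50×50 cells with 3 classes, and the
i.i.d. generator is a *harder* segmentation workload than real
landscapes (it maximizes patch fragmentation). What these fixtures do
not emulate is spatial autocorrelation, class-dependent patch size
distributions, or georeferencing quirks of real LULC products; passing
tests demonstrate the algorithms' correctness, not the ecological
realism of any particular input.

Test problem sizes (mosaics of 20–60 cells a side, 2–3 classes, a few
dozen seeds) were chosen as the smallest grids that exercise every
code path — multi-patch classes, nodata, borders, both connectivities —
while keeping the oracles' quadratic cost trivial.

## Numerical choices

* Patch ids are assigned in row-major first-contact order, so tables
  are reproducible across runs and platforms.
* Adjacency counting and segmentation are single compiled passes
  (O(#cells)); the ENN search compares boundary cells only, which
  provably attains the all-pairs minimum, and brute-forces patch pairs
  within each class — exact, and fast far beyond the tested sizes.
* `min_perimeter_cells()` guards the `floor(sqrt(n))` edge case where
  floating-point `sqrt` of a perfect square lands just below the
  integer root.
* Undefined values are NaN throughout (never silently zero);
  `write_table()` renders them as empty CSV fields.
* An all-nodata landscape is valid: tables come back empty or NaN, not
  as errors.

## Command line

The `summarize`, `spatiotemporal`, `buffer` and `zonal` subcommands
(`run_cli()`, or the launcher script in `inst/cli/`) wrap the library
functions with no numeric logic of their own; their CSV output is
byte-identical to `write_table()` on the corresponding data frame.
Rasters are read and written as Esri ASCII grids — the plain-text,
GDAL-readable single-band dialect — which keeps the package's I/O free
of external geospatial system libraries; `landscape()` accepts any
in-memory integer matrix for data arriving through other R packages.

## Known limitations

* No reprojection or resampling; geometries must already be in the
  raster's CRS, and distances are planar.
* No GeoTIFF/NetCDF reader; use Esri ASCII grids or in-memory arrays.
* The core-area, proximity, contiguity, aggregation-index, division,
  Simpson-diversity and information-theoretic metric families are out
  of scope, as are moving-window analysis, transition matrices between
  dates and grain-rescaling scalograms.
* Contagion and the shape-index family inherit the FRAGSTATS
  formulas' known edge behaviours discussed above.
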