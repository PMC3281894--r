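---
title: "Landscape resistance models and effective distance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape resistance models and effective distance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landres)
```

## The modelling problem

Landscape genetics asks how landscape structure — the composition,
configuration and extent of habitat — shapes dispersal and gene flow.
The core quantity is the *effective distance* between two sampling
locations: straight-line distance modified for the effect of the
intervening landscape on an organism's movement. `landres` implements a
complete a-priori modelling chain for raster landscapes: per-species
resistance surfaces are built from tree cover, habitat suitability or
expert opinion; pairwise effective distances between sampling sites are
computed under two movement models; null models representing pure
isolation by distance are identified and validated; and competing,
strongly correlated distance models are compared with a bootstrap that
respects the non-independence of pairwise data. The intended use is to
encode explicit, ranked hypotheses about which landscape model should
best predict genetic structure for each species *before* genetic data
are analysed, so that the genetic test is confirmatory rather than post
hoc.

Everything operates on a simple raster data model (`lg_grid`): a matrix
of cell values in projected planar metres, row 1 northernmost, with
`NA` marking no-data cells, read and written as ESRI ASCII grids. No
reprojection or geographic-coordinate support is provided; a study area
is assumed to live in one projected CRS.

## Resistance surfaces

A resistance surface assigns every cell a cost per unit distance in
`[1, 10000]`. Four families are supported.

* **Uniform null** (`uniform_surface`): every cell 1. This is the
  raster analogue of isolation by distance and the reference against
  which heterogeneous models are compared.
* **Tree cover** (`tree_surface`): treed cells 1, other cells a single
  higher resistance from {2, 5, 10, 100} (`TREE_1_2` … `TREE_1_100`).
  The spread of off-tree values encodes ignorance about how strongly
  cleared land impedes movement; other values are allowed for
  sensitivity analyses but flagged. Fine-scale (e.g. 10 m) tree rasters
  are generalized to the working resolution by
  `generalize_tree_cover`, which marks a coarse cell treed when at
  least one fine tree-pixel *centre* falls inside it — chosen because
  the natural-language rule ("any cell containing a tree pixel") is
  ambiguous for partial overlap at non-integer resolution ratios, and
  the centre rule is exact, monotone and testable.
* **Habitat suitability** (`habitat_surface`): a continuous
  probability-of-occurrence surface is binarized by `binarize_sdm` at
  the threshold maximizing Youden's J (sensitivity + specificity − 1)
  over presence/absence evaluation points — our operationalization of a
  diagnosticity-maximizing default threshold; ties are broken toward
  the lower threshold, i.e. the more inclusive habitat map. Habitat
  cells get 1, others 2 or 10 (`HAB_1_2`, `HAB_1_10`).
* **Expert opinion** (`landcover_surface` with tables from
  `build_eo_tables`): per-class resistances derived from elicited
  traversal probabilities (below), on a nine-class land-cover raster in
  which agricultural cells within 50 m of a tree cell (and not
  themselves treed) are reassigned to scattered-tree variants by
  `classify_scattered_trees`. The 50 m rule is evaluated centre to
  centre, and "contiguous tree cover" is taken to mean "the cell itself
  is treed in the generalized tree grid" — no patch-size criterion is
  imposed, since none is defensible without additional data.

The computational study region (`build_study_region`) is the minimum
convex polygon around the site points — site points, not landscape
boundaries, because sites are the only locations whose pairwise
distances enter the analysis — dilated by a buffer (default 25 km) and
rasterized by a cell-centre test. Cells outside are no-data and excluded
from every computation. The buffer exists to push the artificial grid
boundary away from the sites; see the edge effect below. Because a
zero-buffer hull around a handful of sites can contain no cell centres
at all, cells containing a site are always included, which also
guarantees the invariant that every site lies inside its region.

## Effective distance

`build_grid_graph` converts a surface into a weighted graph: valid
cells are nodes, 4- or 8-neighbours (default 8) are joined, and an edge
between cells with resistances $r_a, r_b$ carries

* electrical resistance $(r_a + r_b)/2$, and
* least-cost traversal cost $(r_a + r_b)/2 \times \text{cellsize}$,

with diagonal edges scaled by $\sqrt 2$ in both roles. The arithmetic
mean with $\sqrt2$ diagonals is the standard raster-circuit convention;
the diagonal cost convention for least-cost software is not universal,
so it is stated here explicitly and shared by both methods, which keeps
the two distances comparable edge for edge.

**Least-cost path distance** (`least_cost_distances`) is the Dijkstra
shortest path between site cells: the distance an omniscient disperser
following the single cheapest route would experience. On a uniform
surface it reduces to the octile metric (straight steps cost one cell,
diagonal steps $\sqrt2$), which overshoots Euclidean distance by at
most a factor $2\sqrt{2-\sqrt2} \approx 1.082$.

**Isolation by resistance** (`effective_resistances`) treats the graph
as a resistor network and returns the two-point effective resistance:
with conductances $c_e = 1/r_e$ and graph Laplacian $L$,
$R_{ij} = (e_i - e_j)^\top L^+ (e_i - e_j)$. Current uses *all* paths,
so with equal edge weights the circuit distance never exceeds the
least-cost distance, and adding routes (or lowering any resistance)
can only lower it (Rayleigh monotonicity) — both properties are tested
against dense pseudo-inverse oracles. Numerically, one node per
connected component is grounded, the reduced Laplacian is factorized
once by sparse Cholesky, and one triangular solve per site yields all
pairwise values; this is direct (no iterative tolerance enters the
results) and scales to the ~10^5–10^6-cell grids the package targets.
Disconnected pairs are reported as `Inf`, never as a large sentinel.

### The grid edge effect and null models

Cells beyond the grid boundary are effectively infinite resistance, so
circuit distances between points near an artificial boundary are
inflated: current that would spread through the missing half-plane is
confined. `edge_effect_experiment` reproduces this on a uniform disc
(resistance 1, cell size 1): for each pair separation, effective
resistance falls monotonically as the pair moves inward from the edge,
and the inflation reaches farther inward for larger separations. Two
practical consequences, both encoded in the package: study regions are
buffered generously (25 km by default), and the proper null model for a
circuit-theory analysis is `CS_UNIFORM` — the circuit distance on a
*uniform* surface over the same grid, which carries the same boundary
inflation — rather than raw geographic distance. For least-cost models
the plain geographic distance `GEOG` is the appropriate null. Far from
the boundary, effective resistance on a uniform surface grows roughly
logarithmically with separation (the two-dimensional lattice Green's
function), which is why the log-transformed distance `logGEOG` is also
carried as a candidate null. `run_model_suite` produces all three null
matrices alongside the per-surface LCP/IBR matrices.

## Comparing correlated distance models

A distance matrix on $n$ sites holds $\binom n2$ pairs but only
$\lfloor n/2\rfloor$ mutually independent ones (no site used twice).
`bootstrap_r2` therefore estimates the squared Pearson correlation
between two distance models by repeatedly drawing a uniformly random
maximal set of disjoint pairs (`sample_independent_pairs`: random
permutation, consecutive pairing; with odd $n$ the leftover site
re-randomizes each draw), correlating the selected entries, and
reporting the mean and empirical 2.5/97.5 percentiles over iterations
(default 1000). Pearson on raw distances is used because that is the
quantity the Mantel-type alternatives this replaces would correlate;
the percentile interval is chosen for distribution-freedom. Iterations
with zero variance or non-finite entries are discarded and counted.
Under independence the expected $R^2$ is approximately $1/(k-1)$ with
$k$ pairs per draw, a property the test suite checks by simulation.

A-priori hypotheses are encoded as per-species ranked model lists
(rank 1 = best expected fit, ties share the printed rank; the packaged
table in `read_hypothesis_rankings()` covers ten woodland bird species
and seven candidate models, plus an expected isolation-by-distance
strength label). `evaluate_ranking` scores a hypothesis against
observed mean $R^2$ values by Spearman correlation with midrank ties;
models marked `NA` (not applicable to a species) are dropped.

## Expert elicitation

Panels are long-form tables of traversal probabilities in
`[0.0001, 1]` over experts × species × land-cover classes × distances.
Aggregation is deliberately simple and auditable:
`mean_conductivity` averages experts per combination (missing estimates
dropped); `resistance_from_conductivity` takes the reciprocal, mapping
the permissible range onto resistances `[1, 10000]` — a unanimous floor
of 0.0001 yields exactly the 10000 ceiling seen in the packaged tables;
`merge_equal_classes` merges classes whose resistances tie (exact
equality by default, since elicited ties are exact; a relative
tolerance is available for noisy synthetic panels); and
`build_eo_tables` composes these into per-species tables coded
`<SPECIES>_EO_<distance>`.

`variance_components` decomposes estimate variance into expert,
land-cover, species (and, pooling distances, distance) components as
percentages of total variance, fitted as crossed random intercepts by
REML in `lme4` on the untransformed probabilities. REML is used rather
than a method-of-moments ANOVA estimator because it is the standard
tool for crossed random effects, returns non-negative components by
construction (no truncate-and-renormalize step), and matches how such
elicitations are analysed in practice. Probabilities are analysed
untransformed; the decomposition should be read as descriptive, not as
a calibrated generative model. A panel with zero total variance returns
all-zero components with a degeneracy flag rather than an error.
Note the package accepts seven elicitation distances (100 m–10 km
including 2 km) even though some elicitations use six; the panel
structure is not hard-coded.

## Synthetic landscapes and panels

`simulate_landcover` generates the study's landscape conditions:
10 × 10 km extents at 25 m resolution, with tree cover obtained by
thresholding a Gaussian random field (white noise smoothed by circular
FFT convolution) at the quantile matching the target cover fraction.
One knob — the smoothing length — separates the configurations:
16 cells (400 m) for `aggregated` and `continuous`, 2 cells (50 m) for
`dispersed`; `continuous` additionally requires cover ≥ 0.7. Cover
fractions of interest span roughly 0.11–0.79, the range observed across
fragmented-to-continuous study landscapes. Thresholding a continuous
field hits the target cover essentially exactly; a ±2-percentage-point
check guards degenerate tiny grids. Non-tree cells are split among
urban (2%), plantation (3%) and the three agricultural classes
(35/35/25% of the non-tree area) by a second smoothed field, giving
spatially coherent class patches. `simulate_sites` draws 3–6 sites on
tree cells with a minimum spacing by rejection; `simulate_sdm` mixes
the tree indicator with smooth noise under a fidelity weight;
`simulate_expert_panel` generates panels as true mean (non-increasing
in distance, default `exp(-d/2000)` floored at 0.02) plus zero-mean
Gaussian expert, land-cover, species and residual effects whose
variances realize requested shares of a total variance, clipped to the
elicitation bounds — clipping, not re-drawing, because that is what the
elicitation instrument's floor does to real answers.

What the generator does *not* emulate: real vegetation ecology
(patch-size distributions, linear roadside strips, riparian corridors),
spatially autocorrelated expert error, and any coupling between
land-cover classes and site placement beyond tree membership. Passing
tests therefore demonstrate that the machinery is correct under
controlled conditions, not that any particular resistance model is
ecologically right.

## Reproducibility and problem sizes

Every stochastic operation takes (or is documented to follow) an
explicit seed; `run_pipeline` takes a single seed and derives
per-stage seeds deterministically, so identical configurations produce
byte-identical artifacts. The test suite exercises the distance
machinery against independent oracles (Floyd–Warshall relaxation,
dense Laplacian pseudo-inverses, brute-force geometry) on grids up to
8 × 8, validates the uniform-surface least-cost null equivalence on a
400 × 400 grid with 65 random sites, runs the edge-effect experiment on
discs of radius 60 (with dense-oracle agreement at radius 20), and
recovers known variance shares from 200 synthetic panels — sizes chosen
so the whole suite completes in well under a minute while leaving the
asymptotic regime to the properties (metricity, Rayleigh monotonicity,
octile bounds) that hold at any size.

## Known limitations

* Single projected CRS; no reprojection, multi-band rasters or GeoTIFF
  I/O — ESRI ASCII grid is the interchange format.
* Circuit solves are direct; grids much beyond ~10^6 valid cells will
  exhaust memory before time.
* The bootstrap assumes the two matrices share one site ordering and
  does not model measurement error in either distance.
* Expert aggregation is a plain mean; no weighting, calibration or
  behavioural aggregation of experts is attempted.
* Genetic data, Mantel/partial-Mantel testing and causal modelling of
  genetic distances are out of scope by design: this package builds and
  validates the predictor side of the analysis.
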