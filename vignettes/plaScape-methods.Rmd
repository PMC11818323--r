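---
title: "plaScape methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plaScape methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`plaScape` analyses segmented per-cell tables from multiplexed tumour
images with an in situ proximity-ligation (isPLA) channel. This vignette
is the package's own account of the underlying models, the parameters that
matter, and the choices we made where the design was genuinely open. The
worked numbers shown in the README are produced by the code there; nothing
here asserts an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The data model

A `CellTable` holds one sample: cell id, centroid (x, y) in microns,
nuclear area in µm², and the median intensity of seven channels (PanCK,
CD20, CD3e, CD8, CD68, isPLA, DAPI). Coordinates live in an arbitrary
image frame — the pipeline never assumes an origin or a pixel size, and
all geometry is translation/rotation-equivariant. Stage outputs (cell
type, region, signed boundary distance, isPLA call, CN labels, spatial
context) are appended as columns on the same table, so a single CSV or
Parquet file carries a sample through the whole pipeline. A label column
is either absent (stage not run) or complete; partial labelling is a
validity error.

## Phenotyping

**QC.** Nuclei outside the closed interval [`qcMinArea`, `qcMaxArea`]
(defaults 10 and 220 µm²) are removed, as are cells below `qcMinDapi`.
The interval is closed because the exclusion rule is stated for nuclei
*smaller* than 10 and *larger* than 220 µm²; a 10 µm² nucleus survives.
There is no published DAPI floor, so `qcMinDapi` defaults to 0 and is a
config knob; the filter report records removals per rule either way.

**Transform and scaling.** Intensities are variance-stabilised with
`asinh(x / 150)`. Nuclear area is listed among the clustering features; we
pass it through the same transform by default (`transformArea = TRUE`)
because leaving a µm²-scaled column next to arcsinh-scaled intensities
would let it dominate Euclidean distances before scaling; the flag exists
because the alternative reading (raw area) is defensible. Scaling is
two-pass: z-score each column (marker), then z-score each row (cell).
"Scaling" could also mean min–max; `scaleMethod = "minmax"` switches both
passes. Zero-variance columns or rows map to zeros rather than NaN, which
also defines the single-cell degenerate case.

**Clustering and annotation.** A k-nearest-neighbour graph (k = 30,
Euclidean in feature space, distance ties broken by ascending cell index)
is partitioned with Leiden at modularity resolution 2, seeded from
`randomSeed`. Clusters are annotated by the canonical marker with the
highest cluster-mean z-score against the grand mean; near-ties (< 1e-6)
resolve by the fixed precedence PanCK > CD20 > CD68 > CD8 > CD3e. The
precedence ordering matters mainly for cytotoxic T cells, which
co-express CD3e: when CD8 and CD3e scores are indistinguishable the
cluster is called CD8 T.

## Tumour mask and boundary distances

The published workflow derives its tumour mask from a pixel classifier on
the PanCK channel. Working from cell tables we have no pixels, so the mask
is rebuilt from *tumour-cell point density*: counts on a grid
(`maskGridPitch` = 20 µm, origin pinned to the data bounding box so the
mask is translation-equivariant), Gaussian smoothing (`maskSigma` = 1 grid
cell), iso-contouring at a threshold, and discarding nests with area at or
below `maskMinNestArea` = 100 µm². The default threshold is half the mean
smoothed density over grid cells that contain at least one tumour cell —
for a uniform nest the half-maximum contour sits at the true edge — and
can be overridden (`maskThreshold`, cells/µm²). Lowering the threshold can
only grow the mask (monotonicity is tested).

Signed distances are exact point-to-polygon-boundary distances, negative
inside a nest. The sign convention is ours (none is published); cells
exactly on a boundary get distance 0 and are labelled tumour, making the
boundary closed and the label deterministic. With an empty mask distances
are `NA` — explicitly undefined, never ±Inf. Distance histograms
("normalized cell count") use `binWidth` = 25 µm bins aligned so 0 is a
bin edge; 25 µm resolves the 200–400 µm scales the distance analysis
discusses while keeping per-bin counts stable at typical cell densities.

## isPLA calls and proximity density

Positivity is a single cohort-wide intensity threshold (`isPLA ≥ t`),
mirroring the requirement that one consistent threshold apply to all
slides. The published threshold was set by visual inspection, which is not
reproducible programmatically; we therefore accept an explicit numeric
threshold or estimate one by Otsu's method on pooled `log(1+x)`
intensities, which assumes a bimodal background/signal mixture. Groups
with zero cells get `NA` fractions — missing, never zero.

Proximity density for a type pair is the number of unordered pairs within
a closed 20 µm ball divided by the combined cell count of the two types;
for a type against itself each unordered pair counts once and the
denominator is that type's count alone (the literal reading of "number of
cells in each cell-pair"). The kd-tree implementation is contractually
identical to the O(n²) definition and is tested against it.

## Cellular neighbourhoods

Each cell's window is itself plus its `cnWindowK` = 10 nearest neighbours.
Two published statements conflict — the methods say 10 neighbours, the
results text says six; we default to the methods value and leave
`cnWindowK` configurable. Whether the window includes the index cell is
unstated; we include it (`includeIndexCell = TRUE`), following the CN
method this analysis builds on. Window label compositions (cell types, or
cell types × isPLA status for the augmented variant) are clustered with
KMeans: Lloyd's algorithm, k-means++ initialisation, best of
`cnRestarts` = 10 restarts by inertia. We wrote Lloyd's loop in-package
because the fit must tolerate duplicate initial centres and re-seed empty
clusters (to the point farthest from its centroid) when K exceeds the
number of distinct windows; it is cross-checked against `stats::kmeans`
on separable data in the tests. Windows are pooled across all samples of
a cohort and labels assigned per sample, since response-group comparisons
need one shared CN vocabulary; per-sample fitting would make labels
incommensurable.

K is scanned over `cnKRange` = 3…15 and the elbow chosen by the Kneedle
rule: min–max normalise K and inertia, invert the inertia axis, and take
the K maximising the gap to the diagonal (sensitivity 1). If the gap curve
has no interior maximum we fall back to maximum discrete curvature, and a
flat curve returns the smallest K. Each scan step seeds one extra restart
with the previous K's centroids plus the farthest window, which guarantees
a non-increasing inertia curve — without it, restart noise can make the
curve locally increase and the elbow ill-defined.

## Spatial contexts

SC windows are the 100 nearest neighbours (`scWindowK`), composed over CN
labels. The minimal combination sorts CNs by descending window frequency
(ties by ascending CN id) and takes the shortest prefix whose cumulative
frequency *strictly* exceeds `scThreshold` = 0.9 — "more than 90 %" is
read literally. Combination identity is the id-sorted tuple. SC-map graphs
keep combinations above `scmMinFraction` = 1e-5 (0.001 %) of a group's
cells and draw directed edges only to supersets exactly one CN larger;
that keeps the graph a sparse DAG matching the hierarchical
"more complex combination" reading (full-subset edges would quadratically
densify it). The barycentric projection keeps windows with at least
`barycentricPurity` = 99.95 % of their mass on a chosen CN triple,
renormalises the three frequencies and maps them into an equilateral unit
triangle; vertices are pure CNs, edges pairwise interfaces.

## Cohort statistics

Cell percentages normalise within tissue or within tumour/stroma region.
Response groups are compared feature-wise (region × cell type isPLA
positivity fractions) with Kruskal–Wallis (tie-corrected H, χ²
approximation on g−1 df); identical observations give H = 0, p = 1 by
convention. The correction is Benjamini–Hochberg across the full feature
family — the published analysis says only "correcting for multiple
comparisons", so the method is a documented, switchable choice.
Stable-disease samples can be excluded from headline contrasts
(`excludeGroups = "SD"`, as the original analysis does on the grounds that
SD sits between response and progression) while remaining in all
summaries.

`barrierCoverage()` operationalises the "macrophage barrier": nest
boundaries are resampled every `boundaryStep` = 10 µm, and a boundary
point is covered when at least `coverageMinCells` = 3 isPLA⁺ macrophages
lie within `coverageDistance` = 50 µm. The defaults encode what "dense
peritumoural layer" means at typical segmented-cell densities — a 50 µm
half-disc at ~0.003 cells/µm² holds roughly a dozen cells, so demanding
three isPLA⁺ macrophages requires genuine local enrichment, while a
scattered stromal macrophage population rarely supplies them. Coverage is
monotone in both parameters (tested) so the choice shifts the scale, not
the ordering, of group contrasts.

## The synthetic-tissue generator

`generateTissue()` is a forward model of the geometries the analysis is
meant to separate. Tumour nests are circles with low-order Fourier radial
perturbations (guaranteed simple, star-shaped polygons — chosen so
analytic distance oracles exist); cells are placed by thinning a uniform
Poisson process with each compartment's indicator, which is an exact
inhomogeneous Poisson sample. The `barrier` archetype adds macrophages in
the band 0–200 µm outside nest boundaries; the `tls` archetype adds
B/T-cell discs centred 0–100 µm outside boundaries. True isPLA state is
Bernoulli with probability `p₀(type)·exp(−d/λ)`, λ = 150 µm, so positivity
decays smoothly from the boundary on both sides. Marker intensities are
log-normal around a per-type mean with off-target bleed-through (30 vs 500
for canonical markers), making phenotyping a genuine clustering problem
rather than an argmax; the isPLA channel is log-normal background plus a
log-normal shift for true positives, so threshold estimation is
non-trivial; 5 % of nuclei are drawn outside the QC window as
segmentation artifacts. Defaults produce ≈5,000 cells on a 1.5 × 1.5 mm
field at tissue-realistic densities (0.002–0.005 cells/µm²).
`generateCohort()` assigns barrier architecture to PD/SD samples and
aggregate architecture to CR/PR, with mild within-group spread, defaulting
to the 14-sample CR = 2 / PR = 4 / SD = 2 / PD = 6 design.

What the generator does *not* emulate: staining chemistry and spectral
bleed between specific channel pairs, segmentation errors that merge or
split cells, spatial intensity gradients and batch effects, necrotic or
folded tissue regions, and holes or invaginated topology inside tumour
nests. Passing tests therefore demonstrate algorithmic correctness and
parameter recovery under the stated geometric model, not robustness to
every failure mode of real imaging data.

## Numerical conventions and problem sizes

Distance ties in every k-NN query break by ascending cell index;
assignment ties in KMeans by lowest centroid index; abundance ties in the
minimal-combination sort by ascending CN id; annotation ties by the fixed
marker precedence. All randomness flows from explicit seeds, so every
stage is bit-reproducible; the run manifest hashes all data artifacts to
make that checkable. Simplex rows are validated to 1e-12; inertia
self-consistency to 1e-9; geometry oracles to 1e-6 (the polygonal
discretisation of test circles is chosen fine enough to sit below that).

The test suite exercises parameter recovery on planted four-archetype
tissues of ≈30,000 cells (five seeds), the barrier-vs-aggregate contrast
on ten independent archetype pairs, and full-pipeline determinism on a
four-sample cohort; `scripts/acceptance.R` re-runs the whole pipeline on
the 14-sample default cohort (≈90,000 cells). These sizes give stable
window compositions and group statistics while keeping a complete run in
minutes on one CPU.

## Known limitations

The density-contour mask is a surrogate for a pixel classifier: very
sparse tumour regions below the density threshold dissolve into stroma,
and nests touching the field edge are closed by the padding ring.
Phenotyping assumes the five canonical types span the tissue; unmodelled
types would be absorbed into the nearest cluster. Otsu thresholding
assumes bimodal isPLA intensities and will mis-place the cutoff on
unimodal data. KMeans CNs inherit KMeans' preference for isotropic
clusters in composition space, and the Kneedle elbow is only as meaningful
as the inertia curve's curvature. Finally, with realistic cohort sizes
(n = 14) the Kruskal–Wallis contrasts are descriptive: the acceptance run
reports the minimum BH-adjusted p it actually obtains rather than claiming
significance.
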