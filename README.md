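# plaScape

Spatial interaction mapping for multiplexed tumour images that carry an
**in situ proximity ligation assay (isPLA)** channel. isPLA produces a
signal only when a receptor and its ligand — here PD-1 on immune cells and
PD-L1 on tumour or myeloid cells — sit within ~40 nm of each other, so the
channel reports *plausible interaction* rather than mere co-expression.
`plaScape` takes segmented per-cell tables (centroids in µm, nuclear area,
median marker intensities for PanCK, CD20, CD3e, CD8, CD68, isPLA, DAPI)
and asks *where* in the tumour microenvironment those interactions
concentrate, and how that differs between therapy response groups
(RECIST: CR/PR/SD/PD).

It is aimed at spatial-biology analysts working with PhenoCycler/Opal-style
segmented cell data who want a reproducible, testable version of this
analysis — including a fully ground-truthed synthetic-tissue generator, so
every stage can be validated without access to patient imaging data.

## What it computes

1. **Phenotyping** — QC on nuclear area (10–220 µm²) and DAPI; arcsinh
   transform `x ↦ asinh(x/c)` with cofactor `c = 150`; two-pass scaling
   (within markers, then across cells); k-NN graph (k = 30) + Leiden
   (resolution 2); cluster annotation by canonical markers
   (PanCK→Tumour, CD20→B, CD68→Macrophage, CD8→CD8 T, CD3e→CD3 T).
2. **Tumour/stroma mask** — tumour-cell point density, Gaussian-smoothed
   and contoured; nests ≤ 100 µm² discarded; per-cell **signed boundary
   distance** (negative inside tumour).
3. **isPLA positivity** — one cohort-wide intensity threshold (explicit, or
   Otsu on pooled log-intensities), then positivity fractions per
   region × cell type.
4. **Proximity density** — for a type pair (A, B) and radius r = 20 µm,
   `density = n_pairs / (n_A + n_B)`, pairs counted once within the closed
   ball.
5. **Cellular neighbourhoods (CN)** — windows of each cell's 10 nearest
   neighbours, label-composition matrix, KMeans over K = 3…15, elbow
   selection by the Kneedle rule; computed with and without isPLA-augmented
   labels.
6. **Spatial contexts (SC)** — 100-neighbour CN-frequency windows; the
   minimal CN combination whose cumulative frequency exceeds 90 %; SC-map
   DAGs per response group (nodes > 0.001 % of cells, edges to
   one-CN-larger supersets); barycentric projection of CN triples at
   99.95 % window purity.
7. **Cohort statistics** — cell-type percentages, Kruskal–Wallis across
   response groups with Benjamini–Hochberg correction, and a
   macrophage-barrier coverage score (fraction of boundary points with ≥ 3
   isPLA⁺ macrophages within 50 µm).

The synthetic generator plants the two architectures the analysis is
designed to separate: a dense peritumoural **macrophage barrier**
(non-responder-like, PD/SD) and **B/T-cell aggregates** near the tumour
edge (responder-like, CR/PR), with isPLA positivity decaying with distance
from the tumour boundary.

## Worked example

```r
library(plaScape)

arch <- tissueArchitecture("barrier")     # non-responder-like architecture
sim  <- generateTissue(arch, seed = 1)
sim$table
#> CellTable 'synth-1': 7712 cells

ph <- phenotypeCells(sim$table)
table(cellData(ph$tables)$cell_type)
#>     B cell CD3 T cell CD8 T cell Macrophage     Tumour
#>        677       1145        872       3156       1476

mask <- buildTumourMask(ph$tables)
mask
#> RegionMask 'synth-1': 3 nest(s), total area 324957 um^2; 1566/7326 cells in tumour

tb <- classifyIspla(assignRegions(ph$tables, mask))
round(isplaThreshold(tb), 1)
#> [1] 57.8

subset(positivityFraction(tb), region == "tumour")
#>   sample_id region  cell_type    n n_positive  fraction
#>     synth-1 tumour     B cell   39         11 0.2820513
#>     synth-1 tumour CD3 T cell   64         27 0.4218750
#>     synth-1 tumour CD8 T cell   39         18 0.4615385
#>     synth-1 tumour Macrophage  110         58 0.5272727
#>     synth-1 tumour     Tumour 1314        331 0.2519026

proximityDensity(tb, "Macrophage", "Tumour", radius = 20)
#>   sample_id     type_a type_b n_pairs n_cells  density radius
#>     synth-1 Macrophage Tumour     805    4632 0.173791     20

barrierCoverage(tb, mask)
#> [1] 0.9810811
```

The phenotyped table shows the macrophage excess a barrier architecture
implies; the mask recovers the three planted nests; the Otsu threshold
separates isPLA background from signal; and the barrier coverage of 0.98
says that almost the entire tumour boundary of this sample is lined with
isPLA⁺ macrophages — the hallmark this pipeline quantifies. CN/SC discovery
runs the same way via `discoverCN()` and `assignSpatialContext()`, or all
stages at once:

```r
runPipeline(list(synthetic = list(n_per_group = list(CR = 2, PD = 2), seed = 7)),
            outDir = "run1")
```

which writes labelled cell tables, GeoJSON masks, CN models and inertia
curves, SC-map graphs (JSON/DOT), tidy statistics CSVs, figure-analogue
plots (PNG + SVG) and a hashed run manifest. A thin CLI wrapper lives at
`inst/scripts/run_pipeline.R`.

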