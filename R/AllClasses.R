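#' @import methods
NULL

#' Channels measured on every cell
#'
#' The six phenotyping markers plus the nuclear counterstain. `plaMarkers()`
#' returns the markers used for clustering (everything except DAPI);
#' `plaChannels()` additionally includes DAPI. `plaCellTypes()` returns the
#' five canonical cell types the phenotyping stage assigns.
#'
#' @return Character vector of channel / cell-type names.
#' @export
plaChannels <- function() c("PanCK", "CD20", "CD3e", "CD8", "CD68", "isPLA", "DAPI")

#' @rdname plaChannels
#' @export
plaMarkers <- function() c("PanCK", "CD20", "CD3e", "CD8", "CD68", "isPLA")

#' @rdname plaChannels
#' @export
plaCellTypes <- function() c("B cell", "CD3 T cell", "CD8 T cell", "Macrophage", "Tumour")

# canonical marker -> cell type, in tie-break precedence order
.canonicalMarkers <- c(
  PanCK = "Tumour",
  CD20  = "B cell",
  CD68  = "Macrophage",
  CD8   = "CD8 T cell",
  CD3e  = "CD3 T cell"
)

.requiredCellCols <- function() c("cell_id", "x", "y", "nuclear_area", plaChannels())

.labelCols <- function() {
  c("cluster", "cell_type", "ispla_positive", "region", "boundary_dist",
    "nearest_nest", "cn_label", "cn_label_pla", "sc_combination")
}

#' Per-cell table for one tissue sample
#'
#' The universal currency of the pipeline: one row per segmented cell with
#' centroid coordinates in microns, nuclear area in square microns and the
#' median intensity of every channel. Downstream stages append label columns
#' (`cell_type`, `ispla_positive`, `region`, `boundary_dist`, `cn_label`,
#' `cn_label_pla`, `sc_combination`) in place.
#'
#' @slot sampleId single sample identifier.
#' @slot cells `data.frame` with columns `cell_id`, `x`, `y`, `nuclear_area`
#'   and one column per channel, plus any label columns added later.
#'
#' @export
setClass("CellTable", representation(sampleId = "character", cells = "data.frame"))

setValidity("CellTable", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId) || !nzchar(object@sampleId))
    msg <- c(msg, "sampleId must be a single non-empty string")
  cells <- object@cells
  missing <- setdiff(.requiredCellCols(), names(cells))
  if (length(missing))
    return(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")))
  if (anyDuplicated(cells$cell_id))
    msg <- c(msg, "cell_id values must be unique within a sample")
  if (nrow(cells)) {
    if (!all(is.finite(cells$x)) || !all(is.finite(cells$y)))
      msg <- c(msg, "coordinates must be finite")
    if (!all(is.finite(cells$nuclear_area)) || any(cells$nuclear_area <= 0))
      msg <- c(msg, "nuclear_area must be positive")
    for (ch in plaChannels()) {
      v <- cells[[ch]]
      if (!is.numeric(v) || anyNA(v) || any(v < 0)) {
        msg <- c(msg, sprintf("channel %s must be non-negative and complete", ch))
        break
      }
    }
    lab <- intersect(.labelCols(), names(cells))
    for (cn in setdiff(lab, c("boundary_dist", "nearest_nest"))) {
      if (anyNA(cells[[cn]]))
        msg <- c(msg, sprintf("label column %s must cover every retained cell", cn))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CellTable
#'
#' @param cells data.frame of per-cell records (see [CellTable-class]).
#' @param sampleId sample identifier.
#' @return A validated [CellTable-class] object.
#' @export
cellTable <- function(cells, sampleId) {
  cells <- as.data.frame(cells)
  cells$cell_id <- as.character(cells$cell_id)
  new("CellTable", sampleId = as.character(sampleId), cells = cells)
}

#' @describeIn CellTable-class number of cells.
#' @param x,object a `CellTable`.
#' @export
setMethod("length", "CellTable", function(x) nrow(x@cells))

setMethod("show", "CellTable", function(object) {
  cat(sprintf("CellTable '%s': %d cells\n", object@sampleId, nrow(object@cells)))
  lab <- intersect(.labelCols(), names(object@cells))
  if (length(lab)) cat("  labels:", paste(lab, collapse = ", "), "\n")
})

#' Accessors for CellTable
#'
#' `cellData()` returns the per-cell data.frame, `sampleId()` the sample
#' identifier. `cellData<-` replaces the data.frame (revalidating).
#'
#' @param x a [CellTable-class].
#' @param value replacement data.frame.
#' @return `cellData`: data.frame; `sampleId`: character scalar.
#' @export
cellData <- function(x) x@cells

#' @rdname cellData
#' @export
`cellData<-` <- function(x, value) {
  x@cells <- as.data.frame(value)
  validObject(x)
  x
}

#' @rdname cellData
#' @export
sampleId <- function(x) x@sampleId

#' Pipeline configuration
#'
#' Holds every numeric parameter of the analysis. Defaults follow the
#' published workflow where one exists: QC nuclear-area window 10--220 um^2,
#' arcsinh cofactor 150, phenotyping k-NN k = 30 at Leiden resolution 2,
#' minimum tumour-nest area 100 um^2, CN windows of the 10 nearest
#' neighbours with KMeans K scanned over 3--15, SC windows of 100 neighbours
#' with the >90 percent minimal-combination rule, SC-map node cutoff
#' 0.001 percent, barycentric purity 99.95 percent, and a 20 um proximity
#' radius. Parameters without a published value (DAPI QC floor, isPLA
#' threshold) default to "auto"/permissive and are documented at their
#' consuming stage.
#'
#' @slot qcMinArea,qcMaxArea nuclear-area QC window, um^2.
#' @slot qcMinDapi minimum median DAPI intensity retained.
#' @slot arcsinhCofactor cofactor of the arcsinh transform.
#' @slot scaleMethod per-column/per-row scaling strategy, `"zscore"` or `"minmax"`.
#' @slot transformArea whether nuclear area passes through the arcsinh transform.
#' @slot phenotypeKnnK,phenotypeResolution k-NN graph size and Leiden resolution.
#' @slot maskGridPitch,maskSigma,maskThreshold tumour-mask grid pitch (um),
#'   Gaussian smoothing in grid cells, and density threshold (NA = automatic,
#'   half the mean smoothed density over tumour-cell-occupied grid cells).
#' @slot maskMinNestArea minimum retained nest area, um^2.
#' @slot binWidth boundary-distance histogram bin width, um.
#' @slot isplaThreshold isPLA intensity cutoff (NA = Otsu automatic).
#' @slot proximityRadius proximity-density radius, um.
#' @slot cnWindowK,cnKRange,cnRestarts CN window size, KMeans K range, restarts.
#' @slot includeIndexCell whether a window contains the index cell itself.
#' @slot scWindowK,scThreshold SC window size and minimal-combination threshold.
#' @slot scmMinFraction minimum cell fraction for an SC-map node.
#' @slot barycentricPurity window purity for the CN interface projection.
#' @slot coverageDistance,coverageMinCells barrier-coverage parameters: a
#'   boundary point is covered when at least `coverageMinCells` isPLA-positive
#'   macrophages lie within `coverageDistance` um.
#' @slot boundaryStep arc-length step between sampled boundary points, um.
#' @slot randomSeed seed for every stochastic stage.
#'
#' @export
setClass("PlaConfig", representation(
  qcMinArea = "numeric", qcMaxArea = "numeric", qcMinDapi = "numeric",
  arcsinhCofactor = "numeric", scaleMethod = "character", transformArea = "logical",
  phenotypeKnnK = "numeric", phenotypeResolution = "numeric",
  maskGridPitch = "numeric", maskSigma = "numeric", maskThreshold = "numeric",
  maskMinNestArea = "numeric", binWidth = "numeric",
  isplaThreshold = "numeric", proximityRadius = "numeric",
  cnWindowK = "numeric", cnKRange = "numeric", cnRestarts = "numeric",
  includeIndexCell = "logical",
  scWindowK = "numeric", scThreshold = "numeric", scmMinFraction = "numeric",
  barycentricPurity = "numeric",
  coverageDistance = "numeric", coverageMinCells = "numeric", boundaryStep = "numeric",
  randomSeed = "numeric"
))

setValidity("PlaConfig", function(object) {
  msg <- character()
  if (!(object@qcMinArea < object@qcMaxArea))
    msg <- c(msg, "qcMinArea must be smaller than qcMaxArea")
  counts <- c(phenotypeKnnK = object@phenotypeKnnK, cnWindowK = object@cnWindowK,
              cnRestarts = object@cnRestarts, scWindowK = object@scWindowK,
              coverageMinCells = object@coverageMinCells)
  if (any(counts < 1 | counts != round(counts)))
    msg <- c(msg, "count parameters must be integers >= 1")
  fr <- c(scThreshold = object@scThreshold, scmMinFraction = object@scmMinFraction,
          barycentricPurity = object@barycentricPurity)
  if (any(fr <= 0 | fr > 1))
    msg <- c(msg, "fraction parameters must lie in (0, 1]")
  if (length(object@cnKRange) != 2L || object@cnKRange[1] > object@cnKRange[2] ||
      object@cnKRange[1] < 1)
    msg <- c(msg, "cnKRange must be an increasing pair of integers >= 1")
  if (!object@scaleMethod %in% c("zscore", "minmax"))
    msg <- c(msg, "scaleMethod must be 'zscore' or 'minmax'")
  pos <- c(object@arcsinhCofactor, object@maskGridPitch, object@maskSigma,
           object@binWidth, object@proximityRadius, object@coverageDistance,
           object@boundaryStep)
  if (any(!is.finite(pos)) || any(pos <= 0))
    msg <- c(msg, "length/scale parameters must be positive")
  if (length(msg)) msg else TRUE
})

#' Create a pipeline configuration
#'
#' @param ... named parameters overriding the defaults; see [PlaConfig-class]
#'   for the full list and units.
#' @return A validated [PlaConfig-class] object.
#' @examples
#' cfg <- plaConfig(proximityRadius = 30)
#' cfg@proximityRadius
#' @export
plaConfig <- function(...) {
  defaults <- list(
    qcMinArea = 10, qcMaxArea = 220, qcMinDapi = 0,
    arcsinhCofactor = 150, scaleMethod = "zscore", transformArea = TRUE,
    phenotypeKnnK = 30, phenotypeResolution = 2,
    maskGridPitch = 20, maskSigma = 1, maskThreshold = NA_real_,
    maskMinNestArea = 100, binWidth = 25,
    isplaThreshold = NA_real_, proximityRadius = 20,
    cnWindowK = 10, cnKRange = c(3, 15), cnRestarts = 10,
    includeIndexCell = TRUE,
    scWindowK = 100, scThreshold = 0.9, scmMinFraction = 1e-5,
    barycentricPurity = 0.9995,
    coverageDistance = 50, coverageMinCells = 3, boundaryStep = 10,
    randomSeed = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop("unknown configuration parameter(s): ", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  do.call(new, c(list(Class = "PlaConfig"), defaults))
}

setMethod("show", "PlaConfig", function(object) {
  cat("PlaConfig\n")
  for (sl in slotNames(object))
    cat(sprintf("  %-20s %s\n", sl, paste(slot(object, sl), collapse = ", ")))
})

#' Expression matrix with an explicit pre-processing stage
#'
#' Rows are retained cells (named `sample|cell_id`), columns the six markers
#' plus nuclear area. The `stage` slot tracks progression through the
#' transform chain: `raw` -> `arcsinh` -> `scaled`.
#'
#' @slot values numeric matrix, cells x features.
#' @slot stage one of `"raw"`, `"arcsinh"`, `"scaled"`.
#' @export
setClass("ExpressionMatrix", representation(values = "matrix", stage = "character"))

setValidity("ExpressionMatrix", function(object) {
  if (!object@stage %in% c("raw", "arcsinh", "scaled"))
    return("stage must be raw, arcsinh or scaled")
  if (anyNA(object@values)) return("values must contain no missing entries")
  TRUE
})

#' @rdname ExpressionMatrix-class
#' @param values numeric matrix (cells x features).
#' @param stage processing stage flag.
#' @export
expressionMatrix <- function(values, stage = "raw") {
  new("ExpressionMatrix", values = as.matrix(values), stage = stage)
}

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d cells x %d features, stage '%s'\n",
              nrow(object@values), ncol(object@values), object@stage))
})

#' Tumour-nest mask for one sample
#'
#' A set of simple polygons (micron coordinates) outlining tumour nests
#' derived from tumour-cell point density, with the per-cell tumour/stroma
#' assignment for the table the mask was built from. Only nests larger than
#' the configured minimum area (default 100 um^2) are retained.
#'
#' @slot sampleId sample identifier.
#' @slot polygons list of closed rings, each a 2-column (x, y) matrix whose
#'   last vertex repeats the first.
#' @slot areas nest areas in um^2, parallel to `polygons`.
#' @slot region factor (`tumour`/`stroma`) per cell of the source table.
#' @slot threshold density threshold used, cells per um^2.
#' @export
setClass("RegionMask", representation(
  sampleId = "character", polygons = "list", areas = "numeric",
  region = "factor", threshold = "numeric"
))

setValidity("RegionMask", function(object) {
  msg <- character()
  if (length(object@polygons) != length(object@areas))
    msg <- c(msg, "polygons and areas must be parallel")
  for (p in object@polygons) {
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 4L) {
      msg <- c(msg, "each polygon must be a closed ring matrix with >= 4 rows")
      break
    }
    if (any(p[1, ] != p[nrow(p), ])) {
      msg <- c(msg, "polygon rings must be closed (first vertex == last)")
      break
    }
  }
  if (length(object@areas) && any(object@areas <= 0))
    msg <- c(msg, "nest areas must be positive")
  if (!all(levels(object@region) %in% c("tumour", "stroma")))
    msg <- c(msg, "region levels must be tumour/stroma")
  if (length(msg)) msg else TRUE
})

#' @describeIn RegionMask-class number of retained nests.
#' @param x,object a `RegionMask`.
#' @export
nNests <- function(x) length(x@polygons)

#' @describeIn RegionMask-class nest areas (um^2).
#' @export
nestAreas <- function(x) x@areas

#' @describeIn RegionMask-class list of nest polygons.
#' @export
nestPolygons <- function(x) x@polygons

setMethod("show", "RegionMask", function(object) {
  cat(sprintf("RegionMask '%s': %d nest(s), total area %.0f um^2; %d/%d cells in tumour\n",
              object@sampleId, length(object@polygons), sum(object@areas),
              sum(object@region == "tumour"), length(object@region)))
})

#' Fitted cellular-neighbourhood model
#'
#' KMeans model over k-NN window compositions, fitted across all samples of
#' a cohort, together with the inertia curve over the scanned K range and
#' the Kneedle-selected K.
#'
#' @slot K number of neighbourhoods of the fitted model.
#' @slot centroids K x alphabet matrix of window-composition centroids.
#' @slot alphabet label alphabet (cell types, optionally crossed with
#'   isPLA status).
#' @slot inertiaCurve data.frame with columns `K`, `inertia`.
#' @slot selectedK elbow K chosen by the Kneedle rule.
#' @slot variant `"plain"` or `"ispla_augmented"`.
#' @slot windowK window size (number of nearest neighbours).
#' @slot seed RNG seed used for fitting.
#' @export
setClass("NeighbourhoodModel", representation(
  K = "numeric", centroids = "matrix", alphabet = "character",
  inertiaCurve = "data.frame", selectedK = "numeric",
  variant = "character", windowK = "numeric", seed = "numeric"
))

setValidity("NeighbourhoodModel", function(object) {
  msg <- character()
  if (nrow(object@centroids) != object@K)
    msg <- c(msg, "centroids must have K rows")
  if (ncol(object@centroids) != length(object@alphabet))
    msg <- c(msg, "centroid columns must match the alphabet")
  if (!object@variant %in% c("plain", "ispla_augmented"))
    msg <- c(msg, "variant must be plain or ispla_augmented")
  if (length(msg)) msg else TRUE
})

#' @describeIn NeighbourhoodModel-class centroid matrix (K x alphabet).
#' @param x,object a `NeighbourhoodModel`.
#' @export
cnCentroids <- function(x) x@centroids

#' @describeIn NeighbourhoodModel-class inertia curve data.frame.
#' @export
inertiaCurve <- function(x) x@inertiaCurve

#' @describeIn NeighbourhoodModel-class human-readable CN names derived from
#'   dominant centroid components (labels with frequency >= 0.2).
#' @export
cnNames <- function(x) {
  apply(x@centroids, 1L, function(w) {
    top <- order(w, decreasing = TRUE)
    keep <- top[w[top] >= 0.2]
    if (!length(keep)) keep <- top[1L]
    paste(x@alphabet[keep], collapse = " + ")
  })
}

setMethod("show", "NeighbourhoodModel", function(object) {
  cat(sprintf("NeighbourhoodModel (%s): K = %d (selected %d), window k = %d\n",
              object@variant, object@K, object@selectedK, object@windowK))
  nm <- cnNames(object)
  for (i in seq_along(nm)) cat(sprintf("  CN%d: %s\n", i - 1L, nm[i]))
})

#' Spatial-context map graph
#'
#' Directed acyclic graph over minimal CN combinations for one response
#' group: nodes are combinations covering more than `minFraction` of the
#' group's cells; an edge joins a combination to each superset exactly one
#' CN larger.
#'
#' @slot graph an `igraph` directed graph; vertex attributes `name`
#'   (combination id string), `fraction`, `count`, `size`.
#' @slot group response-group label the graph was built for.
#' @slot minFraction node cutoff as a fraction of group cells.
#' @export
setClass("SCMGraph", representation(
  graph = "ANY", group = "character", minFraction = "numeric"
))

setMethod("show", "SCMGraph", function(object) {
  cat(sprintf("SCMGraph '%s': %d combination(s), %d edge(s), cutoff %g\n",
              object@group, igraph::vcount(object@graph),
              igraph::ecount(object@graph), object@minFraction))
})
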