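#' Quality-control filter on nuclear area and DAPI signal
#'
#' Removes artifactual nuclei: cells are retained when
#' `qcMinArea <= nuclear_area <= qcMaxArea` (closed interval, so nuclei of
#' exactly 10 or 220 um^2 survive the default window) and median DAPI is at
#' least `qcMinDapi`. The filter report (counts removed per rule) is
#' attached as the `"qcReport"` attribute and readable with [qcReport()].
#'
#' @param table a [CellTable-class].
#' @param cfg a [plaConfig()] object.
#' @return The filtered [CellTable-class] (with a `qcReport` attribute).
#' @export
qcFilter <- function(table, cfg = plaConfig()) {
  cells <- cellData(table)
  areaOk <- cells$nuclear_area >= cfg@qcMinArea & cells$nuclear_area <= cfg@qcMaxArea
  dapiOk <- cells$DAPI >= cfg@qcMinDapi
  keep <- areaOk & dapiOk
  report <- list(n_input = nrow(cells),
                 n_removed_area = sum(!areaOk),
                 n_removed_dapi = sum(areaOk & !dapiOk),
                 n_retained = sum(keep))
  if (report$n_retained == 0L && report$n_input > 0L)
    warning("QC filter removed every cell of sample ", sampleId(table))
  out <- table
  out@cells <- cells[keep, , drop = FALSE]
  rownames(out@cells) <- NULL
  attr(out, "qcReport") <- report
  out
}

#' @rdname qcFilter
#' @param x a filtered `CellTable`.
#' @export
qcReport <- function(x) attr(x, "qcReport")

#' Assemble the clustering feature matrix
#'
#' Features are the six markers (PanCK, CD20, CD3e, CD8, CD68, isPLA) plus
#' nuclear area; rows are cells of one or more samples, named
#' `sample|cell_id`.
#'
#' @param tables a [CellTable-class] or list of them.
#' @return An [ExpressionMatrix-class] at stage `"raw"`.
#' @export
buildExpressionMatrix <- function(tables) {
  if (is(tables, "CellTable")) tables <- list(tables)
  feats <- c(plaMarkers(), "nuclear_area")
  mats <- lapply(tables, function(tb) {
    m <- as.matrix(cellData(tb)[, feats, drop = FALSE])
    rownames(m) <- paste(sampleId(tb), cellData(tb)$cell_id, sep = "|")
    m
  })
  expressionMatrix(do.call(rbind, mats), stage = "raw")
}

#' Arcsinh variance-stabilising transform
#'
#' Applies `x -> asinh(x / cofactor)` to every feature (default cofactor
#' 150). Nuclear area passes through the same transform by default; set
#' `transformArea = FALSE` to keep it on its raw scale.
#'
#' @param m an [ExpressionMatrix-class] at stage `"raw"`.
#' @param cofactor positive scalar.
#' @param transformArea transform the nuclear-area column too?
#' @return The transformed matrix at stage `"arcsinh"`.
#' @export
arcsinhTransform <- function(m, cofactor = 150, transformArea = TRUE) {
  stopifnot(is(m, "ExpressionMatrix"))
  if (m@stage != "raw") stop("arcsinhTransform expects a raw-stage matrix")
  if (!is.finite(cofactor) || cofactor <= 0) stop("cofactor must be positive")
  v <- m@values
  skip <- if (!transformArea) which(colnames(v) == "nuclear_area") else integer(0)
  cols <- setdiff(seq_len(ncol(v)), skip)
  v[, cols] <- asinh(v[, cols] / cofactor)
  expressionMatrix(v, stage = "arcsinh")
}

.scaleColumns <- function(v, method) {
  if (method == "zscore") {
    mu <- colMeans(v)
    sdv <- apply(v, 2L, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- Inf  # constant column -> zeros
    sweep(sweep(v, 2L, mu, "-"), 2L, sdv, "/")
  } else {
    lo <- apply(v, 2L, min); hi <- apply(v, 2L, max)
    rng <- hi - lo
    rng[rng == 0] <- Inf
    sweep(sweep(v, 2L, lo, "-"), 2L, rng, "/")
  }
}

#' Two-pass scaling: within markers, then across cells
#'
#' Pass 1 standardises each column (marker), pass 2 standardises each row
#' (cell); zero-variance columns or rows map to zeros. With
#' `method = "minmax"` both passes rescale to \[0, 1\] instead. A
#' single-cell input degenerates to all zeros by the constant-column rule.
#'
#' @param m an [ExpressionMatrix-class] at stage `"arcsinh"`.
#' @param method `"zscore"` (default) or `"minmax"`.
#' @return The scaled matrix at stage `"scaled"`.
#' @export
dualScale <- function(m, method = c("zscore", "minmax")) {
  stopifnot(is(m, "ExpressionMatrix"))
  method <- match.arg(method)
  if (m@stage != "arcsinh") stop("dualScale expects an arcsinh-stage matrix")
  v <- .scaleColumns(m@values, method)
  v <- t(.scaleColumns(t(v), method))
  expressionMatrix(v, stage = "scaled")
}

#' Graph-based clustering of the scaled feature matrix
#'
#' Builds an (undirected, unweighted) k-nearest-neighbour graph in feature
#' space — Euclidean distances, ties broken by ascending cell index — and
#' partitions it with Leiden community detection under the modularity
#' objective at the given resolution. Deterministic for a fixed seed.
#'
#' @param m an [ExpressionMatrix-class] at stage `"scaled"`.
#' @param k neighbours per cell (default 30).
#' @param resolution Leiden resolution (default 2).
#' @param seed RNG seed.
#' @return Integer cluster labels `0..C-1`, one per cell.
#' @export
clusterCells <- function(m, k = 30, resolution = 2, seed = 1) {
  stopifnot(is(m, "ExpressionMatrix"))
  if (m@stage != "scaled") stop("clusterCells expects a scaled-stage matrix")
  n <- nrow(m@values)
  if (n < k + 1L) stop("fewer cells than k + 1; reduce k")
  nn <- .knnIndices(m@values, k)
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(as.integer(seed))
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
  labels <- as.integer(igraph::membership(comm)) - 1L
  labels
}

#' Annotate clusters with canonical cell types
#'
#' Each cluster is assigned the cell type whose canonical marker
#' (PanCK -> Tumour, CD20 -> B cell, CD68 -> Macrophage, CD8 -> CD8 T cell,
#' CD3e -> CD3 T cell) has the highest cluster-mean z-score relative to the
#' grand mean of the arcsinh-stage matrix. Clusters whose top two scores
#' differ by less than `1e-6` are resolved by the fixed precedence
#' PanCK > CD20 > CD68 > CD8 > CD3e, which in particular lets CD8 win over
#' CD3e in genuinely ambiguous cytotoxic-T clusters.
#'
#' @param labels integer cluster labels from [clusterCells()].
#' @param mArcsinh the arcsinh-stage [ExpressionMatrix-class] (same rows).
#' @return A list of class `PhenotypeResult`: `cellType` (character per
#'   cell), `cluster` (the input labels) and `annotation` (data.frame with
#'   one row per cluster: id, assigned type, mean canonical-marker values).
#' @export
annotateClusters <- function(labels, mArcsinh) {
  stopifnot(is(mArcsinh, "ExpressionMatrix"))
  v <- mArcsinh@values
  if (length(labels) != nrow(v)) stop("labels must cover all cells")
  markers <- names(.canonicalMarkers)
  grandMean <- colMeans(v[, markers, drop = FALSE])
  grandSd <- apply(v[, markers, drop = FALSE], 2L, stats::sd)
  grandSd[grandSd == 0] <- 1
  ids <- sort(unique(labels))
  ann <- lapply(ids, function(cl) {
    rows <- labels == cl
    mu <- colMeans(v[rows, markers, drop = FALSE])
    z <- (mu - grandMean) / grandSd
    best <- max(z)
    # precedence order of .canonicalMarkers resolves near-ties
    pick <- markers[which(z >= best - 1e-6)[1L]]
    c(list(cluster = cl, cell_type = unname(.canonicalMarkers[pick]),
           n = sum(rows)), as.list(mu))
  })
  annotation <- do.call(rbind, lapply(ann, function(a) as.data.frame(a)))
  typeOf <- stats::setNames(annotation$cell_type, annotation$cluster)
  res <- list(cellType = unname(typeOf[as.character(labels)]),
              cluster = labels, annotation = annotation)
  class(res) <- "PhenotypeResult"
  res
}

#' Full phenotyping chain for a cohort
#'
#' QC-filters every sample, pools the retained cells, applies
#' arcsinh + two-pass scaling, clusters the pooled matrix and annotates the
#' clusters, then writes `cluster` and `cell_type` back onto each table.
#'
#' @param tables a [CellTable-class] or list of them.
#' @param cfg a [plaConfig()] object.
#' @return A list: `tables` (filtered + labelled), `result`
#'   (`PhenotypeResult`), `qc` (per-sample QC reports).
#' @export
phenotypeCells <- function(tables, cfg = plaConfig()) {
  single <- is(tables, "CellTable")
  if (single) tables <- list(tables)
  filtered <- lapply(tables, qcFilter, cfg = cfg)
  qc <- lapply(filtered, qcReport)
  mRaw <- buildExpressionMatrix(filtered)
  mAsinh <- arcsinhTransform(mRaw, cfg@arcsinhCofactor, cfg@transformArea)
  mScaled <- dualScale(mAsinh, cfg@scaleMethod)
  labels <- clusterCells(mScaled, k = cfg@phenotypeKnnK,
                         resolution = cfg@phenotypeResolution,
                         seed = cfg@randomSeed)
  res <- annotateClusters(labels, mAsinh)
  offset <- 0L
  for (i in seq_along(filtered)) {
    n <- length(filtered[[i]])
    idx <- seq_len(n) + offset
    filtered[[i]]@cells$cluster <- res$cluster[idx]
    filtered[[i]]@cells$cell_type <- res$cellType[idx]
    offset <- offset + n
  }
  names(filtered) <- vapply(filtered, sampleId, character(1))
  list(tables = if (single) filtered[[1L]] else filtered, result = res, qc = qc)
}
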