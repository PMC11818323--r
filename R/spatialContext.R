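#' Large CN windows for spatial-context detection
#'
#' Window compositions over CN labels using a large neighbourhood (default
#' the 100 nearest neighbours), the first step of spatial-context (SC)
#' detection. Same window semantics as [knnWindows()].
#'
#' @param table a [CellTable-class] with the CN label column present.
#' @param k window size (default 100).
#' @param cnColumn CN label column, `"cn_label_pla"` (default) or
#'   `"cn_label"`.
#' @param nCN total number of CNs of the fitted model (defines the column
#'   count); defaults to `max(label) + 1`.
#' @param includeIndexCell window convention, as for CN windows.
#' @return Numeric matrix, rows = cells, columns = CN ids `0..nCN-1`;
#'   every row sums to 1.
#' @export
scWindows <- function(table, k = 100, cnColumn = "cn_label_pla",
                      nCN = NULL, includeIndexCell = TRUE) {
  cells <- cellData(table)
  lab <- cells[[cnColumn]]
  if (is.null(lab)) stop("CN labels missing: run discoverCN() first")
  if (is.null(nCN)) nCN <- max(lab) + 1L
  win <- knnWindows(table, k, includeIndexCell)
  windowComposition(win, as.character(lab), as.character(seq_len(nCN) - 1L))
}

#' Minimal CN combination of a window
#'
#' Sorts the CNs of a window by descending frequency (ties by ascending CN
#' id) and returns the shortest prefix whose cumulative frequency strictly
#' exceeds the threshold (default 0.9): if the most abundant CN alone
#' covers more than 90 percent of the window it forms the combination,
#' otherwise CNs are added in abundance order until the threshold is
#' exceeded. The combination identity is the id-sorted tuple.
#'
#' @param freq CN-frequency vector (simplex), or a matrix of such rows.
#' @param threshold cumulative-frequency threshold in (0, 1).
#' @return For a vector: integer vector of CN ids (0-based, ascending).
#'   For a matrix: character vector of combination ids, ids joined by
#'   `"&"`.
#' @export
minimalCombination <- function(freq, threshold = 0.9) {
  stopifnot(threshold > 0, threshold < 1)
  one <- function(v) {
    if (all(v == 0)) stop("all-zero frequency vector")
    ord <- order(-v, seq_along(v))
    m <- which(cumsum(v[ord]) > threshold)[1L]
    if (is.na(m)) m <- length(v)  # guards rounding at sum(v) == threshold
    sort(ord[seq_len(m)]) - 1L
  }
  if (is.matrix(freq))
    return(apply(freq, 1L, function(v) paste(one(v), collapse = "&")))
  one(as.numeric(freq))
}

#' Assign spatial contexts to every cell
#'
#' @param table a [CellTable-class] with CN labels.
#' @param cfg a [plaConfig()] object (`scWindowK`, `scThreshold`).
#' @param cnColumn CN label column to use.
#' @param nCN number of CNs of the model.
#' @return The table with an `sc_combination` character column (CN ids
#'   joined by `"&"`).
#' @export
assignSpatialContext <- function(table, cfg = plaConfig(),
                                 cnColumn = "cn_label_pla", nCN = NULL) {
  w <- scWindows(table, cfg@scWindowK, cnColumn, nCN, cfg@includeIndexCell)
  table@cells$sc_combination <- minimalCombination(w, cfg@scThreshold)
  table
}

#' Build a spatial-context map (SCM) graph
#'
#' Directed graph over the minimal combinations of one response group:
#' nodes are combinations covering strictly more than `minFraction` of the
#' group's cells (default 1e-5, i.e. 0.001 percent); a directed edge joins
#' combination c1 to c2 whenever c1 is a subset of c2 and c2 has exactly
#' one more CN — the "more complex combination" relation. The size-(n to
#' n+1) edge rule makes the graph a DAG.
#'
#' @param combinations character vector of per-cell combination ids
#'   (`"&"`-joined CN ids) for all cells of the group.
#' @param group group label stored on the graph.
#' @param minFraction node cutoff as a fraction of the group's cells.
#' @return An [SCMGraph-class].
#' @export
buildSCMGraph <- function(combinations, group = "all", minFraction = 1e-5) {
  n <- length(combinations)
  tab <- table(combinations)
  frac <- as.numeric(tab) / n
  keep <- frac > minFraction
  ids <- names(tab)[keep]
  counts <- as.integer(tab)[keep]
  fracs <- frac[keep]
  members <- lapply(strsplit(ids, "&", fixed = TRUE), as.integer)
  sizes <- lengths(members)
  edges <- character(0)
  if (length(ids) > 1L) {
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (sizes[j] == sizes[i] + 1L && all(members[[i]] %in% members[[j]]))
        edges <- c(edges, ids[i], ids[j])
    }
  }
  g <- igraph::make_empty_graph(directed = TRUE) + igraph::vertices(ids)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::V(g)$fraction <- fracs
  igraph::V(g)$count <- counts
  igraph::V(g)$size <- sizes
  new("SCMGraph", graph = g, group = group, minFraction = minFraction)
}

#' Export an SCM graph
#'
#' `writeSCMGraph` writes node-link JSON (nodes with combination id,
#' fraction, count, size; links as source/target ids); `writeSCMGraphDot`
#' writes Graphviz DOT.
#'
#' @param scm an [SCMGraph-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSCMGraph <- function(scm, path) {
  g <- scm@graph
  nodes <- data.frame(id = igraph::V(g)$name,
                      fraction = igraph::V(g)$fraction,
                      count = igraph::V(g)$count,
                      size = igraph::V(g)$size, stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  links <- if (nrow(el)) data.frame(source = el[, 1], target = el[, 2],
                                    stringsAsFactors = FALSE)
           else data.frame(source = character(0), target = character(0))
  jsonlite::write_json(list(group = scm@group, minFraction = scm@minFraction,
                            nodes = nodes, links = links),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSCMGraph
#' @export
writeSCMGraphDot <- function(scm, path) {
  igraph::write_graph(scm@graph, path, format = "dot")
  invisible(path)
}

#' Barycentric projection of CN interfaces
#'
#' Restricts windows to those whose mass on three chosen CNs reaches the
#' purity threshold (default 99.95 percent), renormalises the three
#' frequencies and maps them into an equilateral unit triangle whose
#' vertices are the pure CNs: cells at a vertex sit in windows of a single
#' CN, cells on an edge at the interface of two, cells in the middle where
#' all three mix.
#'
#' @param windows CN-frequency window matrix from [scWindows()].
#' @param triple three distinct CN ids (0-based).
#' @param purity minimum window mass on the triple, in (0, 1].
#' @param cnLabels per-cell CN labels used to colour the points.
#' @param cellIds optional cell identifiers.
#' @return data.frame (`cell_id`, `px`, `py`, `cn_label`, plus the three
#'   renormalised weights `w1..w3`) with attributes `triple` and `purity`;
#'   empty (with a warning) when no window qualifies.
#' @export
barycentricProjection <- function(windows, triple, purity = 0.9995,
                                  cnLabels = NULL, cellIds = NULL) {
  stopifnot(length(triple) == 3L, !anyDuplicated(triple),
            purity > 0, purity <= 1)
  cols <- as.character(triple)
  if (!all(cols %in% colnames(windows))) stop("triple outside the CN alphabet")
  mass <- rowSums(windows[, cols, drop = FALSE])
  keep <- which(mass >= purity)
  verts <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  if (!length(keep)) {
    warning("no window reaches the purity threshold; empty projection")
    out <- data.frame(cell_id = character(0), px = numeric(0), py = numeric(0),
                      cn_label = integer(0), w1 = numeric(0), w2 = numeric(0),
                      w3 = numeric(0))
  } else {
    w <- windows[keep, cols, drop = FALSE] / mass[keep]
    xy <- w %*% verts
    out <- data.frame(
      cell_id = if (is.null(cellIds)) as.character(keep) else cellIds[keep],
      px = xy[, 1], py = xy[, 2],
      cn_label = if (is.null(cnLabels)) NA_integer_ else cnLabels[keep],
      w1 = w[, 1], w2 = w[, 2], w3 = w[, 3], stringsAsFactors = FALSE)
  }
  attr(out, "triple") <- triple
  attr(out, "purity") <- purity
  out
}
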