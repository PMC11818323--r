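#' Proximity density of a cell-type pair
#'
#' Counts unordered pairs (a, b) with a of the first type, b of the second,
#' separated by at most `radius` um (closed ball), and divides by the
#' combined number of cells of the two types in the sample:
#' `density = n_pairs / (n_A + n_B)` for distinct types, and
#' `density = n_pairs / n_A` for a type paired with itself (each unordered
#' pair counted once). Types may optionally be restricted to an isPLA
#' state. Computed with a kd-tree radius query, with results identical to
#' the quadratic definition.
#'
#' @param table a [CellTable-class] with `cell_type` (and `ispla_positive`
#'   when states are requested).
#' @param typeA,typeB cell types.
#' @param radius interaction radius, um (default 20).
#' @param isplaA,isplaB optional logical isPLA state restricting each side
#'   (`NA` = either state).
#' @return A one-row data.frame of class `ProximityScore`: `sample_id`,
#'   `type_a`, `type_b`, `n_pairs`, `n_cells`, `density`, `radius`. When a
#'   requested type is absent, `n_pairs` is 0 and the row carries attribute
#'   `flag = "type absent"`.
#' @export
proximityDensity <- function(table, typeA, typeB, radius = 20,
                             isplaA = NA, isplaB = NA) {
  stopifnot(radius > 0)
  cells <- cellData(table)
  if (is.null(cells$cell_type)) stop("cell_type labels required")
  pick <- function(tp, state) {
    sel <- cells$cell_type == tp
    if (!is.na(state)) sel <- sel & cells$ispla_positive == state
    which(sel)
  }
  ia <- pick(typeA, isplaA)
  ib <- pick(typeB, isplaB)
  same <- typeA == typeB && identical(isplaA, isplaB)
  nCells <- if (same) length(ia) else length(ia) + length(ib)
  flag <- NULL
  if (!length(ia) || !length(ib)) {
    nPairs <- 0L
    flag <- "type absent"
  } else if (same) {
    A <- as.matrix(cells[ia, c("x", "y")])
    nPairs <- sum(.radiusCounts(A, A, radius, excludeSelf = TRUE)) / 2
  } else {
    A <- as.matrix(cells[ia, c("x", "y")])
    B <- as.matrix(cells[ib, c("x", "y")])
    nPairs <- sum(.radiusCounts(A, B, radius))
  }
  out <- data.frame(sample_id = sampleId(table), type_a = typeA, type_b = typeB,
                    n_pairs = nPairs, n_cells = nCells,
                    density = if (nCells > 0) nPairs / nCells else NA_real_,
                    radius = radius, stringsAsFactors = FALSE)
  class(out) <- c("ProximityScore", class(out))
  if (!is.null(flag)) attr(out, "flag") <- flag
  out
}

#' Proximity densities for a list of type pairs
#'
#' @param table a [CellTable-class].
#' @param pairs list of length-2 character vectors of cell types.
#' @param radius interaction radius, um.
#' @return data.frame with one [proximityDensity()] row per pair.
#' @export
proximityDensityTable <- function(table, pairs, radius = 20) {
  out <- do.call(rbind, lapply(pairs, function(p)
    proximityDensity(table, p[1L], p[2L], radius = radius)))
  rownames(out) <- NULL
  out
}
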