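#' Build the tumour/stroma mask from tumour-cell point density
#'
#' Rasterises the density of `Tumour`-phenotyped cells on a regular grid
#' (default 20 um pitch, origin fixed at the data bounding box so the mask
#' is translation-equivariant), smooths it with a Gaussian (default sigma of
#' one grid cell), thresholds it and extracts iso-contour polygons. The
#' default threshold is half the mean smoothed density over grid cells that
#' contain at least one tumour cell; `cfg@maskThreshold` (cells/um^2)
#' overrides it. Nests with area at or below `cfg@maskMinNestArea` (default
#' 100 um^2) are discarded, and every cell is labelled `tumour` when it
#' lies inside or on the boundary of a retained nest, `stroma` otherwise.
#'
#' @param table a [CellTable-class] with `cell_type` labels.
#' @param cfg a [plaConfig()] object.
#' @return A [RegionMask-class].
#' @export
buildTumourMask <- function(table, cfg = plaConfig()) {
  cells <- cellData(table)
  if (is.null(cells$cell_type)) stop("cell_type labels required; run phenotyping first")
  emptyMask <- function() {
    warning("no tumour nests found in sample ", sampleId(table), "; all cells stroma")
    new("RegionMask", sampleId = sampleId(table), polygons = list(),
        areas = numeric(0),
        region = factor(rep("stroma", nrow(cells)), levels = c("tumour", "stroma")),
        threshold = NA_real_)
  }
  tum <- cells[cells$cell_type == "Tumour", c("x", "y"), drop = FALSE]
  if (nrow(cells) == 0L || nrow(tum) == 0L) return(emptyMask())

  pitch <- cfg@maskGridPitch
  x0 <- min(cells$x); y0 <- min(cells$y)
  nx <- max(1L, ceiling((max(cells$x) - x0) / pitch))
  ny <- max(1L, ceiling((max(cells$y) - y0) / pitch))
  ix <- pmin(nx, pmax(1L, ceiling((tum$x - x0) / pitch + 1e-12)))
  iy <- pmin(ny, pmax(1L, ceiling((tum$y - y0) / pitch + 1e-12)))
  counts <- matrix(0, nx, ny)
  for (i in seq_along(ix)) counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1
  density <- counts / pitch^2
  sm <- .gaussSmooth(density, cfg@maskSigma)

  thr <- cfg@maskThreshold
  if (!is.finite(thr)) thr <- 0.5 * mean(sm[counts > 0])
  if (!is.finite(thr) || thr <= 0) return(emptyMask())

  # pad with a zero ring so every contour closes
  pad <- matrix(0, nx + 2L, ny + 2L)
  pad[2:(nx + 1L), 2:(ny + 1L)] <- sm
  xc <- x0 + (seq_len(nx + 2L) - 1.5) * pitch
  yc <- y0 + (seq_len(ny + 2L) - 1.5) * pitch
  cl <- grDevices::contourLines(xc, yc, pad, levels = thr)
  rings <- list(); areas <- numeric(0)
  for (cc in cl) {
    ring <- cbind(cc$x, cc$y)
    if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    if (nrow(ring) < 4L) next
    a <- .polygonArea(ring)
    if (a > cfg@maskMinNestArea) {
      rings[[length(rings) + 1L]] <- ring
      areas <- c(areas, a)
    }
  }
  if (!length(rings)) return(emptyMask())
  inside <- .inAnyRing(cells$x, cells$y, rings)
  new("RegionMask", sampleId = sampleId(table), polygons = rings, areas = areas,
      region = factor(ifelse(inside, "tumour", "stroma"),
                      levels = c("tumour", "stroma")),
      threshold = thr)
}

#' Signed distance of every cell to the tumour boundary
#'
#' Distance to the nearest nest-polygon boundary, negative for cells inside
#' a nest (cells exactly on a boundary get distance 0 and count as tumour).
#' With an empty mask the distances are undefined and returned as `NA`
#' (never infinite), with a warning.
#'
#' @param table a [CellTable-class].
#' @param mask a [RegionMask-class] for the same sample.
#' @return data.frame with `cell_id`, `distance` (um), `nearest_nest`
#'   (1-based nest index) and `region`.
#' @export
signedBoundaryDistance <- function(table, mask) {
  cells <- cellData(table)
  if (nNests(mask) == 0L) {
    warning("empty mask: boundary distances undefined for sample ", sampleId(table))
    return(data.frame(cell_id = cells$cell_id, distance = NA_real_,
                      nearest_nest = NA_integer_,
                      region = factor(rep("stroma", nrow(cells)),
                                      levels = c("tumour", "stroma"))))
  }
  sd <- .signedDistToRings(cells$x, cells$y, mask@polygons)
  data.frame(cell_id = cells$cell_id,
             distance = ifelse(sd$inside, -abs(sd$dist), abs(sd$dist)),
             nearest_nest = sd$nest,
             region = factor(ifelse(sd$inside, "tumour", "stroma"),
                             levels = c("tumour", "stroma")))
}

#' Attach region and boundary-distance labels to a cell table
#'
#' @param table a [CellTable-class].
#' @param mask a [RegionMask-class].
#' @return The table with `region`, `boundary_dist` and `nearest_nest`
#'   columns added.
#' @export
assignRegions <- function(table, mask) {
  bd <- signedBoundaryDistance(table, mask)
  table@cells$region <- as.character(bd$region)
  table@cells$boundary_dist <- bd$distance
  table@cells$nearest_nest <- bd$nearest_nest
  table
}

#' Distance-density profiles by group
#'
#' Histogram of signed boundary distances per group, normalised so that
#' every group's profile sums to one ("normalized cell count"). Bins are
#' aligned so that 0 (the tumour boundary) is a bin edge; negative bins lie
#' inside the tumour.
#'
#' @param distances numeric vector of signed distances, um.
#' @param groups data.frame (or list) of parallel grouping vectors, e.g.
#'   cell type, isPLA status, response group; may be omitted for a single
#'   pooled profile.
#' @param binWidth bin width, um (default 25).
#' @return data.frame with the grouping columns, `bin_left`, `bin_mid` and
#'   `density`; per-group densities sum to 1.
#' @export
distanceDensityProfile <- function(distances, groups = NULL, binWidth = 25) {
  ok <- is.finite(distances)
  if (!is.null(groups)) {
    groups <- as.data.frame(groups, stringsAsFactors = FALSE)
    groups <- groups[ok, , drop = FALSE]
  }
  distances <- distances[ok]
  if (!length(distances)) {
    warning("no finite distances; empty profile")
    return(data.frame(bin_left = numeric(0), bin_mid = numeric(0),
                      density = numeric(0)))
  }
  breaks <- seq(binWidth * floor(min(distances) / binWidth),
                binWidth * ceiling(max(distances) / binWidth + 1e-12), by = binWidth)
  if (length(breaks) < 2L) breaks <- c(breaks, breaks + binWidth)
  bins <- cut(distances, breaks, right = FALSE, include.lowest = FALSE)
  key <- if (is.null(groups)) rep("all", length(distances)) else
    do.call(paste, c(groups, sep = "\r"))
  out <- lapply(split(seq_along(distances), key), function(idx) {
    cnt <- table(bins[idx])
    data.frame(bin_left = breaks[-length(breaks)],
               bin_mid = breaks[-length(breaks)] + binWidth / 2,
               density = as.numeric(cnt) / length(idx))
  })
  res <- do.call(rbind, Map(function(df, k) {
    if (!is.null(groups)) {
      g <- strsplit(k, "\r", fixed = TRUE)[[1L]]
      for (j in seq_along(groups)) df[[names(groups)[j]]] <- g[j]
      df <- df[, c(names(groups), "bin_left", "bin_mid", "density"), drop = FALSE]
    }
    df
  }, out, names(out)))
  rownames(res) <- NULL
  res
}
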