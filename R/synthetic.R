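#' Describe a synthetic tissue architecture
#'
#' Builds the parameter set for [generateTissue()]. Three archetypes capture
#' the geometries the analysis targets: `"barrier"` adds a dense
#' macrophage band hugging the outside of every tumour nest (the
#' non-responder-like phenotype), `"tls"` adds organised B/T-cell aggregates
#' just outside nest boundaries (responder-like tertiary lymphoid
#' structures), and `"neutral"` has neither. Any preset value can be
#' overridden, and the band and aggregates can be combined freely.
#'
#' Defaults emulate moderately cellular carcinoma tissue: a 1500 x 1500 um
#' field, three tumour nests of mean radius 180 um drawn as low-order
#' Fourier-perturbed circles, 0.005 cells/um^2 inside nests and
#' 0.002 cells/um^2 in stroma (about 5,000 cells per field), a 200 um
#' barrier band, 60 um aggregates, and an isPLA-positive probability that
#' decays with distance d from the nest boundary as `exp(-d / 150)`.
#'
#' @param archetype `"neutral"`, `"barrier"` or `"tls"`.
#' @param fieldSize field width and height, um.
#' @param nNests number of tumour nests.
#' @param nestRadiusMean,nestRadiusSd nest radius distribution, um.
#' @param tumourDensity,stromaDensity cell densities, cells/um^2.
#' @param tumourMixture,stromaMixture named cell-type proportions per
#'   compartment (must sum to 1).
#' @param barrierBandWidth width of the peritumoural band, um.
#' @param barrierMacrophageDensity extra macrophage density inside the band,
#'   cells/um^2 (0 disables the band).
#' @param tlsAggregateCount,tlsAggregateRadius number and radius (um) of
#'   B/T-cell aggregates (0 disables them).
#' @param tlsAggregateOffset range (um) of aggregate-centre distances
#'   outside the nest boundary; default 0--100 um puts aggregates at the
#'   tumour edge.
#' @param tlsDensity cell density inside aggregates, cells/um^2.
#' @param tlsMixture cell-type proportions inside aggregates.
#' @param isplaBoundaryScale decay length (um) of the isPLA-positive
#'   probability with distance from the nest boundary.
#' @param isplaBaseProb named per-type isPLA-positive probability at the
#'   boundary (distance 0).
#' @param markerMeans cell-type x marker matrix of mean intensities for the
#'   five phenotyping markers (isPLA is modelled separately).
#' @param markerSdlog log-normal noise sd (log scale) for all channels.
#' @param isplaBaseMean,isplaPositiveShift isPLA channel model: every cell
#'   gets log-normal baseline signal with this mean; truly interacting cells
#'   add a log-normal shift with mean `isplaPositiveShift`.
#' @param dapiMean mean DAPI intensity.
#' @param areaMeanlog named per-type mean of log nuclear area (um^2).
#' @param areaSdlog log sd of nuclear area.
#' @param artifactFraction proportion of cells drawn outside the 10--220
#'   um^2 QC window (segmentation artifacts).
#' @return A list of class `TissueArchitecture`.
#' @export
tissueArchitecture <- function(archetype = c("neutral", "barrier", "tls"),
                               fieldSize = c(1500, 1500),
                               nNests = 3, nestRadiusMean = 180, nestRadiusSd = 30,
                               tumourDensity = 0.005, stromaDensity = 0.002,
                               tumourMixture = c("B cell" = 0.02, "CD3 T cell" = 0.04,
                                                 "CD8 T cell" = 0.02, "Macrophage" = 0.04,
                                                 "Tumour" = 0.88),
                               stromaMixture = c("B cell" = 0.18, "CD3 T cell" = 0.30,
                                                 "CD8 T cell" = 0.22, "Macrophage" = 0.26,
                                                 "Tumour" = 0.04),
                               barrierBandWidth = 200,
                               barrierMacrophageDensity = if (match.arg(archetype) == "barrier") 0.0025 else 0,
                               tlsAggregateCount = if (match.arg(archetype) == "tls") 3 else 0,
                               tlsAggregateRadius = 60,
                               tlsAggregateOffset = c(0, 100),
                               tlsDensity = 0.006,
                               tlsMixture = c("B cell" = 0.60, "CD3 T cell" = 0.25,
                                              "CD8 T cell" = 0.15, "Macrophage" = 0,
                                              "Tumour" = 0),
                               isplaBoundaryScale = 150,
                               isplaBaseProb = c("B cell" = 0.50, "CD3 T cell" = 0.45,
                                                 "CD8 T cell" = 0.45, "Macrophage" = 0.60,
                                                 "Tumour" = 0.35),
                               markerMeans = NULL,
                               markerSdlog = 0.35,
                               isplaBaseMean = 20, isplaPositiveShift = 150,
                               dapiMean = 800,
                               areaMeanlog = c("B cell" = log(30), "CD3 T cell" = log(35),
                                               "CD8 T cell" = log(35), "Macrophage" = log(60),
                                               "Tumour" = log(80)),
                               areaSdlog = 0.30,
                               artifactFraction = 0.05) {
  archetype <- match.arg(archetype)
  if (is.null(markerMeans)) {
    # canonical marker bright (500), off-target bleed dim (30); CD8 T cells
    # co-express CD3e at intermediate level, as real cytotoxic T cells do
    markerMeans <- matrix(30, nrow = 5, ncol = 5,
                          dimnames = list(plaCellTypes(),
                                          c("PanCK", "CD20", "CD3e", "CD8", "CD68")))
    markerMeans["Tumour", "PanCK"] <- 500
    markerMeans["B cell", "CD20"] <- 500
    markerMeans["CD3 T cell", "CD3e"] <- 500
    markerMeans["CD8 T cell", "CD8"] <- 500
    markerMeans["CD8 T cell", "CD3e"] <- 250
    markerMeans["Macrophage", "CD68"] <- 500
  }
  arch <- list(archetype = archetype, fieldSize = fieldSize, nNests = nNests,
               nestRadiusMean = nestRadiusMean, nestRadiusSd = nestRadiusSd,
               tumourDensity = tumourDensity, stromaDensity = stromaDensity,
               tumourMixture = tumourMixture, stromaMixture = stromaMixture,
               barrierBandWidth = barrierBandWidth,
               barrierMacrophageDensity = barrierMacrophageDensity,
               tlsAggregateCount = tlsAggregateCount,
               tlsAggregateRadius = tlsAggregateRadius,
               tlsAggregateOffset = tlsAggregateOffset,
               tlsDensity = tlsDensity, tlsMixture = tlsMixture,
               isplaBoundaryScale = isplaBoundaryScale,
               isplaBaseProb = isplaBaseProb,
               markerMeans = markerMeans, markerSdlog = markerSdlog,
               isplaBaseMean = isplaBaseMean, isplaPositiveShift = isplaPositiveShift,
               dapiMean = dapiMean, areaMeanlog = areaMeanlog, areaSdlog = areaSdlog,
               artifactFraction = artifactFraction)
  .validateArchitecture(arch)
  class(arch) <- "TissueArchitecture"
  arch
}

.validateArchitecture <- function(a) {
  if (any(a$fieldSize <= 0)) stop("configuration error: zero-area field")
  for (mx in list(a$tumourMixture, a$stromaMixture)) {
    if (!length(mx) || abs(sum(mx) - 1) > 1e-9)
      stop("configuration error: compartment mixtures must be non-empty and sum to 1")
    if (any(!names(mx) %in% plaCellTypes())) stop("unknown cell type in mixture")
  }
  if (a$tlsAggregateCount > 0 && abs(sum(a$tlsMixture) - 1) > 1e-9)
    stop("configuration error: tlsMixture must sum to 1")
  if (a$artifactFraction < 0 || a$artifactFraction >= 1)
    stop("artifactFraction must lie in [0, 1)")
  lens <- c(a$nestRadiusMean, a$barrierBandWidth, a$tlsAggregateRadius,
            a$isplaBoundaryScale)
  if (any(lens <= 0)) stop("all length parameters must be positive")
  invisible(TRUE)
}

# place nest centres with rejection on minimum separation
.placeNests <- function(a) {
  margin <- a$nestRadiusMean * 1.3
  minSep <- 2.4 * a$nestRadiusMean
  centres <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(centres) < a$nNests && tries < 5000L) {
    tries <- tries + 1L
    cand <- c(stats::runif(1, margin, a$fieldSize[1] - margin),
              stats::runif(1, margin, a$fieldSize[2] - margin))
    if (!nrow(centres) ||
        min(sqrt((centres[, 1] - cand[1])^2 + (centres[, 2] - cand[2])^2)) >= minSep)
      centres <- rbind(centres, cand)
  }
  # relax separation if the field is crowded
  while (nrow(centres) < a$nNests) {
    centres <- rbind(centres, c(stats::runif(1, margin, a$fieldSize[1] - margin),
                                stats::runif(1, margin, a$fieldSize[2] - margin)))
  }
  centres
}

.samplePoisson <- function(density, area) stats::rpois(1L, density * area)

#' Generate one synthetic tissue sample with ground truth
#'
#' Forward model of the tissue geometries the pipeline analyses. Cells are
#' placed by inhomogeneous Poisson sampling per compartment (uniform
#' candidates over the field thinned by the compartment indicator, which is
#' an exact Poisson process on the compartment): tumour cells inside
#' Fourier-perturbed circular nests, stromal cells outside, an optional
#' macrophage band within `barrierBandWidth` um outside nest boundaries and
#' optional B/T-cell aggregate discs centred 0--100 um outside boundaries.
#' The true isPLA-interaction probability decays as
#' `isplaBaseProb[type] * exp(-d / isplaBoundaryScale)` with d the distance
#' to the nearest nest boundary. Marker intensities are log-normal around
#' the cell type's mean vector (with off-target bleed-through), the isPLA
#' channel is log-normal baseline plus a positive shift for truly
#' interacting cells, and a small `artifactFraction` of nuclei is drawn
#' outside the 10--220 um^2 QC window.
#'
#' @param arch a [tissueArchitecture()] object.
#' @param seed integer seed; identical seeds give identical tissues.
#' @param sampleId sample identifier stored on the table.
#' @return A list with elements `table` (a [CellTable-class]) and `truth`
#'   (class `GroundTruth`: data.frame `cells` with `cell_id`, `true_type`,
#'   `true_ispla`, `compartment`, `boundary_dist`; list `polygons` of nest
#'   rings; numeric `areas`).
#' @export
generateTissue <- function(arch, seed, sampleId = sprintf("synth-%d", seed)) {
  stopifnot(inherits(arch, "TissueArchitecture"))
  .validateArchitecture(arch)
  set.seed(as.integer(seed))
  W <- arch$fieldSize[1]; H <- arch$fieldSize[2]
  fieldArea <- W * H

  centres <- .placeNests(arch)
  radii <- pmax(60, stats::rnorm(arch$nNests, arch$nestRadiusMean, arch$nestRadiusSd))
  rings <- lapply(seq_len(arch$nNests), function(i)
    .blobRing(centres[i, 1], centres[i, 2], radii[i]))
  areas <- vapply(rings, .polygonArea, numeric(1))

  px <- numeric(0); py <- numeric(0)
  type <- character(0); compartment <- character(0)

  addCells <- function(x, y, tp, comp) {
    px <<- c(px, x); py <<- c(py, y)
    type <<- c(type, rep_len(tp, length(x)))
    compartment <<- c(compartment, rep_len(comp, length(x)))
  }
  drawTypes <- function(n, mixture)
    sample(names(mixture), n, replace = TRUE, prob = mixture)

  # tumour nests (thinning: uniform candidates kept inside a nest)
  nT <- .samplePoisson(arch$tumourDensity, fieldArea)
  if (nT > 0) {
    cx <- stats::runif(nT, 0, W); cy <- stats::runif(nT, 0, H)
    nestId <- rep(NA_integer_, nT)
    for (i in seq_along(rings)) {
      hit <- is.na(nestId) & sp::point.in.polygon(cx, cy, rings[[i]][, 1], rings[[i]][, 2]) > 0
      nestId[hit] <- i
    }
    keep <- !is.na(nestId)
    if (any(keep))
      addCells(cx[keep], cy[keep], drawTypes(sum(keep), arch$tumourMixture),
               sprintf("nest%d", nestId[keep]))
  }

  # stroma (outside all nests)
  nS <- .samplePoisson(arch$stromaDensity, fieldArea)
  if (nS > 0) {
    cx <- stats::runif(nS, 0, W); cy <- stats::runif(nS, 0, H)
    keep <- !.inAnyRing(cx, cy, rings)
    if (any(keep))
      addCells(cx[keep], cy[keep], drawTypes(sum(keep), arch$stromaMixture), "stroma")
  }

  # peritumoural macrophage band
  if (arch$barrierMacrophageDensity > 0) {
    nB <- .samplePoisson(arch$barrierMacrophageDensity, fieldArea)
    if (nB > 0) {
      cx <- stats::runif(nB, 0, W); cy <- stats::runif(nB, 0, H)
      sd <- .signedDistToRings(cx, cy, rings)
      keep <- sd$dist > 0 & sd$dist <= arch$barrierBandWidth
      if (any(keep))
        addCells(cx[keep], cy[keep], rep("Macrophage", sum(keep)), "band")
    }
  }

  # lymphoid aggregates just outside nest boundaries
  aggregates <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "radius")))
  if (arch$tlsAggregateCount > 0) {
    for (j in seq_len(arch$tlsAggregateCount)) {
      ri <- sample.int(length(rings), 1L)
      ring <- rings[[ri]]
      vi <- sample.int(nrow(ring) - 1L, 1L)
      v <- ring[vi, ]
      dir <- v - centres[ri, ]
      dir <- dir / sqrt(sum(dir^2))
      centre <- v + dir * stats::runif(1, arch$tlsAggregateOffset[1],
                                       arch$tlsAggregateOffset[2])
      aggregates <- rbind(aggregates, c(centre, arch$tlsAggregateRadius))
      nA <- .samplePoisson(arch$tlsDensity, pi * arch$tlsAggregateRadius^2)
      if (nA > 0) {
        rr <- arch$tlsAggregateRadius * sqrt(stats::runif(nA))
        th <- stats::runif(nA, 0, 2 * pi)
        addCells(centre[1] + rr * cos(th), centre[2] + rr * sin(th),
                 drawTypes(nA, arch$tlsMixture), sprintf("aggregate%d", j))
      }
    }
  }

  n <- length(px)
  if (n == 0) stop("configuration error: generated an empty tissue")

  # ground-truth boundary distances and isPLA state
  sd <- .signedDistToRings(px, py, rings)
  dBoundary <- abs(sd$dist)
  signedDist <- ifelse(sd$inside, -dBoundary, dBoundary)
  pPos <- arch$isplaBaseProb[type] * exp(-dBoundary / arch$isplaBoundaryScale)
  isplaTrue <- stats::runif(n) < pPos

  # intensities: log-normal around the type's marker means
  mk <- arch$markerMeans
  intens <- sapply(colnames(mk), function(ch)
    stats::rlnorm(n, meanlog = log(mk[type, ch]), sdlog = arch$markerSdlog))
  ispla <- stats::rlnorm(n, log(arch$isplaBaseMean), 0.5)
  if (any(isplaTrue))
    ispla[isplaTrue] <- ispla[isplaTrue] +
      stats::rlnorm(sum(isplaTrue), log(arch$isplaPositiveShift), 0.4)
  dapi <- stats::rlnorm(n, log(arch$dapiMean), 0.2)

  # nuclear areas: truncated to the QC window, then a fraction re-drawn as
  # artifacts outside it
  area <- stats::rlnorm(n, arch$areaMeanlog[type], arch$areaSdlog)
  for (i in 1:20) {
    out <- area < 10.5 | area > 219
    if (!any(out)) break
    area[out] <- stats::rlnorm(sum(out), arch$areaMeanlog[type][out], arch$areaSdlog)
  }
  area <- pmin(pmax(area, 10.5), 219)
  nArt <- round(arch$artifactFraction * n)
  if (nArt > 0) {
    ai <- sample.int(n, nArt)
    small <- stats::runif(nArt) < 0.5
    area[ai] <- ifelse(small, stats::runif(nArt, 2, 9.5), stats::runif(nArt, 221, 400))
  }

  ids <- sprintf("c%06d", seq_len(n))
  cells <- data.frame(cell_id = ids, x = px, y = py, nuclear_area = area,
                      PanCK = intens[, "PanCK"], CD20 = intens[, "CD20"],
                      CD3e = intens[, "CD3e"], CD8 = intens[, "CD8"],
                      CD68 = intens[, "CD68"], isPLA = ispla, DAPI = dapi,
                      stringsAsFactors = FALSE)
  truth <- list(cells = data.frame(cell_id = ids, x = px, y = py,
                                   true_type = type,
                                   true_ispla = isplaTrue,
                                   compartment = compartment,
                                   boundary_dist = signedDist,
                                   stringsAsFactors = FALSE),
                polygons = rings, areas = areas, aggregates = aggregates,
                bandWidth = if (arch$barrierMacrophageDensity > 0)
                  arch$barrierBandWidth else 0)
  class(truth) <- "GroundTruth"
  list(table = cellTable(cells, sampleId), truth = truth)
}

#' Generate a synthetic patient cohort
#'
#' One tissue per sample: PD and SD samples use the `"barrier"` archetype,
#' CR and PR the `"tls"` archetype, with mild within-group parameter spread
#' (nest count, nest radius, band width / aggregate count). Default counts
#' mirror a 14-sample response cohort (CR = 2, PR = 4, SD = 2, PD = 6).
#'
#' @param nPerGroup named counts per response group.
#' @param seed master integer seed; per-sample seeds are derived from it.
#' @param ... overrides forwarded to [tissueArchitecture()] for every sample.
#' @return A list with `tables` (list of [CellTable-class]), `metadata`
#'   (data.frame: sample_id, patient_id, response_group) and `truths`
#'   (list of `GroundTruth`).
#' @export
generateCohort <- function(nPerGroup = c(CR = 2, PR = 4, SD = 2, PD = 6),
                           seed = 1, ...) {
  stopifnot(all(nPerGroup >= 0))
  groups <- rep(names(nPerGroup), times = nPerGroup)
  n <- length(groups)
  meta <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                     patient_id = sprintf("P%02d", seq_len(n)),
                     response_group = factor(groups, levels = c("CR", "PR", "SD", "PD")),
                     stringsAsFactors = FALSE)
  if (n == 0)
    return(list(tables = list(), metadata = meta[0, ], truths = list()))
  set.seed(as.integer(seed))
  sampleSeeds <- sample.int(.Machine$integer.max - 1L, n)
  spread <- data.frame(nNests = sample(2:4, n, replace = TRUE),
                       radius = stats::rnorm(n, 180, 15),
                       band = stats::rnorm(n, 200, 15),
                       nAgg = sample(2:4, n, replace = TRUE))
  tables <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    archetype <- if (groups[i] %in% c("PD", "SD")) "barrier" else "tls"
    arch <- tissueArchitecture(archetype = archetype,
                               nNests = spread$nNests[i],
                               nestRadiusMean = max(120, spread$radius[i]),
                               barrierBandWidth = max(150, spread$band[i]),
                               tlsAggregateCount = if (archetype == "tls") spread$nAgg[i] else 0,
                               ...)
    out <- generateTissue(arch, sampleSeeds[i], sampleId = meta$sample_id[i])
    tables[[i]] <- out$table
    truths[[i]] <- out$truth
  }
  names(tables) <- names(truths) <- meta$sample_id
  list(tables = tables, metadata = meta, truths = truths)
}

#' Location-based ground-truth compartments
#'
#' Assigns every generated cell the compartment of the tissue location it
#' occupies — `tumour` (inside a nest), `aggregate` (inside an aggregate
#' disc), `band` (within the barrier band outside a nest, when the
#' architecture has one) or `stroma` — regardless of which generating
#' process placed it. This is the natural target for neighbourhood
#' recovery: a stromal cell sitting inside the macrophage band genuinely
#' lives in a macrophage neighbourhood.
#'
#' @param truth a `GroundTruth` from [generateTissue()].
#' @return Character vector of compartments, parallel to `truth$cells`.
#' @export
spatialCompartments <- function(truth) {
  d <- truth$cells$boundary_dist
  comp <- rep("stroma", length(d))
  comp[d <= 0] <- "tumour"
  if (truth$bandWidth > 0)
    comp[d > 0 & d <= truth$bandWidth] <- "band"
  if (nrow(truth$aggregates)) {
    for (i in seq_len(nrow(truth$aggregates))) {
      a <- truth$aggregates[i, ]
      inDisc <- (truth$cells$x - a["x"])^2 + (truth$cells$y - a["y"])^2 <= a["radius"]^2
      comp[inDisc & d > 0] <- "aggregate"
    }
  }
  comp
}

#' Export ground-truth nest polygons as GeoJSON
#'
#' @param truth a `GroundTruth` object from [generateTissue()].
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
writeNestGeoJSON <- function(truth, path) {
  features <- lapply(seq_along(truth$polygons), function(i) {
    ring <- truth$polygons[[i]]
    list(type = "Feature",
         properties = list(nest = i, area_um2 = truth$areas[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) c(ring[j, 1], ring[j, 2])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
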