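# Shared fixtures, built in code at test time.

# minimal valid per-cell data.frame
makeCells <- function(n, seed = 1, types = NULL) {
  set.seed(seed)
  df <- data.frame(
    cell_id = sprintf("c%04d", seq_len(n)),
    x = stats::runif(n, 0, 1000), y = stats::runif(n, 0, 1000),
    nuclear_area = stats::runif(n, 20, 120),
    PanCK = stats::rlnorm(n, 3), CD20 = stats::rlnorm(n, 3),
    CD3e = stats::rlnorm(n, 3), CD8 = stats::rlnorm(n, 3),
    CD68 = stats::rlnorm(n, 3), isPLA = stats::rlnorm(n, 2),
    DAPI = stats::rlnorm(n, 6), stringsAsFactors = FALSE)
  if (!is.null(types)) df$cell_type <- sample(types, n, replace = TRUE)
  df
}

makeTable <- function(n, seed = 1, types = NULL, sampleId = "test") {
  cellTable(makeCells(n, seed, types), sampleId)
}

# closed ring approximating a circle
circleRing <- function(cx, cy, r, nV = 720L) {
  th <- seq(0, 2 * pi, length.out = nV + 1L)[-(nV + 1L)]
  ring <- cbind(cx + r * cos(th), cy + r * sin(th))
  rbind(ring, ring[1L, ])
}

# a RegionMask built directly from rings (bypassing density contouring)
maskFromRings <- function(rings, nCellRegion = 0L, sampleId = "manual") {
  new("RegionMask", sampleId = sampleId, polygons = rings,
      areas = vapply(rings, plaScape:::.polygonArea, numeric(1)),
      region = factor(rep("stroma", nCellRegion), levels = c("tumour", "stroma")),
      threshold = NA_real_)
}

# architecture planting four distinct spatial archetypes (tumour nest,
# peritumoural macrophage band, detached B-cell aggregates, T-cell stroma)
# with compositions pure enough for neighbourhood recovery
plantedArchitecture <- function() {
  tissueArchitecture("barrier",
    fieldSize = c(2400, 2400), nNests = 2,
    nestRadiusMean = 280, nestRadiusSd = 20,
    tumourDensity = 0.006, stromaDensity = 0.002,
    tumourMixture = c(Tumour = 1),
    stromaMixture = c("CD3 T cell" = 0.95, "CD8 T cell" = 0.02,
                      "Macrophage" = 0.01, "B cell" = 0.02),
    barrierMacrophageDensity = 0.012, barrierBandWidth = 250,
    tlsAggregateCount = 5, tlsAggregateRadius = 100, tlsDensity = 0.02,
    tlsAggregateOffset = c(420, 560),
    tlsMixture = c("B cell" = 1))
}

# adjusted Rand index (contingency-table closed form), kept independent of
# any clustering code under test
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  sumA <- sum(choose(rowSums(tab), 2))
  sumB <- sum(choose(colSums(tab), 2))
  expected <- sumA * sumB / choose(n, 2)
  maxidx <- (sumA + sumB) / 2
  if (maxidx == expected) return(1)
  (sumij - expected) / (maxidx - expected)
}

# brute-force k nearest neighbours by (distance, index)
bruteKnn <- function(coords, k) {
  n <- nrow(coords)
  t(vapply(seq_len(n), function(i) {
    d <- sqrt((coords[, 1] - coords[i, 1])^2 + (coords[, 2] - coords[i, 2])^2)
    ord <- order(d, seq_len(n))
    ord <- ord[ord != i]
    ord[seq_len(k)]
  }, integer(k)))
}

# brute-force unordered pair count within radius
brutePairs <- function(A, B, r, same = FALSE) {
  cnt <- 0L
  if (same) {
    n <- nrow(A)
    if (n < 2L) return(0L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      if (sqrt(sum((A[i, ] - A[j, ])^2)) <= r) cnt <- cnt + 1L
  } else {
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
      if (sqrt(sum((A[i, ] - B[j, ])^2)) <= r) cnt <- cnt + 1L
  }
  cnt
}
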