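#' Spatial k-nearest-neighbour windows
#'
#' For each cell, its `k` spatially nearest other cells (Euclidean distance,
#' distance ties broken by ascending cell index). By default the window
#' includes the index cell itself, giving windows of size `k + 1`.
#'
#' @param table a [CellTable-class] with at least `k + 1` cells.
#' @param k number of neighbours (default 10).
#' @param includeIndexCell include the index cell in its own window?
#' @return Integer matrix, one row per cell, of row indices into the table;
#'   the first column is the index cell itself when included.
#' @export
knnWindows <- function(table, k = 10, includeIndexCell = TRUE) {
  cells <- cellData(table)
  nn <- .knnIndices(as.matrix(cells[, c("x", "y")]), k)
  if (includeIndexCell) cbind(seq_len(nrow(cells)), nn) else nn
}

#' Window label compositions
#'
#' Converts neighbour windows into the frequency of each label of an
#' alphabet within the window; every row sums to one.
#'
#' @param windows integer index matrix from [knnWindows()].
#' @param labels per-cell labels (length = number of cells).
#' @param alphabet label alphabet defining the column order; defaults to the
#'   sorted unique labels.
#' @return Numeric matrix, rows = cells, columns = alphabet.
#' @export
windowComposition <- function(windows, labels, alphabet = sort(unique(labels))) {
  labels <- as.character(labels)
  code <- match(labels, alphabet)
  if (anyNA(code))
    stop("label(s) outside the alphabet: ",
         paste(unique(labels[is.na(code)]), collapse = ", "))
  lw <- matrix(code[windows], nrow = nrow(windows))
  comp <- vapply(seq_along(alphabet), function(j) rowSums(lw == j),
                 numeric(nrow(windows)))
  comp <- matrix(comp, nrow = nrow(windows),
                 dimnames = list(NULL, alphabet))
  comp / ncol(windows)
}

# squared Euclidean distances rows of x vs rows of centroids
.sqDistToCentroids <- function(x, cen) {
  d <- outer(rowSums(x^2), rowSums(cen^2), "+") - 2 * x %*% t(cen)
  d[d < 0] <- 0
  d
}

.kmeansPlusPlusInit <- function(x, K) {
  n <- nrow(x)
  centers <- integer(K)
  centers[1L] <- sample.int(n, 1L)
  d2 <- colSums((t(x) - x[centers[1L], ])^2)
  for (j in seq_len(K - 1L)) {
    if (sum(d2) <= 0) {
      centers[j + 1L] <- sample.int(n, 1L)
    } else {
      centers[j + 1L] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, colSums((t(x) - x[centers[j + 1L], ])^2))
  }
  x[centers, , drop = FALSE]
}

.lloyd <- function(x, K, maxIter = 100L, init = NULL) {
  cen <- if (is.null(init)) .kmeansPlusPlusInit(x, K) else init
  assign <- rep(0L, nrow(x))
  for (it in seq_len(maxIter)) {
    d <- .sqDistToCentroids(x, cen)
    newAssign <- max.col(-d, ties.method = "first")
    # re-seed empty clusters to the point farthest from its centroid
    for (j in which(tabulate(newAssign, K) == 0L)) {
      far <- which.max(d[cbind(seq_len(nrow(x)), newAssign)])
      cen[j, ] <- x[far, ]
      newAssign[far] <- j
    }
    if (identical(newAssign, assign)) break
    assign <- newAssign
    for (j in seq_len(K)) {
      rows <- assign == j
      if (any(rows)) cen[j, ] <- colMeans(x[rows, , drop = FALSE])
    }
  }
  d <- .sqDistToCentroids(x, cen)
  list(centroids = cen, labels = assign,
       inertia = sum(d[cbind(seq_len(nrow(x)), assign)]))
}

#' Fit cellular neighbourhoods by KMeans
#'
#' Lloyd's algorithm with k-means++ initialisation, keeping the best of
#' `nRestarts` runs by inertia (the sum of squared distances of windows to
#' their assigned centroid). Empty clusters are re-seeded to the point
#' farthest from its centroid, so K larger than the number of distinct
#' windows degenerates gracefully. Deterministic for a fixed seed.
#'
#' @param comp window-composition matrix from [windowComposition()].
#' @param K number of neighbourhoods (1 <= K <= rows).
#' @param seed RNG seed.
#' @param nRestarts independent restarts (default 10).
#' @param warmStart optional (K-1) x alphabet centroid matrix from the fit
#'   at K-1; it is extended by the farthest window and used as one extra
#'   restart, which guarantees a non-increasing inertia curve over K.
#' @return list(`centroids` K x alphabet, `labels` integer `0..K-1` per
#'   window, `inertia`).
#' @export
fitCN <- function(comp, K, seed = 1, nRestarts = 10, warmStart = NULL) {
  comp <- as.matrix(comp)
  if (K < 1 || K > nrow(comp)) stop("K must lie in [1, rows]")
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(nRestarts)) {
    fit <- .lloyd(comp, as.integer(K))
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  if (!is.null(warmStart) && nrow(warmStart) == K - 1L) {
    d <- .sqDistToCentroids(comp, warmStart)
    far <- which.max(apply(d, 1L, min))
    fit <- .lloyd(comp, as.integer(K), init = rbind(warmStart, comp[far, ]))
    if (fit$inertia < best$inertia) best <- fit
  }
  colnames(best$centroids) <- colnames(comp)
  list(centroids = best$centroids, labels = best$labels - 1L,
       inertia = best$inertia)
}

#' Kneedle elbow selection on an inertia curve
#'
#' For a decreasing inertia curve over K, min-max normalises both axes,
#' inverts the y-axis and returns the K maximising the difference between
#' the normalised curve and the diagonal (Kneedle with sensitivity 1). If
#' the difference curve has no interior local maximum the point of maximum
#' discrete curvature is used instead; a flat curve returns the smallest K.
#'
#' @param K integer vector of scanned K values (increasing).
#' @param inertia positive inertia at each K.
#' @return The selected K.
#' @export
selectKneedle <- function(K, inertia) {
  stopifnot(length(K) == length(inertia), length(K) >= 3L)
  if (any(inertia < 0)) stop("inertia must be non-negative")
  if (all(diff(inertia) >= 0) && any(diff(inertia) > 0))
    stop("monotone-increasing curve is not an inertia curve")
  rngY <- max(inertia) - min(inertia)
  if (rngY == 0) return(K[1L])  # flat curve
  xN <- (K - min(K)) / (max(K) - min(K))
  yN <- (inertia - min(inertia)) / rngY
  d <- (1 - yN) - xN
  n <- length(d)
  interiorMax <- which(seq_len(n) > 1L & seq_len(n) < n &
                         d >= c(-Inf, d[-n]) & d >= c(d[-1L], -Inf))
  if (length(interiorMax)) {
    best <- interiorMax[which.max(d[interiorMax])]
    return(K[best])
  }
  # fallback: maximum discrete curvature (second difference of y)
  curv <- yN[3:n] - 2 * yN[2:(n - 1L)] + yN[1:(n - 2L)]
  K[which.max(curv) + 1L]
}

#' Discover cellular neighbourhoods across a cohort
#'
#' Builds k-NN window compositions per sample (shared label alphabet),
#' pools the windows across samples, scans K over `cfg@cnKRange` with
#' [fitCN()], selects the elbow K with [selectKneedle()] and writes the
#' per-cell CN labels back onto each table (`cn_label` for the plain
#' variant, `cn_label_pla` for the isPLA-augmented variant whose alphabet
#' is cell types crossed with isPLA status).
#'
#' @param tables a [CellTable-class] or list of them, with `cell_type`
#'   (and `ispla_positive` for the augmented variant) present.
#' @param variant `"plain"` or `"ispla_augmented"`.
#' @param cfg a [plaConfig()] object.
#' @return list(`model` a [NeighbourhoodModel-class], `tables` labelled).
#' @export
discoverCN <- function(tables, variant = c("plain", "ispla_augmented"),
                       cfg = plaConfig()) {
  variant <- match.arg(variant)
  single <- is(tables, "CellTable")
  if (single) tables <- list(tables)
  labcol <- if (variant == "plain") "cn_label" else "cn_label_pla"
  labelsOf <- function(tb) {
    cells <- cellData(tb)
    if (is.null(cells$cell_type)) stop("cell_type labels required")
    if (variant == "plain") return(cells$cell_type)
    if (is.null(cells$ispla_positive)) stop("ispla_positive labels required")
    paste0(cells$cell_type, ifelse(cells$ispla_positive, " isPLA+", " isPLA-"))
  }
  alphabet <- if (variant == "plain") plaCellTypes() else
    sort(as.vector(outer(plaCellTypes(), c(" isPLA+", " isPLA-"), paste0)))
  comps <- lapply(tables, function(tb) {
    win <- knnWindows(tb, cfg@cnWindowK, cfg@includeIndexCell)
    windowComposition(win, labelsOf(tb), alphabet)
  })
  pooled <- do.call(rbind, comps)
  Ks <- seq(cfg@cnKRange[1L], cfg@cnKRange[2L])
  fits <- vector("list", length(Ks))
  for (i in seq_along(Ks)) {
    warm <- if (i > 1L) fits[[i - 1L]]$centroids else NULL
    fits[[i]] <- fitCN(pooled, Ks[i], seed = cfg@randomSeed + Ks[i],
                       nRestarts = cfg@cnRestarts, warmStart = warm)
  }
  curve <- data.frame(K = Ks, inertia = vapply(fits, `[[`, numeric(1), "inertia"))
  selK <- selectKneedle(curve$K, curve$inertia)
  fit <- fits[[match(selK, Ks)]]
  model <- new("NeighbourhoodModel", K = selK, centroids = fit$centroids,
               alphabet = alphabet, inertiaCurve = curve, selectedK = selK,
               variant = variant, windowK = cfg@cnWindowK, seed = cfg@randomSeed)
  offset <- 0L
  for (i in seq_along(tables)) {
    n <- length(tables[[i]])
    tables[[i]]@cells[[labcol]] <- fit$labels[seq_len(n) + offset]
    offset <- offset + n
  }
  list(model = model, tables = if (single) tables[[1L]] else tables)
}

#' Assign CN labels from a fitted model
#'
#' Labels each cell of a table with the nearest centroid of a fitted
#' [NeighbourhoodModel-class], recomputing window compositions with the
#' model's window size and alphabet.
#'
#' @param model a [NeighbourhoodModel-class].
#' @param table a [CellTable-class] carrying the labels the model's
#'   alphabet requires.
#' @param includeIndexCell window convention, as at fitting time.
#' @return The table with `cn_label` (plain) or `cn_label_pla` (augmented)
#'   written.
#' @export
assignCN <- function(model, table, includeIndexCell = TRUE) {
  cells <- cellData(table)
  labels <- if (model@variant == "plain") cells$cell_type else
    paste0(cells$cell_type, ifelse(cells$ispla_positive, " isPLA+", " isPLA-"))
  if (is.null(labels) || anyNA(match(unique(labels), model@alphabet)))
    stop("table labels do not match the model alphabet")
  win <- knnWindows(table, model@windowK, includeIndexCell)
  comp <- windowComposition(win, labels, model@alphabet)
  d <- .sqDistToCentroids(comp, model@centroids)
  lab <- max.col(-d, ties.method = "first") - 1L
  labcol <- if (model@variant == "plain") "cn_label" else "cn_label_pla"
  table@cells[[labcol]] <- lab
  table
}

#' Persist / restore a neighbourhood model as JSON
#'
#' @param model a [NeighbourhoodModel-class].
#' @param path JSON path.
#' @return `writeCNModel`: `path` invisibly; `readCNModel`: the model.
#' @export
writeCNModel <- function(model, path) {
  jsonlite::write_json(list(
    K = model@K, selectedK = model@selectedK, variant = model@variant,
    windowK = model@windowK, seed = model@seed, alphabet = model@alphabet,
    centroids = model@centroids, inertiaCurve = model@inertiaCurve
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCNModel
#' @export
readCNModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cen <- as.matrix(j$centroids)
  colnames(cen) <- j$alphabet
  new("NeighbourhoodModel", K = j$K, centroids = cen, alphabet = j$alphabet,
      inertiaCurve = as.data.frame(j$inertiaCurve), selectedK = j$selectedK,
      variant = j$variant, windowK = j$windowK, seed = j$seed)
}
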