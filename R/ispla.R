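#' Otsu threshold for a positive intensity distribution
#'
#' One-dimensional Otsu on `log(1 + x)` (256-bin histogram): picks the cut
#' maximising between-class variance, then maps it back to the intensity
#' scale. Used to estimate a single cohort-wide isPLA cutoff when no manual
#' threshold is supplied.
#'
#' @param x non-negative intensities.
#' @param nBins histogram resolution.
#' @return Threshold on the original intensity scale.
#' @export
otsuThreshold <- function(x, nBins = 256L) {
  if (any(!is.finite(x)) || any(x < 0)) stop("intensities must be finite and non-negative")
  lx <- log1p(x)
  lo <- min(lx); hi <- max(lx)
  if (hi <= lo) return(expm1(lo))
  edges <- seq(lo, hi, length.out = nBins + 1L)
  h <- tabulate(pmin(nBins, pmax(1L, findInterval(lx, edges, rightmost.closed = TRUE))),
                nbins = nBins)
  mids <- (edges[-1L] + edges[-(nBins + 1L)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  total <- w[nBins]; muT <- mu[nBins]
  w0 <- w[-nBins]; w1 <- total - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, nBins - 1L)
  between[valid] <- (muT * w0[valid] - total * mu[-nBins][valid])^2 /
    (w0[valid] * w1[valid])
  cut <- which.max(between)
  expm1(edges[cut + 1L])
}

#' Classify cells as isPLA-positive
#'
#' Applies one fixed intensity threshold to every sample (positivity means
#' `isPLA >= threshold`). With `threshold = NA` (auto), a single cohort-wide
#' cutoff is estimated by Otsu's method on the pooled log-intensities, which
#' assumes a bimodal signal (background vs true rolling-circle signal) and
#' mirrors the requirement that one consistent threshold be used across all
#' slides.
#'
#' @param tables a [CellTable-class] or list of them.
#' @param threshold numeric cutoff, or `NA` for automatic estimation.
#' @return The input table(s) with an `ispla_positive` logical column; the
#'   threshold used is attached as attribute `"isplaThreshold"` (also
#'   readable with [isplaThreshold()]).
#' @export
classifyIspla <- function(tables, threshold = NA_real_) {
  single <- is(tables, "CellTable")
  if (single) tables <- list(tables)
  pooled <- unlist(lapply(tables, function(tb) cellData(tb)$isPLA))
  if (any(!is.finite(pooled))) stop("non-finite isPLA intensities")
  if (!is.finite(threshold)) threshold <- otsuThreshold(pooled)
  tables <- lapply(tables, function(tb) {
    tb@cells$ispla_positive <- cellData(tb)$isPLA >= threshold
    attr(tb, "isplaThreshold") <- threshold
    tb
  })
  out <- if (single) tables[[1L]] else tables
  attr(out, "isplaThreshold") <- threshold
  out
}

#' @rdname classifyIspla
#' @param x a classified table (or list) returned by [classifyIspla()].
#' @export
isplaThreshold <- function(x) attr(x, "isplaThreshold")

#' isPLA positivity fractions per region and cell type
#'
#' Fraction of isPLA-positive cells for every combination of the grouping
#' columns within one sample. Combinations with zero cells are reported
#' with `n = 0` and `fraction = NA` (explicitly missing, never zero).
#'
#' @param table a [CellTable-class] with `ispla_positive` (and the grouping
#'   columns) present.
#' @param by grouping columns, default `c("region", "cell_type")`.
#' @return Tidy data.frame: `sample_id`, grouping columns, `n`,
#'   `n_positive`, `fraction`.
#' @export
positivityFraction <- function(table, by = c("region", "cell_type")) {
  cells <- cellData(table)
  missing <- setdiff(c(by, "ispla_positive"), names(cells))
  if (length(missing))
    stop("missing label column(s): ", paste(missing, collapse = ", "))
  levelsOf <- function(cn) {
    if (cn == "cell_type") plaCellTypes()
    else if (cn == "region") c("tumour", "stroma")
    else sort(unique(as.character(cells[[cn]])))
  }
  grid <- expand.grid(lapply(stats::setNames(by, by), levelsOf),
                      stringsAsFactors = FALSE)
  key <- do.call(paste, c(cells[by], sep = "\r"))
  gridKey <- do.call(paste, c(grid, sep = "\r"))
  n <- as.integer(table(factor(key, levels = gridKey)))
  npos <- vapply(gridKey, function(k)
    sum(cells$ispla_positive[key == k]), integer(1), USE.NAMES = FALSE)
  out <- cbind(data.frame(sample_id = sampleId(table), stringsAsFactors = FALSE),
               grid,
               data.frame(n = n, n_positive = npos,
                          fraction = ifelse(n > 0, npos / n, NA_real_)))
  rownames(out) <- NULL
  out
}
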