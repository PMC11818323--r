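#' Cell-type frequencies per sample
#'
#' Percentage of each cell type, normalised within the whole tissue
#' (`scope = "tissue"`) or within each tumour/stroma region
#' (`scope = "region"`). Percentages sum to 100 within each scope unit;
#' empty regions yield no rows (missing, never zero).
#'
#' @param table a [CellTable-class] with `cell_type` (and `region` for
#'   region scope).
#' @param scope `"tissue"` or `"region"`.
#' @return Tidy data.frame: `sample_id`, (`region`,) `cell_type`, `n`,
#'   `percent`.
#' @export
cellFrequencies <- function(table, scope = c("tissue", "region")) {
  scope <- match.arg(scope)
  cells <- cellData(table)
  if (is.null(cells$cell_type)) stop("cell_type labels required")
  if (scope == "region" && is.null(cells$region)) stop("region labels required")
  key <- if (scope == "region") cells$region else rep("tissue", nrow(cells))
  out <- do.call(rbind, lapply(split(cells$cell_type, key), function(tp) {
    cnt <- table(factor(tp, levels = plaCellTypes()))
    data.frame(cell_type = names(cnt), n = as.integer(cnt),
               percent = 100 * as.integer(cnt) / length(tp),
               stringsAsFactors = FALSE)
  }))
  unit <- sub("\\..*$", "", rownames(out))
  res <- data.frame(sample_id = sampleId(table), stringsAsFactors = FALSE)
  if (scope == "region") res <- cbind(res, region = unit)
  res <- cbind(res, out)
  rownames(res) <- NULL
  res
}

#' Kruskal-Wallis tests across response groups
#'
#' Runs one rank-based Kruskal-Wallis test (with tie correction, p-value
#' from the chi-squared approximation on g-1 degrees of freedom) per
#' feature, across response groups, and adjusts the resulting p-value
#' family for multiple comparisons (Benjamini-Hochberg by default).
#' Features whose observations are all identical get H = 0, p = 1 by
#' convention. Stable-disease samples can be excluded from the contrast via
#' `excludeGroups` (they sit between response and progression and blur
#' group contrasts) while remaining in any upstream summaries.
#'
#' @param data tidy data.frame with one observation per sample per feature.
#' @param feature,value,group column names for the feature id, the numeric
#'   observation and the response group.
#' @param correction `"benjamini-hochberg"` or `"none"`.
#' @param excludeGroups groups dropped before testing (default none).
#' @return data.frame: `feature`, `n`, `H`, `p`, `p_adj`, one
#'   `median_<group>` column per group.
#' @export
kruskalWallisByGroup <- function(data, feature = "feature", value = "value",
                                 group = "group",
                                 correction = c("benjamini-hochberg", "none"),
                                 excludeGroups = character()) {
  correction <- match.arg(correction)
  data <- as.data.frame(data)
  data <- data[!data[[group]] %in% excludeGroups & !is.na(data[[value]]), , drop = FALSE]
  groupsAll <- sort(unique(as.character(data[[group]])))
  rows <- lapply(split(data, data[[feature]]), function(df) {
    g <- factor(as.character(df[[group]]))
    v <- df[[value]]
    if (nlevels(g) < 2L)
      stop("Kruskal-Wallis needs at least two groups with observations")
    if (stats::var(v) == 0 || length(unique(v)) == 1L) {
      H <- 0; p <- 1
    } else {
      kt <- stats::kruskal.test(v, g)
      H <- unname(kt$statistic); p <- kt$p.value
    }
    med <- tapply(v, g, stats::median)
    out <- data.frame(feature = df[[feature]][1L], n = length(v), H = H, p = p,
                      stringsAsFactors = FALSE)
    for (gr in groupsAll)
      out[[paste0("median_", gr)]] <- if (gr %in% names(med)) unname(med[gr]) else NA_real_
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$p_adj <- if (correction == "benjamini-hochberg")
    stats::p.adjust(res$p, method = "BH") else res$p
  res[, c("feature", "n", "H", "p", "p_adj",
          grep("^median_", names(res), value = TRUE))]
}

#' Macrophage barrier coverage of the tumour boundary
#'
#' Operationalises the "macrophage barrier": nest boundaries are sampled at
#' fixed arc-length steps (default 10 um) and a boundary point counts as
#' covered when at least `m` isPLA-positive macrophages lie within `d` um.
#' The coverage is the covered fraction of boundary points, in \[0, 1\]: a
#' dense peritumoural macrophage layer gives values near 1, scattered or
#' absent macrophages give values near 0.
#'
#' @param table a [CellTable-class] with `cell_type` and `ispla_positive`.
#' @param mask a [RegionMask-class]; an empty mask gives `NA` with a
#'   warning.
#' @param d coverage radius, um.
#' @param m minimum number of qualifying macrophages.
#' @param step boundary sampling step, um.
#' @return Fraction of covered boundary points (scalar).
#' @export
barrierCoverage <- function(table, mask, d = 50, m = 3, step = 10) {
  if (nNests(mask) == 0L) {
    warning("empty mask: barrier coverage undefined")
    return(NA_real_)
  }
  cells <- cellData(table)
  if (is.null(cells$cell_type) || is.null(cells$ispla_positive))
    stop("cell_type and ispla_positive labels required")
  pts <- do.call(rbind, lapply(mask@polygons, .resampleRing, step = step))
  mac <- cells[cells$cell_type == "Macrophage" & cells$ispla_positive,
               c("x", "y"), drop = FALSE]
  if (!nrow(mac)) return(0)
  counts <- .radiusCounts(pts, as.matrix(mac), d)
  mean(counts >= m)
}
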