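# Figure-analogue plots, base graphics. Each plot function draws on the
# current device; .savePlot() renders to PNG and SVG side by side.

.savePlot <- function(drawFn, path, width = 7, height = 5) {
  grDevices::png(paste0(path, ".png"), width = width * 100, height = height * 100,
                 res = 100)
  try(drawFn(), silent = TRUE)
  grDevices::dev.off()
  grDevices::svg(paste0(path, ".svg"), width = width, height = height)
  try(drawFn(), silent = TRUE)
  grDevices::dev.off()
  invisible(path)
}

#' Plot boundary-distance density profiles
#'
#' One line per group (the non-bin columns of the profile), density versus
#' signed distance to the tumour boundary; the dashed vertical line marks
#' the boundary.
#'
#' @param profile data.frame from [distanceDensityProfile()].
#' @param main plot title.
#' @return invisibly, the group keys plotted.
#' @export
plotDistanceProfile <- function(profile, main = "Distance to tumour boundary") {
  gcols <- setdiff(names(profile), c("bin_left", "bin_mid", "density"))
  key <- if (length(gcols)) do.call(paste, c(profile[gcols], sep = " / "))
         else rep("all", nrow(profile))
  keys <- unique(key)
  cols <- grDevices::hcl.colors(max(3L, length(keys)), "Dark 3")
  plot(NA, xlim = range(profile$bin_mid), ylim = c(0, max(profile$density)),
       xlab = "signed distance to tumour boundary (um)",
       ylab = "normalized cell count", main = main)
  graphics::abline(v = 0, lty = 2, col = "grey40")
  for (i in seq_along(keys)) {
    sel <- key == keys[i]
    graphics::lines(profile$bin_mid[sel], profile$density[sel], col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = keys, col = cols[seq_along(keys)],
                   lwd = 2, cex = 0.7, bty = "n")
  invisible(keys)
}

#' Heatmap of CN centroid compositions
#'
#' @param model a [NeighbourhoodModel-class].
#' @param main plot title.
#' @export
plotCNComposition <- function(model, main = sprintf("CN composition (%s)", model@variant)) {
  cen <- cnCentroids(model)
  op <- graphics::par(mar = c(9, 6, 3, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(ncol(cen)), seq_len(nrow(cen)), t(cen),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::axis(1, at = seq_len(ncol(cen)), labels = colnames(cen), las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(nrow(cen)),
                 labels = sprintf("CN%d", seq_len(nrow(cen)) - 1L), las = 1, cex.axis = 0.7)
}

#' Plot a spatial-context map
#'
#' Layered layout: combination size increases downwards, node area scales
#' with the cell fraction.
#'
#' @param scm an [SCMGraph-class].
#' @export
plotSCMGraph <- function(scm) {
  g <- scm@graph
  if (igraph::vcount(g) == 0L) {
    plot(NA, xlim = 0:1, ylim = 0:1, axes = FALSE, xlab = "", ylab = "",
         main = sprintf("SCM %s (empty)", scm@group))
    return(invisible(NULL))
  }
  set.seed(0)
  lay <- igraph::layout_with_sugiyama(g, layers = igraph::V(g)$size)$layout
  plot(g, layout = lay,
       vertex.size = 8 + 40 * sqrt(igraph::V(g)$fraction),
       vertex.label.cex = 0.7, edge.arrow.size = 0.4,
       main = sprintf("SCM %s", scm@group))
}

#' Plot a barycentric CN-interface projection
#'
#' @param proj data.frame from [barycentricProjection()].
#' @param main plot title.
#' @export
plotBarycentric <- function(proj, main = "CN interface projection") {
  verts <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  plot(NA, xlim = c(-0.1, 1.1), ylim = c(-0.1, 1.0), asp = 1, axes = FALSE,
       xlab = "", ylab = "", main = main)
  graphics::polygon(verts[, 1], verts[, 2], border = "grey30")
  triple <- attr(proj, "triple")
  if (!is.null(triple))
    graphics::text(verts[, 1], verts[, 2] + c(-0.05, -0.05, 0.05),
                   labels = sprintf("CN%s", triple), cex = 0.8)
  if (nrow(proj)) {
    cols <- grDevices::hcl.colors(max(3L, length(unique(proj$cn_label))), "Dark 3")
    graphics::points(proj$px, proj$py, pch = 16, cex = 0.4,
                     col = cols[as.integer(factor(proj$cn_label))])
  }
}
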