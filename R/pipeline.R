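#' Run the full analysis pipeline
#'
#' Orchestrates every stage in order — QC + transform + phenotyping,
#' tumour masking, boundary distances, isPLA classification, proximity
#' scoring, CN discovery (plain and isPLA-augmented), spatial contexts with
#' SC maps and the barycentric interface projection, and response-group
#' statistics — writing labelled cell tables, masks (GeoJSON), models
#' (JSON), graphs, tidy statistics CSVs, figure-analogue plots and a run
#' manifest into `outDir`.
#'
#' The configuration is a YAML file or an equivalent nested list with
#' blocks:
#' \describe{
#'   \item{synthetic}{`n_per_group` (named counts) and `seed` — generate a
#'     synthetic cohort; or instead}
#'   \item{samples / metadata}{paths to per-sample cell tables and the
#'     metadata CSV;}
#'   \item{params}{overrides for [plaConfig()] (plus `ispla_auto`: set
#'     `FALSE` to require an explicit `isplaThreshold`);}
#'   \item{pairs}{cell-type pairs for proximity scoring.}
#' }
#'
#' @param config YAML path or nested list.
#' @param outDir output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  failMarker <- file.path(outDir, "FAILED")
  if (file.exists(failMarker)) unlink(failMarker)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage %s: %s", name, conditionMessage(e)), failMarker)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  log <- function(...) message(sprintf("[plaScape] %s", sprintf(...)))

  params <- config$params
  isplaAuto <- !identical(params$ispla_auto, FALSE)
  baryTriple <- params$barycentricTriple
  params$ispla_auto <- NULL
  params$barycentricTriple <- NULL
  cfg <- do.call(plaConfig, if (is.null(params)) list() else params)
  if (!isplaAuto && !is.finite(cfg@isplaThreshold))
    stop("missing required parameter: isplaThreshold (automatic estimation disabled)")

  # ---- inputs ---------------------------------------------------------
  truths <- NULL
  inputs <- stage("input", {
    if (!is.null(config$synthetic)) {
      npg <- unlist(config$synthetic$n_per_group)
      seed <- config$synthetic$seed %||% cfg@randomSeed
      coh <- generateCohort(npg, seed = seed)
      truths <<- coh$truths
      list(tables = coh$tables, metadata = coh$metadata)
    } else {
      tabs <- lapply(config$samples, function(s) readCellTable(s$path %||% s))
      names(tabs) <- vapply(tabs, sampleId, character(1))
      list(tables = tabs, metadata = readSampleMetadata(config$metadata))
    }
  })
  tables <- inputs$tables
  meta <- inputs$metadata
  log("loaded %d sample(s)", length(tables))

  # ---- phenotyping ----------------------------------------------------
  ph <- stage("phenotype", phenotypeCells(tables, cfg))
  tables <- ph$tables
  log("phenotyped %d cells into %d clusters",
      length(ph$result$cellType), nrow(ph$result$annotation))

  # ---- masks + boundary distances ------------------------------------
  masks <- stage("mask", lapply(tables, buildTumourMask, cfg = cfg))
  tables <- stage("distance", Map(assignRegions, tables, masks))

  # ---- isPLA ----------------------------------------------------------
  tables <- stage("ispla", classifyIspla(tables, cfg@isplaThreshold))
  thr <- isplaThreshold(tables)
  log("isPLA threshold %.2f", thr)

  # ---- proximity ------------------------------------------------------
  pairs <- config$pairs %||% list(c("Macrophage", "Tumour"), c("B cell", "Tumour"),
                                  c("CD8 T cell", "Tumour"), c("CD3 T cell", "Tumour"))
  prox <- stage("proximity", do.call(rbind, lapply(tables, proximityDensityTable,
                                                   pairs = pairs,
                                                   radius = cfg@proximityRadius)))

  # ---- cellular neighbourhoods (both variants) ------------------------
  cnPlain <- stage("cn", discoverCN(tables, "plain", cfg))
  tables <- cnPlain$tables
  cnPla <- stage("cn", discoverCN(tables, "ispla_augmented", cfg))
  tables <- cnPla$tables
  log("CN variants: plain K = %d, isPLA-augmented K = %d",
      cnPlain$model@selectedK, cnPla$model@selectedK)

  # ---- spatial contexts ----------------------------------------------
  nCN <- cnPla$model@K
  tables <- stage("sc", lapply(tables, assignSpatialContext, cfg = cfg,
                               cnColumn = "cn_label_pla", nCN = nCN))
  groupOf <- stats::setNames(as.character(meta$response_group), meta$sample_id)
  combosByGroup <- split(
    unlist(lapply(tables, function(tb) cellData(tb)$sc_combination)),
    unlist(lapply(tables, function(tb) rep(groupOf[sampleId(tb)], length(tb)))))
  scms <- stage("scm", lapply(names(combosByGroup), function(g)
    buildSCMGraph(combosByGroup[[g]], group = g, minFraction = cfg@scmMinFraction)))
  names(scms) <- names(combosByGroup)

  # barycentric triple: the three CNs with the largest tumour-component mass,
  # i.e. the tumour and tumour-immune interface neighbourhoods
  tumourCols <- grep("^Tumour", cnPla$model@alphabet)
  triple <- order(rowSums(cnPla$model@centroids[, tumourCols, drop = FALSE]),
                  decreasing = TRUE)[1:3] - 1L
  triple <- as.integer(baryTriple %||% triple)
  bary <- stage("barycentric", do.call(rbind, lapply(tables, function(tb) {
    w <- scWindows(tb, cfg@scWindowK, "cn_label_pla", nCN, cfg@includeIndexCell)
    pr <- barycentricProjection(w, triple, cfg@barycentricPurity,
                                cnLabels = cellData(tb)$cn_label_pla,
                                cellIds = cellData(tb)$cell_id)
    if (nrow(pr)) cbind(sample_id = sampleId(tb),
                        group = groupOf[sampleId(tb)], pr)
    else NULL
  })))

  # ---- statistics -----------------------------------------------------
  statsOut <- stage("stats", {
    freqT <- do.call(rbind, lapply(tables, cellFrequencies, scope = "tissue"))
    freqR <- do.call(rbind, lapply(tables, cellFrequencies, scope = "region"))
    posv <- do.call(rbind, lapply(tables, positivityFraction))
    posv$group <- groupOf[posv$sample_id]
    posv$feature <- paste(posv$region, posv$cell_type, sep = " / ")
    tryKW <- function(...) {
      ok <- nrow(posv) && !all(is.na(posv$fraction))
      if (!ok) return(NULL)
      tryCatch(kruskalWallisByGroup(posv, feature = "feature",
                                    value = "fraction", group = "group", ...),
               error = function(e) {
        warning("group comparison skipped: ", conditionMessage(e))
        NULL
      })
    }
    kw <- tryKW(excludeGroups = "SD")
    kwAll <- tryKW()
    cov <- data.frame(sample_id = names(tables),
                      group = groupOf[names(tables)],
                      coverage = vapply(names(tables), function(s)
                        barrierCoverage(tables[[s]], masks[[s]],
                                        d = cfg@coverageDistance,
                                        m = cfg@coverageMinCells,
                                        step = cfg@boundaryStep), numeric(1)),
                      stringsAsFactors = FALSE)
    dists <- do.call(rbind, lapply(tables, function(tb) {
      cells <- cellData(tb)
      data.frame(sample_id = sampleId(tb), group = groupOf[sampleId(tb)],
                 cell_type = cells$cell_type,
                 ispla = ifelse(cells$ispla_positive, "isPLA+", "isPLA-"),
                 distance = cells$boundary_dist, stringsAsFactors = FALSE)
    }))
    prof <- distanceDensityProfile(dists$distance,
                                   dists[, c("cell_type", "ispla", "group")],
                                   binWidth = cfg@binWidth)
    list(freqT = freqT, freqR = freqR, posv = posv, kw = kw, kwAll = kwAll,
         cov = cov, prof = prof, dists = dists)
  })

  # ---- outputs --------------------------------------------------------
  stage("write", {
    for (d in c("cells", "masks", "models", "scm", "stats", "plots"))
      dir.create(file.path(outDir, d), showWarnings = FALSE)
    for (s in names(tables))
      writeCellTable(tables[[s]], file.path(outDir, "cells", paste0(s, ".csv")))
    writeSampleMetadata(meta, file.path(outDir, "metadata.csv"))
    for (s in names(masks)) {
      mk <- masks[[s]]
      writeNestGeoJSON(structure(list(polygons = mk@polygons, areas = mk@areas),
                                 class = "GroundTruth"),
                       file.path(outDir, "masks", paste0(s, ".geojson")))
    }
    if (!is.null(truths))
      for (s in names(truths))
        jsonlite::write_json(truths[[s]]$cells,
                             file.path(outDir, "cells", paste0(s, "_truth.json")),
                             auto_unbox = TRUE, digits = NA)
    utils::write.csv(ph$result$annotation,
                     file.path(outDir, "models", "phenotype_annotation.csv"),
                     row.names = FALSE)
    writeCNModel(cnPlain$model, file.path(outDir, "models", "cn_plain.json"))
    writeCNModel(cnPla$model, file.path(outDir, "models", "cn_ispla.json"))
    utils::write.csv(inertiaCurve(cnPlain$model),
                     file.path(outDir, "models", "inertia_plain.csv"), row.names = FALSE)
    utils::write.csv(inertiaCurve(cnPla$model),
                     file.path(outDir, "models", "inertia_ispla.csv"), row.names = FALSE)
    for (g in names(scms)) {
      writeSCMGraph(scms[[g]], file.path(outDir, "scm", paste0("scm_", g, ".json")))
      writeSCMGraphDot(scms[[g]], file.path(outDir, "scm", paste0("scm_", g, ".dot")))
    }
    if (!is.null(bary))
      utils::write.csv(bary, file.path(outDir, "barycentric.csv"), row.names = FALSE)
    st <- statsOut
    utils::write.csv(prox, file.path(outDir, "stats", "proximity.csv"), row.names = FALSE)
    utils::write.csv(st$freqT, file.path(outDir, "stats", "cell_frequencies_tissue.csv"), row.names = FALSE)
    utils::write.csv(st$freqR, file.path(outDir, "stats", "cell_frequencies_region.csv"), row.names = FALSE)
    utils::write.csv(st$posv, file.path(outDir, "stats", "ispla_positivity.csv"), row.names = FALSE)
    if (!is.null(st$kw))
      utils::write.csv(st$kw, file.path(outDir, "stats", "positivity_kruskal_wallis.csv"), row.names = FALSE)
    if (!is.null(st$kwAll))
      utils::write.csv(st$kwAll, file.path(outDir, "stats", "positivity_kruskal_wallis_all_groups.csv"), row.names = FALSE)
    utils::write.csv(st$cov, file.path(outDir, "stats", "barrier_coverage.csv"), row.names = FALSE)
    utils::write.csv(st$prof, file.path(outDir, "stats", "distance_profiles.csv"), row.names = FALSE)
  })

  stage("plot", {
    mac <- statsOut$prof[statsOut$prof$cell_type == "Macrophage" &
                           statsOut$prof$ispla == "isPLA+", , drop = FALSE]
    if (nrow(mac))
      .savePlot(function() plotDistanceProfile(mac[, c("group", "bin_left", "bin_mid", "density")],
                                               main = "isPLA+ macrophages"),
                file.path(outDir, "plots", "distance_macrophage"))
    .savePlot(function() plotCNComposition(cnPlain$model),
              file.path(outDir, "plots", "cn_composition_plain"))
    .savePlot(function() plotCNComposition(cnPla$model),
              file.path(outDir, "plots", "cn_composition_ispla"))
    for (g in names(scms))
      .savePlot(function() plotSCMGraph(scms[[g]]),
                file.path(outDir, "plots", paste0("scm_", g)))
    if (!is.null(bary))
      for (g in unique(bary$group)) {
        pr <- bary[bary$group == g, , drop = FALSE]
        attr(pr, "triple") <- triple
        .savePlot(function() plotBarycentric(pr, main = sprintf("CN interfaces, %s", g)),
                  file.path(outDir, "plots", paste0("barycentric_", g)))
      }
  })

  manifest <- stage("manifest", {
    files <- list.files(outDir, recursive = TRUE, full.names = TRUE)
    files <- files[!grepl("^plots/|manifest\\.json$",
                          sub(paste0("^", outDir, "/?"), "", files))]
    hashes <- as.list(tools::md5sum(sort(files)))
    names(hashes) <- sub(paste0("^", outDir, "/?"), "", names(hashes))
    m <- list(package_version = as.character(utils::packageVersion("plaScape")),
              config = config,
              seed = cfg@randomSeed,
              ispla_threshold = thr,
              cn_selected_k = list(plain = cnPlain$model@selectedK,
                                   ispla = cnPla$model@selectedK),
              qc = ph$qc,
              hashes = hashes)
    jsonlite::write_json(m, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    m
  })
  log("pipeline complete: %s", outDir)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
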