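test_that("QC keeps the closed nuclear-area interval and reports removals", {
  cells <- makeCells(5)
  cells$nuclear_area <- c(5, 50, 250, 10, 220)
  tb <- cellTable(cells, "qc")
  out <- qcFilter(tb, plaConfig())
  expect_setequal(cellData(out)$nuclear_area, c(50, 10, 220))
  rep <- qcReport(out)
  expect_equal(rep$n_input, 5L)
  expect_equal(rep$n_removed_area, 2L)
  expect_equal(rep$n_removed_area + rep$n_removed_dapi + rep$n_retained, 5L)
  # idempotence
  again <- qcFilter(out, plaConfig())
  expect_identical(cellData(again)$cell_id, cellData(out)$cell_id)
})

test_that("a DAPI floor can empty the table with counts conserved", {
  tb <- makeTable(20)
  cfg <- plaConfig(qcMinDapi = max(cellData(tb)$DAPI) + 1)
  expect_warning(out <- qcFilter(tb, cfg), "removed every cell")
  expect_equal(length(out), 0L)
  rep <- qcReport(out)
  expect_equal(rep$n_removed_area + rep$n_removed_dapi, 20L)
})

test_that("arcsinh transform matches its closed form and is monotone", {
  m <- expressionMatrix(matrix(c(0, 150, 300, 75), 2, 2,
                               dimnames = list(NULL, c("PanCK", "CD20"))))
  out <- arcsinhTransform(m, 150)
  expect_equal(out@values[1, 1], 0, ignore_attr = TRUE)
  expect_equal(out@values[2, 1], log(1 + sqrt(2)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(out@stage, "arcsinh")
  set.seed(1)
  x1 <- stats::runif(1000, 0, 1e4)
  x2 <- x1 + stats::runif(1000, 1e-6, 100)
  expect_true(all(asinh(x1 / 150) < asinh(x2 / 150)))
  expect_error(arcsinhTransform(m, -1), "cofactor")
  expect_error(arcsinhTransform(out, 150), "raw")
})

test_that("nuclear area can bypass the arcsinh transform", {
  v <- matrix(c(150, 300, 80, 90), 2, 2,
              dimnames = list(NULL, c("PanCK", "nuclear_area")))
  keep <- arcsinhTransform(expressionMatrix(v), 150, transformArea = FALSE)
  expect_equal(keep@values[, "nuclear_area"], c(80, 90))
  trans <- arcsinhTransform(expressionMatrix(v), 150, transformArea = TRUE)
  expect_equal(trans@values[, "nuclear_area"], asinh(c(80, 90) / 150))
})

test_that("two-pass scaling standardises columns then rows", {
  m <- expressionMatrix(matrix(c(0, 2, 2, 0), 2, 2), stage = "arcsinh")
  out <- dualScale(m)@values
  # hand computation: both columns z-score to (-x, x)/..; rows then re-centre
  expect_equal(rowMeans(out), c(0, 0), tolerance = 1e-10)
  expect_equal(out[1, ], -out[2, ], tolerance = 1e-10)
  expect_equal(abs(out[1, 1]), abs(out[1, 2]), tolerance = 1e-10)

  cm <- matrix(c(1, 1, 1, 4, 2, 9), 3, 2)
  sc <- dualScale(expressionMatrix(cm, stage = "arcsinh"))@values
  expect_false(any(is.na(sc)))  # constant column maps to zeros, not NaN

  set.seed(2)
  big <- matrix(stats::rnorm(200), 20, 10)
  out2 <- dualScale(expressionMatrix(big, stage = "arcsinh"))@values
  expect_true(all(abs(rowMeans(out2)) < 1e-10))
})

test_that("pass-1 column scaling is invariant to affine input transforms", {
  set.seed(3)
  v <- matrix(stats::rnorm(300), 30, 10)
  a <- plaScape:::.scaleColumns(v, "zscore")
  v2 <- v
  v2[, 4] <- 3.7 * v2[, 4] + 11
  b <- plaScape:::.scaleColumns(v2, "zscore")
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("graph clustering separates well-separated blobs and is seeded", {
  set.seed(2)
  x <- rbind(matrix(stats::rnorm(100 * 4, 0, 1), ncol = 4),
             matrix(stats::rnorm(100 * 4, 10, 1), ncol = 4))
  m <- expressionMatrix(x, stage = "scaled")
  lab <- clusterCells(m, k = 15, resolution = 0.5, seed = 1)
  expect_equal(ari(lab, rep(1:2, each = 100)), 1)
  expect_identical(lab, clusterCells(m, k = 15, resolution = 0.5, seed = 1))

  dup <- expressionMatrix(matrix(0, 40, 4), stage = "scaled")
  expect_equal(length(unique(clusterCells(dup, k = 10, resolution = 1, seed = 1))), 1L)
  expect_error(clusterCells(m, k = 500), "fewer cells")
})

test_that("cluster annotation follows canonical markers with a deterministic tie-break", {
  set.seed(4)
  n <- 60
  v <- matrix(stats::rlnorm(n * 5, 1), n, 5,
              dimnames = list(NULL, c("PanCK", "CD20", "CD3e", "CD8", "CD68")))
  v[1:30, "CD20"] <- v[1:30, "CD20"] + 50   # strong B-cell cluster
  v[31:60, "CD68"] <- v[31:60, "CD68"] + 50
  m <- expressionMatrix(v, stage = "arcsinh")
  res <- annotateClusters(rep(0:1, each = 30), m)
  expect_identical(res$annotation$cell_type, c("B cell", "Macrophage"))
  expect_identical(unique(res$cellType[1:30]), "B cell")

  flat <- expressionMatrix(matrix(1, 10, 5,
    dimnames = list(NULL, c("PanCK", "CD20", "CD3e", "CD8", "CD68"))),
    stage = "arcsinh")
  tie <- annotateClusters(rep(0L, 10), flat)
  expect_identical(tie$annotation$cell_type, "Tumour")  # precedence order
})

test_that("phenotyping recovers ground-truth cell types on synthetic tissue", {
  scores <- vapply(c(7, 8), function(seed) {
    out <- generateTissue(tissueArchitecture("barrier"), seed)
    ph <- phenotypeCells(out$table, plaConfig())
    m <- match(cellData(ph$tables)$cell_id, out$truth$cells$cell_id)
    ari(cellData(ph$tables)$cell_type, out$truth$cells$true_type[m])
  }, numeric(1))
  expect_true(all(scores >= 0.8))
})
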