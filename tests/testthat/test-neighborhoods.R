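test_that("k-NN windows follow hand geometry and deterministic tie-breaks", {
  cells <- makeCells(3)
  cells$x <- c(0, 10, 25); cells$y <- 0
  win <- knnWindows(cellTable(cells, "l"), k = 1, includeIndexCell = FALSE)
  expect_equal(win[, 1], c(2L, 1L, 2L))

  dup <- makeCells(6)
  dup$x <- rep(c(0, 0, 50), 2); dup$y <- rep(c(0, 0, 0), 2)
  tb <- cellTable(dup, "d")
  w1 <- knnWindows(tb, k = 2)
  w2 <- knnWindows(tb, k = 2)
  expect_identical(w1, w2)
  # cells 1,2,4,5 coincide at the origin: ties resolve by ascending index
  expect_equal(w1[1, ], c(1L, 2L, 4L))
  expect_equal(w1[2, ], c(2L, 1L, 4L))
})

test_that("k-NN windows equal the brute-force definition on random instances", {
  for (seed in c(1, 2)) {
    tb <- makeTable(400, seed = seed)
    coords <- as.matrix(cellData(tb)[, c("x", "y")])
    expect_identical(knnWindows(tb, 10, includeIndexCell = FALSE),
                     bruteKnn(coords, 10))
  }
  expect_error(knnWindows(makeTable(5), k = 10), "at least")
})

test_that("the kd-tree k-NN path agrees with brute force on large instances", {
  tb <- makeTable(2000, seed = 31)
  coords <- as.matrix(cellData(tb)[, c("x", "y")])
  expect_identical(knnWindows(tb, 12, includeIndexCell = FALSE),
                   bruteKnn(coords, 12))
  # duplicated coordinates stress the tie-break layer on the kd-tree path
  tb@cells$x[1:200] <- rep(tb@cells$x[1:40], 5)
  tb@cells$y[1:200] <- rep(tb@cells$y[1:40], 5)
  coords2 <- as.matrix(cellData(tb)[, c("x", "y")])
  expect_identical(knnWindows(tb, 8, includeIndexCell = FALSE),
                   bruteKnn(coords2, 8))
})

test_that("window compositions count labels on the simplex", {
  win <- matrix(rep(1:11, each = 1), nrow = 1)
  labels <- c(rep("Tumour", 11))
  comp <- windowComposition(win, labels, plaCellTypes())
  expect_equal(comp[1, "Tumour"], 1, ignore_attr = TRUE)
  expect_equal(sum(comp), 1)

  labels2 <- c(rep("Tumour", 6), rep("Macrophage", 5))
  comp2 <- windowComposition(win, labels2, plaCellTypes())
  expect_equal(comp2[1, "Tumour"], 6 / 11, ignore_attr = TRUE)
  expect_equal(comp2[1, "Macrophage"], 5 / 11, ignore_attr = TRUE)

  set.seed(1)
  tb <- makeTable(300, types = plaCellTypes())
  w <- knnWindows(tb, 10)
  cm <- windowComposition(w, cellData(tb)$cell_type, plaCellTypes())
  expect_true(all(abs(rowSums(cm) - 1) < 1e-12))
  expect_error(windowComposition(w, rep("Alien", 300), plaCellTypes()), "alphabet")
})

test_that("KMeans fits satisfy closed-form and self-consistency checks", {
  set.seed(5)
  x <- matrix(stats::runif(200), 40, 5)
  x <- x / rowSums(x)
  one <- fitCN(x, 1, seed = 1)
  expect_equal(one$centroids[1, ], colMeans(x), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(one$inertia, sum(sweep(x, 2, colMeans(x))^2), tolerance = 1e-9)

  sep <- rbind(matrix(rep(c(1, 0, 0, 0, 0), 20), 20, byrow = TRUE),
               matrix(rep(c(0, 1, 0, 0, 0), 20), 20, byrow = TRUE))
  two <- fitCN(sep, 2, seed = 1)
  expect_equal(two$inertia, 0)
  expect_equal(length(unique(two$labels[1:20])), 1L)
  expect_true(all(two$labels %in% 0:1))

  fit <- fitCN(x, 4, seed = 2)
  recomputed <- sum((x - fit$centroids[fit$labels + 1L, ])^2)
  expect_equal(fit$inertia, recomputed, tolerance = 1e-9)
  # agreement with the reference KMeans implementation on separable data
  km <- stats::kmeans(sep, 2, nstart = 5)
  expect_equal(ari(two$labels, km$cluster), 1)
})

test_that("degenerate K exceeding distinct rows is re-seeded, not an error", {
  x <- matrix(rep(c(1, 0, 0.5, 0.5), 5), 10, 2, byrow = FALSE)
  fit <- fitCN(x, 5, seed = 1)
  expect_equal(fit$inertia, 0, tolerance = 1e-12)
  expect_error(fitCN(x, 11, seed = 1), "K must lie")
})

test_that("Kneedle finds constructed elbows and degenerate curves", {
  K <- 3:15
  y <- ifelse(K <= 6, 100 - 10 * (K - 3), 100 - 30 - 0.1 * (K - 6))
  expect_equal(selectKneedle(K, y), 6)

  # definitional oracle on exponential decay, computed independently
  y2 <- 2^(-K)
  xN <- (K - 3) / 12; yN <- (y2 - min(y2)) / (max(y2) - min(y2))
  d <- (1 - yN) - xN
  oracle <- K[which.max(d)]
  expect_equal(selectKneedle(K, y2), oracle)

  expect_equal(selectKneedle(K, rep(5, 13)), 3)
  expect_error(selectKneedle(K, as.numeric(K)), "monotone")
})

test_that("CN discovery labels planted structure and the inertia curve decreases", {
  out <- generateTissue(tissueArchitecture("barrier", fieldSize = c(900, 900),
                                           nNests = 1, nestRadiusMean = 200),
                        seed = 6)
  tb <- out$table
  tb@cells$cell_type <- out$truth$cells$true_type  # isolate the CN stage
  cfg <- plaConfig(cnKRange = c(3, 10))
  cn <- discoverCN(tb, "plain", cfg)
  curve <- inertiaCurve(cn$model)
  expect_true(all(diff(curve$inertia) <= 1e-9))
  expect_true("cn_label" %in% names(cellData(cn$tables)))
  expect_true(all(cellData(cn$tables)$cn_label %in% 0:(cn$model@K - 1L)))

  # a macrophage-band tissue must contain a macrophage/tumour-dominated CN
  cen <- cnCentroids(cn$model)
  expect_gt(max(cen[, "Macrophage"] + cen[, "Tumour"]), 0.6)
})

test_that("CN assignment is nearest-centroid and permutation-equivariant", {
  out <- generateTissue(tissueArchitecture("neutral", fieldSize = c(700, 700)),
                        seed = 8)
  tb <- out$table
  tb@cells$cell_type <- out$truth$cells$true_type
  cfg <- plaConfig(cnKRange = c(3, 6), cnRestarts = 3)
  cn <- discoverCN(tb, "plain", cfg)
  model <- cn$model
  re <- assignCN(model, tb)
  expect_identical(cellData(re)$cn_label, cellData(cn$tables)$cn_label)

  perm <- sample(model@K)
  permModel <- model
  permModel@centroids <- model@centroids[perm, , drop = FALSE]
  lab1 <- cellData(assignCN(model, tb))$cn_label
  lab2 <- cellData(assignCN(permModel, tb))$cn_label
  expect_identical(perm[lab2 + 1L] - 1L, lab1)
})

test_that("CN discovery is equivariant under rigid motions", {
  out <- generateTissue(tissueArchitecture("neutral", fieldSize = c(700, 700)),
                        seed = 9)
  tb <- out$table
  tb@cells$cell_type <- out$truth$cells$true_type
  cfg <- plaConfig(cnKRange = c(3, 6), cnRestarts = 3)
  lab0 <- cellData(discoverCN(tb, "plain", cfg)$tables)$cn_label
  rot <- tb
  th <- 1.1
  x <- cellData(tb)$x; y <- cellData(tb)$y
  rot@cells$x <- cos(th) * x - sin(th) * y + 500
  rot@cells$y <- sin(th) * x + cos(th) * y - 200
  lab1 <- cellData(discoverCN(rot, "plain", cfg)$tables)$cn_label
  expect_identical(lab0, lab1)
})

test_that("neighbourhood models persist through JSON", {
  out <- generateTissue(tissueArchitecture("neutral", fieldSize = c(700, 700)),
                        seed = 10)
  tb <- out$table
  tb@cells$cell_type <- out$truth$cells$true_type
  cn <- discoverCN(tb, "plain", plaConfig(cnKRange = c(3, 6), cnRestarts = 2))
  path <- tempfile(fileext = ".json")
  writeCNModel(cn$model, path)
  back <- readCNModel(path)
  expect_equal(cnCentroids(back), cnCentroids(cn$model), tolerance = 1e-12)
  expect_identical(back@variant, cn$model@variant)
  expect_equal(back@selectedK, cn$model@selectedK)
  unlink(path)
})
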