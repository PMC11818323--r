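test_that("the minimal-combination rule matches its forced cases", {
  expect_equal(minimalCombination(c(0.95, 0.05, 0)), 0L)
  expect_equal(minimalCombination(c(0.50, 0.45, 0.05)), c(0L, 1L))
  expect_equal(minimalCombination(c(0.40, 0.35, 0.25)), c(0L, 1L, 2L))
  expect_error(minimalCombination(c(0, 0, 0)), "all-zero")
  # ties in abundance break by ascending CN id
  expect_equal(minimalCombination(c(0.5, 0.5, 0)), c(0L, 1L))
})

test_that("minimal combinations are invariant to zero-frequency padding and truly minimal", {
  set.seed(11)
  for (i in 1:200) {
    k <- sample(3:8, 1)
    v <- stats::rexp(k); v <- v / sum(v)
    got <- minimalCombination(v)
    expect_equal(minimalCombination(c(v, 0, 0)), got)
    # exhaustive prefix search over the abundance ordering
    ord <- order(-v, seq_along(v))
    cums <- cumsum(v[ord])
    mStar <- which(cums > 0.9)[1L]
    expect_equal(got, sort(ord[seq_len(mStar)]) - 1L)
    expect_gt(sum(v[got + 1L]), 0.9)
    if (length(got) > 1L) {
      drop <- got[which.min(v[got + 1L])]
      expect_lte(sum(v[setdiff(got, drop) + 1L]), 0.9)
    }
  }
})

test_that("SC windows are simplex-valued and match a brute-force recount", {
  tb <- makeTable(300, seed = 12)
  set.seed(12)
  tb@cells$cn_label <- sample(0:3, 300, TRUE)
  w <- scWindows(tb, k = 20, cnColumn = "cn_label", nCN = 4)
  expect_true(all(abs(rowSums(w) - 1) < 1e-12))
  coords <- as.matrix(cellData(tb)[, c("x", "y")])
  nn <- bruteKnn(coords, 20)
  for (i in c(1, 57, 300)) {
    idx <- c(i, nn[i, ])
    cnt <- tabulate(tb@cells$cn_label[idx] + 1L, 4)
    expect_equal(as.numeric(w[i, ]), cnt / 21)
  }

  # a pure region gives one-hot windows
  tb@cells$cn_label <- rep(2L, 300)
  w2 <- scWindows(tb, k = 20, cnColumn = "cn_label", nCN = 4)
  expect_true(all(w2[, "2"] == 1))
})

test_that("SCM graphs implement the subset/size edge rule on a DAG", {
  scm <- buildSCMGraph(rep("0", 100))
  expect_equal(igraph::vcount(scm@graph), 1L)
  expect_equal(igraph::ecount(scm@graph), 0L)

  combos <- c(rep("0", 40), rep("1", 40), rep("0&1", 20))
  scm2 <- buildSCMGraph(combos, group = "CR")
  g <- scm2@graph
  expect_setequal(igraph::V(g)$name, c("0", "1", "0&1"))
  el <- igraph::as_edgelist(g)
  expect_equal(nrow(el), 2L)
  expect_setequal(paste(el[, 1], el[, 2]), c("0 0&1", "1 0&1"))
  expect_equal(sum(igraph::V(g)$fraction), 1)

  set.seed(13)
  for (i in 1:20) {
    ids <- replicate(50, paste(sort(sample(0:4, sample(1:3, 1))), collapse = "&"))
    gg <- buildSCMGraph(ids)@graph
    expect_true(igraph::is_dag(gg))
  }
})

test_that("the SCM node cutoff removes rare combinations", {
  combos <- c(rep("0", 9999), "1&2")
  scm <- buildSCMGraph(combos, minFraction = 1e-3)
  expect_identical(igraph::V(scm@graph)$name, "0")
})

test_that("barycentric projection maps pure, edge and centre windows correctly", {
  w <- rbind(c(1, 0, 0, 0), c(0.5, 0.5, 0, 0), c(1, 1, 1, 0) / 3,
             c(0.2, 0.2, 0.2, 0.4))
  colnames(w) <- as.character(0:3)
  pr <- barycentricProjection(w, triple = c(0, 1, 2), purity = 0.99)
  expect_equal(nrow(pr), 3L)  # the impure window is filtered out
  expect_equal(unlist(pr[1, c("px", "py")]), c(px = 0, py = 0))
  expect_equal(unlist(pr[2, c("px", "py")]), c(px = 0.5, py = 0))  # edge midpoint
  centroid <- colMeans(rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)))
  expect_equal(as.numeric(pr[3, c("px", "py")]), as.numeric(centroid),
               tolerance = 1e-12)
  expect_true(all(abs(rowSums(pr[, c("w1", "w2", "w3")]) - 1) < 1e-12))

  expect_warning(empty <- barycentricProjection(w[4, , drop = FALSE],
                                                c(0, 1, 2), purity = 0.9995),
                 "purity")
  expect_equal(nrow(empty), 0L)
})

test_that("spatial-context assignment writes combinations for every cell", {
  out <- generateTissue(tissueArchitecture("neutral", fieldSize = c(700, 700)),
                        seed = 14)
  tb <- out$table
  tb@cells$cell_type <- out$truth$cells$true_type
  cn <- discoverCN(tb, "plain", plaConfig(cnKRange = c(3, 5), cnRestarts = 2))
  tb <- cn$tables
  tb <- assignSpatialContext(tb, plaConfig(scWindowK = 50), cnColumn = "cn_label",
                             nCN = cn$model@K)
  sc <- cellData(tb)$sc_combination
  expect_false(anyNA(sc))
  expect_true(all(grepl("^[0-9]+(&[0-9]+)*$", sc)))
})
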