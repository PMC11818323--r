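test_that("a dense tumour disc yields one nest of the right area", {
  for (seed in 1:5) {
    set.seed(seed)
    nT <- stats::rpois(1, 0.01 * pi * 200^2)
    rr <- 200 * sqrt(stats::runif(nT)); th <- stats::runif(nT, 0, 2 * pi)
    nS <- stats::rpois(1, 0.0005 * 1000^2)
    cells <- makeCells(nT + nS, seed = seed)
    cells$x <- c(500 + rr * cos(th), stats::runif(nS, 0, 1000))
    cells$y <- c(500 + rr * sin(th), stats::runif(nS, 0, 1000))
    cells$cell_type <- c(rep("Tumour", nT), rep("CD3 T cell", nS))
    mask <- buildTumourMask(cellTable(cells, "disc"), plaConfig())
    expect_equal(nNests(mask), 1L)
    expect_lt(abs(nestAreas(mask) - pi * 200^2) / (pi * 200^2), 0.15)
  }
})

test_that("nests at or below 100 um^2 are discarded", {
  set.seed(3)
  cells <- makeCells(25)
  cells$x <- c(stats::rnorm(5, 0, 1.5), stats::runif(20, 200, 1000))
  cells$y <- c(stats::rnorm(5, 0, 1.5), stats::runif(20, 200, 1000))
  cells$cell_type <- c(rep("Tumour", 5), rep("CD3 T cell", 20))
  mask <- suppressWarnings(buildTumourMask(cellTable(cells, "tiny"),
                                           plaConfig(maskGridPitch = 1)))
  expect_equal(nNests(mask), 0L)
})

test_that("empty and tumour-free tables give an empty mask with stroma labels", {
  tb <- makeTable(30, types = c("B cell", "CD3 T cell"))
  expect_warning(mask <- buildTumourMask(tb, plaConfig()), "stroma")
  expect_equal(nNests(mask), 0L)
  expect_true(all(mask@region == "stroma"))
  expect_warning(bd <- signedBoundaryDistance(tb, mask), "undefined")
  expect_true(all(is.na(bd$distance)))
  expect_false(any(is.infinite(bd$distance)))
})

test_that("signed distances match square-nest geometry", {
  sq <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100), c(0, 0))
  mask <- maskFromRings(list(sq))
  cells <- makeCells(3)
  cells$x <- c(50, 130, 50); cells$y <- c(50, 50, -30)
  bd <- signedBoundaryDistance(cellTable(cells, "sq"), mask)
  expect_equal(bd$distance, c(-50, 30, 30), tolerance = 1e-9)
  expect_identical(as.character(bd$region), c("tumour", "stroma", "stroma"))
})

test_that("signed distances agree with the analytic circle oracle", {
  R <- 200
  ring <- circleRing(0, 0, R, nV = 50000L)
  mask <- maskFromRings(list(ring))
  set.seed(9)
  n <- 1000
  r <- stats::runif(n, 0, 2 * R); th <- stats::runif(n, 0, 2 * pi)
  cells <- makeCells(n)
  cells$x <- r * cos(th); cells$y <- r * sin(th)
  bd <- signedBoundaryDistance(cellTable(cells, "circ"), mask)
  expect_lt(max(abs(abs(bd$distance) - abs(r - R))), 1e-6)
  expect_true(all((bd$distance <= 0) == (r <= R)))
})

test_that("region labels and distance signs stay mutually consistent", {
  out <- generateTissue(tissueArchitecture("neutral"), 4)
  mask <- maskFromRings(out$truth$polygons)
  bd <- signedBoundaryDistance(out$table, mask)
  inside <- plaScape:::.inAnyRing(cellData(out$table)$x, cellData(out$table)$y,
                                  out$truth$polygons)
  expect_identical(bd$distance <= 0, inside)
  expect_identical(as.character(bd$region) == "tumour", inside)
})

test_that("the mask is translation-equivariant and grows monotonically", {
  set.seed(4)
  cells <- makeCells(600)
  cells$x <- c(stats::rnorm(300, 500, 60), stats::runif(300, 0, 1000))
  cells$y <- c(stats::rnorm(300, 500, 60), stats::runif(300, 0, 1000))
  cells$cell_type <- c(rep("Tumour", 300), rep("B cell", 300))
  m1 <- buildTumourMask(cellTable(cells, "t"), plaConfig())
  shifted <- cells
  shifted$x <- shifted$x + 37.5; shifted$y <- shifted$y - 11.25
  m2 <- buildTumourMask(cellTable(shifted, "t"), plaConfig())
  expect_equal(nNests(m1), nNests(m2))
  expect_equal(m1@polygons[[1]],
               sweep(m2@polygons[[1]], 2, c(37.5, -11.25)), tolerance = 1e-9)

  areas <- vapply(c(1, 0.5, 0.25) * m1@threshold, function(thr)
    sum(nestAreas(buildTumourMask(cellTable(cells, "t"),
                                  plaConfig(maskThreshold = thr)))), numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("distance profiles normalise per group with boundary-aligned bins", {
  prof <- distanceDensityProfile(rep(10, 50), binWidth = 50)
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$bin_left, 0)
  expect_equal(prof$density, 1)

  set.seed(5)
  d <- stats::rnorm(500, 0, 150)
  g <- data.frame(grp = sample(c("a", "b"), 500, TRUE))
  prof2 <- distanceDensityProfile(d, g, binWidth = 25)
  sums <- tapply(prof2$density, prof2$grp, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(prof2$bin_left %% 25 == 0))
})
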