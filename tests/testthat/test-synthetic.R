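# Seeded generators: determinism, marginals, validator compliance.

test_that("identical seeds reproduce identical networks and mosaics", {
  s <- networkSpec(nSegments = 60, seed = 42)
  n1 <- makeNetwork(s); n2 <- makeNetwork(s)
  expect_identical(segmentTable(n1), segmentTable(n2))
  expect_identical(segmentGeometry(n1), segmentGeometry(n2))
  m1 <- makeMosaic(mosaicSpec(nx = 10, ny = 10, seed = 42))
  m2 <- makeMosaic(mosaicSpec(nx = 10, ny = 10, seed = 42))
  expect_identical(mapClasses(m1), mapClasses(m2))
  # a different seed changes the draw
  n3 <- makeNetwork(networkSpec(nSegments = 60, seed = 43))
  expect_false(identical(segmentGeometry(n1), segmentGeometry(n3)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123); a <- runif(3)
  set.seed(123); invisible(makeNetwork(networkSpec(nSegments = 10, seed = 9)))
  b <- runif(3)
  expect_identical(a, b)
})

test_that("forced marginals propagate to scores", {
  net <- makeNetwork(networkSpec(nSegments = 40, pNps = 1, pUnknown = 0,
                                 seed = 6))
  p <- scorePresence(net, "nps")
  expect_true(all(p == 0))
  net2 <- makeNetwork(networkSpec(nSegments = 40, pBarrier = 1, pUnknown = 0,
                                  seed = 6))
  expect_true(all(scoreBarrier(segmentTable(net2)$barrier) == 2))
  expect_error(networkSpec(nSegments = 0))
})

test_that("generated networks are connected trees with the requested size", {
  net <- makeNetwork(networkSpec(nSegments = 120, seed = 14))
  expect_equal(nSegments(net), 120L)
  g <- riparify:::networkGraph(net)
  expect_equal(igraph::components(g)$no, 1L)
  # grid mode builds a lattice, also connected at this size
  netg <- makeNetwork(networkSpec(nSegments = 60, mode = "grid", seed = 14))
  expect_equal(nSegments(netg), 60L)
})

test_that("attribute frequencies converge to the spec marginals", {
  spec <- networkSpec(nSegments = 5000, pBarrier = 0.4,
                      pEc = c(natural = 0.2, semi_natural = 0.3,
                              artificial = 0.5),
                      pUnknown = 0, pRestored = 0.1, seed = 27)
  seg <- segmentTable(makeNetwork(spec))
  bt <- table(factor(seg$barrier, c("yes", "no")))
  expect_gt(chisq.test(bt, p = c(0.4, 0.6))$p.value, 0.01)
  et <- table(factor(seg$ec, c("natural", "semi_natural", "artificial")))
  expect_gt(chisq.test(et, p = c(0.2, 0.3, 0.5))$p.value, 0.01)
  expect_equal(mean(seg$restored), 0.1, tolerance = 0.3)
})

test_that("mosaic class mixture is honored within sampling error", {
  mix <- c(EI = 0, Farmland = 0.7, Forest = 0.3, Settlement = 0, TI = 0)
  m <- makeMosaic(mosaicSpec(nx = 80, ny = 80, mixture = mix, seed = 12))
  a <- vapply(mapPolygons(m), riparify:::polygonArea, numeric(1))
  share <- sum(a[mapClasses(m) == "Farmland"]) / sum(a)
  expect_equal(share, 0.7, tolerance = 0.03 / 0.7)  # within 3 points
  # single-class mixture dissolves to one patch spanning the grid
  mix1 <- c(EI = 0, Farmland = 1, Forest = 0, Settlement = 0, TI = 0)
  m1 <- makeMosaic(mosaicSpec(nx = 8, ny = 8, mixture = mix1, seed = 1))
  expect_equal(metricNP(dissolvePatches(m1, "Farmland")), 1L)
})

test_that("the category-unknown share tracks the data-deficiency rate", {
  net <- makeNetwork(networkSpec(nSegments = 2000, pUnknown = 0.13, seed = 5))
  sc <- scoreNetwork(net)
  restored <- segmentTable(net)$restored
  unk <- mean(sc$category[!restored] == "unknown")
  expect_equal(unk, 0.13, tolerance = 0.25)
})

test_that("the worked fixture exercises every scoring branch", {
  fx <- makeWorkedFixture()
  seg <- segmentTable(fx$network)
  expect_setequal(fx$expected$category,
                  c("very_high", "very_low", "moderate", "high",
                    "already_restored", "unknown"))
  expect_true(all(c("natural", "semi_natural", "artificial", "unknown") %in%
                    seg$ec))
  expect_true(any(seg$restored))
  sc <- scoreNetwork(fx$network)
  expect_equal(as.character(sc$category), fx$expected$category)
})
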