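# Study-area buffers and land-cover composition within them.

test_that("straight-segment buffer area matches the closed-form capsule", {
  net <- buildNetwork(list(rbind(c(0, 0), c(1000, 0))))
  sa <- buildStudyArea(net, spec = bufferSpec(sideWidthM = 40))
  exact <- 2 * 40 * 1000 + pi * 40^2
  expect_equal(areaM2(sa), exact, tolerance = 1e-3)
  # flat caps drop the two half-discs
  saf <- buildStudyArea(net, spec = bufferSpec(sideWidthM = 40),
                        capStyle = "flat")
  expect_equal(areaM2(saf), 2 * 40 * 1000, tolerance = 1e-3)
})

test_that("disjoint far-apart segments give a two-part study area", {
  net <- buildNetwork(list(rbind(c(0, 0), c(500, 0)),
                           rbind(c(5000, 0), c(5500, 0))))
  sa <- buildStudyArea(net)
  expect_equal(nParts(sa), 2L)
  # close segments merge into one part
  net2 <- buildNetwork(list(rbind(c(0, 0), c(500, 0)),
                            rbind(c(550, 0), c(1000, 0))))
  expect_equal(nParts(buildStudyArea(net2)), 1L)
})

test_that("study-area area is monotone in both widths and subadditive", {
  net <- buildNetwork(list(rbind(c(0, 0), c(400, 0)),
                           rbind(c(400, 0), c(400, 300))))
  main <- rbind(c(-200, 150), c(600, 150))
  a1 <- areaM2(buildStudyArea(net, main, bufferSpec(60, 40)))
  a2 <- areaM2(buildStudyArea(net, main, bufferSpec(80, 40)))
  a3 <- areaM2(buildStudyArea(net, main, bufferSpec(60, 55)))
  expect_gt(a2, a1)
  expect_gt(a3, a1)
  partSum <- areaM2(buildStudyArea(net, NULL, bufferSpec(60, 40))) +
    areaM2(new("StudyArea",
               sources = cbind(riparify:::polylineEdges(main), width = 60),
               capStyle = "round"))
  expect_lte(a1, partSum * (1 + 1e-6))
  expect_error(buildStudyArea(buildNetwork(list())), "non-empty")
})

test_that("a buffer inside one class reports 100% of that class", {
  m <- landCoverMap(list(sq(-100, -100, 1200)), "Farmland", "2019")
  net <- buildNetwork(list(rbind(c(100, 400), c(900, 500))))
  sc <- scoreNetwork(net)
  sc$category <- factor("very_high", levels = reportCategories())
  comp <- bufferComposition(net, sc, m, widthM = 40)
  expect_equal(comp$Farmland, 100, tolerance = 1e-6)
  expect_equal(comp$uncovered, 0, tolerance = 1e-6)
})

test_that("a buffer split evenly across two classes reports 50/50 at 1 dp", {
  m <- landCoverMap(list(rbind(c(-200, -200), c(1200, -200), c(1200, 0), c(-200, 0)),
                         rbind(c(-200, 0), c(1200, 0), c(1200, 200), c(-200, 200))),
                    c("Farmland", "Forest"), "2019")
  net <- buildNetwork(list(rbind(c(0, 0), c(1000, 0))))
  sc <- scoreNetwork(net)
  sc$category <- factor("high", levels = reportCategories())
  comp <- bufferComposition(net, sc, m, widthM = 40)
  expect_equal(roundHalfUp(comp$Farmland, 1), 50.0)
  expect_equal(roundHalfUp(comp$Forest, 1), 50.0)
})

test_that("composition rows sum to 100 and uncovered ground is explicit", {
  m <- makeMosaic(mosaicSpec(nx = 20, ny = 20, cellM = 50, seed = 8,
                             origin = c(0, 0)))
  net <- buildNetwork(list(rbind(c(100, 200), c(700, 300)),
                           rbind(c(700, 300), c(950, 800)),
                           rbind(c(100, 900), c(1900, 950))))  # leaves the map
  sc <- scoreNetwork(net)
  sc$category <- factor(c("high", "high", "moderate"),
                        levels = reportCategories())
  comp <- bufferComposition(net, sc, m, widthM = 40)
  sums <- rowSums(comp[, c(landCoverClasses(), "uncovered")])
  expect_equal(unname(sums), rep(100, nrow(comp)), tolerance = 1e-6)
  expect_gt(comp$uncovered[comp$category == "moderate"], 0)
})

test_that("composition is invariant to segment order and collinear splits", {
  m <- makeMosaic(mosaicSpec(nx = 12, ny = 12, cellM = 60, seed = 10,
                             origin = c(0, 0)))
  gA <- list(rbind(c(50, 100), c(650, 120)), rbind(c(100, 500), c(600, 520)))
  gB <- rev(gA)
  gSplit <- list(rbind(c(50, 100), c(350, 110)), rbind(c(350, 110), c(650, 120)),
                 rbind(c(100, 500), c(600, 520)))
  mk <- function(g) {
    net <- buildNetwork(g)
    sc <- scoreNetwork(net)
    sc$category <- factor("low", levels = reportCategories())
    bufferComposition(net, sc, m, widthM = 40)
  }
  cA <- mk(gA); cB <- mk(gB); cS <- mk(gSplit)
  for (cl in landCoverClasses()) {
    expect_equal(cA[[cl]], cB[[cl]], tolerance = 1e-9)
    expect_equal(cA[[cl]], cS[[cl]], tolerance = 1e-3)
  }
})
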