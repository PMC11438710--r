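# Patch dissolution and the class-level metric set.

test_that("abutting polygons dissolve into one patch, separated ones stay apart", {
  m <- landCoverMap(list(sq(0, 0, 1), sq(1, 0, 1), sq(3, 0, 1)),
                    c("EI", "EI", "EI"), "t")
  p <- dissolvePatches(m, "EI")
  expect_equal(metricNP(p), 2L)
  areas <- sort(vapply(p, `[[`, numeric(1), "area_m2"))
  expect_equal(areas, c(1, 2))
  # merged pair: perimeter of a 2 x 1 rectangle, internal wall cancelled
  per <- vapply(p, `[[`, numeric(1), "perimeter_m")
  expect_equal(sort(per), c(4, 6))
  expect_equal(dissolvePatches(m, "Forest"), list())
})

test_that("corner contact merges under queen and splits under rook contiguity", {
  cls <- matrix(c("EI", "Farmland", "Farmland", "EI"), 2, 2)
  m <- gridMosaic(cls)
  expect_equal(metricNP(dissolvePatches(m, "EI", "queen")), 1L)
  expect_equal(metricNP(dissolvePatches(m, "EI", "rook")), 2L)
  # flood-fill oracle agrees on random checkerboards
  set.seed(31)
  for (k in 1:8) {
    mask <- matrix(runif(49) < 0.5, 7, 7)
    cm <- ifelse(mask, "Forest", "Farmland")
    mm <- gridMosaic(cm)
    expect_equal(metricNP(dissolvePatches(mm, "Forest", "queen")),
                 oracleFloodCount(mask, queen = TRUE))
    expect_equal(metricNP(dissolvePatches(mm, "Forest", "rook")),
                 oracleFloodCount(mask, queen = FALSE))
  }
})

test_that("a dissolved ring keeps its hole in area and perimeter", {
  # 3x3 ring of EI around one Farmland cell
  cls <- matrix("EI", 3, 3); cls[2, 2] <- "Farmland"
  m <- gridMosaic(cls)
  p <- dissolvePatches(m, "EI")
  expect_equal(metricNP(p), 1L)
  expect_equal(p[[1]]$area_m2, 8)
  expect_equal(p[[1]]$perimeter_m, 12 + 4)  # outer 12, hole boundary 4
})

test_that("NP, MPS and ED compute their defining formulas", {
  m <- landCoverMap(list(sq(0, 0, 100)), "Forest", "t")
  p <- dissolvePatches(m, "Forest")
  expect_equal(metricNP(p), 1L)
  expect_equal(metricMPS(p), 1.0)   # 10,000 m2 -> 1 ha
  m2 <- landCoverMap(list(sq(0, 0, sqrt(5000)), sq(200, 0, sqrt(15000))),
                     c("Forest", "Forest"), "t")
  expect_equal(metricMPS(dissolvePatches(m2, "Forest")), 1.0)
  expect_equal(metricED(p, landscapeAreaM2 = 10000), 400)
  expect_equal(metricED(p, landscapeAreaM2 = 20000), 200)  # linear in 1/area
  expect_equal(metricED(list(), 10000), 0)
  expect_error(metricED(p, 0), "landscapeAreaM2")
  expect_true(is.na(metricMPS(list())))
})

test_that("MNND matches constructed cases and the exhaustive oracle", {
  # collinear squares with gaps 10 and 30
  m <- landCoverMap(list(sq(0, 0, 10), sq(20, 0, 10), sq(60, 0, 10)),
                    rep("Settlement", 3), "t")
  p <- dissolvePatches(m, "Settlement")
  expect_equal(metricMNND(p), (10 + 10 + 30) / 3)
  expect_equal(metricMNND(p), oracleMNND(p))
  # symmetric pair
  m2 <- landCoverMap(list(sq(0, 0, 10), sq(20, 0, 10)), rep("TI", 2), "t")
  expect_equal(metricMNND(dissolvePatches(m2, "TI")), 10)
  expect_true(is.na(metricMNND(dissolvePatches(
    landCoverMap(list(sq(0, 0, 10)), "TI", "t"), "TI"))))
  # random scatters against the O(n^2) oracle
  set.seed(17)
  for (k in 1:5) {
    polys <- lapply(1:8, function(i) sq(runif(1, 0, 200), runif(1, 0, 200), 5))
    mm <- landCoverMap(polys, rep("EI", 8), "t")
    pp <- dissolvePatches(mm, "EI")
    expect_equal(metricMNND(pp), oracleMNND(pp), tolerance = 1e-9)
  }
})

test_that("MSI is 1 for circles, 2/sqrt(pi) for squares, mean over patches", {
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  circle <- cbind(50 * cos(th), 50 * sin(th))
  m <- landCoverMap(list(circle), "Forest", "t")
  expect_equal(metricMSI(dissolvePatches(m, "Forest")), 1, tolerance = 1e-3)
  msq <- landCoverMap(list(sq(0, 0, 30)), "Forest", "t")
  expect_equal(metricMSI(dissolvePatches(msq, "Forest")), 2 / sqrt(pi),
               tolerance = 1e-9)
  # adding an identical square leaves the mean unchanged
  msq2 <- landCoverMap(list(sq(0, 0, 30), sq(100, 0, 30)),
                       rep("Forest", 2), "t")
  expect_equal(metricMSI(dissolvePatches(msq2, "Forest")), 2 / sqrt(pi),
               tolerance = 1e-9)
})

test_that("metrics scale correctly under uniform geometry scaling", {
  set.seed(23)
  polys <- lapply(1:6, function(i) sq(runif(1, 0, 100), runif(1, 0, 100),
                                      runif(1, 3, 10)))
  m1 <- landCoverMap(polys, rep("EI", 6), "t")
  k <- 3.5
  m2 <- landCoverMap(lapply(polys, function(p) p * k), rep("EI", 6), "t")
  p1 <- dissolvePatches(m1, "EI"); p2 <- dissolvePatches(m2, "EI")
  A1 <- 200^2; A2 <- (200 * k)^2
  expect_equal(metricMPS(p2), metricMPS(p1) * k^2, tolerance = 1e-9)
  expect_equal(metricED(p2, A2), metricED(p1, A1) / k, tolerance = 1e-9)
  expect_equal(metricMNND(p2), metricMNND(p1) * k, tolerance = 1e-9)
  expect_equal(metricMSI(p2), metricMSI(p1), tolerance = 1e-9)
})

test_that("class areas of an exhaustive mosaic conserve the landscape area", {
  m <- makeMosaic(mosaicSpec(nx = 18, ny = 14, seed = 4))
  tab <- classMetrics(m)
  expect_equal(sum(tab$area_pct), 100, tolerance = 1e-6)
  byClassArea <- sum(tab$area_pct / 100 * landscapeAreaM2(m))
  expect_equal(byClassArea, landscapeAreaM2(m), tolerance = 1e-6)
})

test_that("ED boundary-exclusion mode drops study-area boundary edges", {
  # single Forest cell in the corner of a 2x2 mosaic: two of its four edges
  # lie on the landscape boundary
  cls <- matrix(c("Forest", "Farmland", "Farmland", "Farmland"), 2, 2)
  m <- gridMosaic(cls, cellM = 10)
  p <- dissolvePatches(m, "Forest")
  boundary <- riparify:::ringEdges(sq(0, 0, 20))
  A <- landscapeAreaM2(m)
  expect_equal(metricED(p, A), 40 / A * 10000)
  expect_equal(metricED(p, A, includeBoundary = FALSE,
                        landscapeBoundary = boundary), 20 / A * 10000)
})

test_that("change tables difference printed area summaries and self-cancel", {
  a <- data.frame(cls = c("Farmland", "Settlement"),
                  area_km2 = c(4.85, 0.06), area_pct = c(84.98, 0.98))
  b <- data.frame(cls = c("Farmland", "Settlement"),
                  area_km2 = c(3.94, 0.43), area_pct = c(69.03, 7.52))
  ch <- changeTable(a, b)
  expect_equal(ch$d_area_km2[ch$cls == "Farmland"], -0.91)
  expect_equal(ch$d_area_km2[ch$cls == "Settlement"], 0.37)
  m <- makeMosaic(mosaicSpec(nx = 10, ny = 10, seed = 6))
  ch0 <- changeTable(m, m)
  expect_true(all(ch0$d_area_km2 == 0) && all(ch0$d_area_pct == 0))
  expect_error(changeTable(a, data.frame(cls = "EI", area_km2 = 1)), "schema")
})
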