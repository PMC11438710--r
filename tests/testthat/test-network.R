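# Topology construction: endpoint snapping, node incidence, validity.

test_that("exact shared endpoints unify into one node at zero tolerance", {
  g <- list(rbind(c(0, 0), c(100, 0)), rbind(c(100, 0), c(200, 50)))
  net <- buildNetwork(g, snapTol = 0)
  expect_equal(nrow(nodeCoords(net)), 3L)
  seg <- segmentTable(net)
  expect_equal(seg$to[1], seg$from[2])
})

test_that("snapping tolerance decides whether nearby endpoints share a node", {
  g <- list(rbind(c(0, 0), c(100, 0)), rbind(c(100.5, 0), c(200, 0)))
  expect_equal(nrow(nodeCoords(buildNetwork(g, snapTol = 1.0))), 3L)
  expect_equal(nrow(nodeCoords(buildNetwork(g, snapTol = 0.1))), 4L)
  # both agree with the brute-force transitive clustering oracle
  expect_equal(nrow(nodeCoords(buildNetwork(g, snapTol = 1.0))),
               oracleNodeCount(g, 1.0))
  expect_equal(nrow(nodeCoords(buildNetwork(g, snapTol = 0.1))),
               oracleNodeCount(g, 0.1))
})

test_that("node construction matches the clustering oracle on random inputs", {
  set.seed(7)
  for (k in 1:15) {
    n <- sample(3:12, 1)
    g <- lapply(seq_len(n), function(i) {
      a <- runif(2, 0, 50)
      rbind(a, a + runif(2, 5, 30))
    })
    tol <- runif(1, 0, 3)
    expect_equal(nrow(nodeCoords(buildNetwork(g, snapTol = tol))),
                 oracleNodeCount(g, tol))
  }
})

test_that("construction rejects duplicate ids and zero-length geometry", {
  g <- list(rbind(c(0, 0), c(100, 0)), rbind(c(100, 0), c(200, 0)))
  expect_error(buildNetwork(g, data.frame(id = c("a", "a"))), "duplicate")
  gz <- list(rbind(c(0, 0), c(0, 0)))
  expect_error(buildNetwork(gz, data.frame(id = "z")), "zero-length.*z")
})

test_that("topology construction is idempotent and order-independent", {
  net <- makeNetwork(networkSpec(nSegments = 40, seed = 3), snapTol = 0.5)
  rebuilt <- buildNetwork(segmentGeometry(net), segmentTable(net),
                          snapTol = net@snapTol)
  expect_equal(nodeCoords(rebuilt), nodeCoords(net))
  expect_equal(segmentTable(rebuilt)$from, segmentTable(net)$from)
  expect_equal(segmentTable(rebuilt)$to, segmentTable(net)$to)

  perm <- sample(nSegments(net))
  permuted <- buildNetwork(segmentGeometry(net)[perm],
                           segmentTable(net)[perm, ], snapTol = net@snapTol)
  expect_equal(nodeCoords(permuted), nodeCoords(net))
  expect_equal(segmentTable(permuted)$from, segmentTable(net)$from[perm])
})

test_that("total length is the sum of planar segment lengths", {
  net <- makeNetwork(networkSpec(nSegments = 25, seed = 9))
  manual <- sum(vapply(segmentGeometry(net), function(g)
    sum(sqrt(diff(g[, 1])^2 + diff(g[, 2])^2)), numeric(1)))
  expect_equal(totalLengthKm(net), manual / 1000, tolerance = 1e-6)
})
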