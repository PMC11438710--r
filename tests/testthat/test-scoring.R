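# The priority model: criterion point rules, network adjacency, weighted
# aggregation, categorization.

test_that("criterion point tables follow the published rules", {
  expect_equal(scoreBarrier(c("yes", "no", "unknown")), c(2, 0, NA))
  expect_equal(scoreEc(c("natural", "semi_natural", "artificial", "unknown")),
               c(0, 1, 2, NA))
})

test_that("adjacency follows along-network distance with the 500 m rule", {
  # chain: A (flagged, 200 m) - B (300 m) - C (600 m)
  g <- list(rbind(c(0, 0), c(200, 0)),
            rbind(c(200, 0), c(500, 0)),
            rbind(c(500, 0), c(1100, 0)))
  at <- data.frame(id = c("A", "B", "C"),
                   nps = c("present", "absent", "absent"))
  net <- buildNetwork(g, at, snapTol = 0)
  adj <- adjacentToFlagged(net, "nps", maxDist = 500)
  expect_true(adj[["B"]])   # shares a node: distance 0
  expect_true(adj[["C"]])   # 300 m along the network
  # with B 600 m long, C sits 600 m away: beyond the rule
  g2 <- g; g2[[2]] <- rbind(c(200, 0), c(800, 0)); g2[[3]] <- rbind(c(800, 0), c(1400, 0))
  net2 <- buildNetwork(g2, at, snapTol = 0)
  expect_false(adjacentToFlagged(net2, "nps", maxDist = 500)[["C"]])
  # sharing a node keeps B adjacent even at maxDist = 0
  expect_true(adjacentToFlagged(net2, "nps", maxDist = 0)[["B"]])
  expect_error(adjacentToFlagged(net, "nps", segId = "nope"), "not in network")
})

test_that("presence scoring: present 0, absent-with-neighbor 2, isolated 1", {
  g <- list(rbind(c(0, 0), c(200, 0)),
            rbind(c(200, 0), c(500, 0)),
            rbind(c(5000, 0), c(5300, 0)))
  at <- data.frame(id = c("A", "B", "far"),
                   nps = c("present", "absent", "absent"))
  net <- buildNetwork(g, at, snapTol = 0)
  p <- scorePresence(net, "nps")
  expect_equal(unname(p), c(0, 2, 1))
  # presence dominates adjacency: two flagged neighbors both score 0
  at2 <- at; at2$nps <- c("present", "present", "absent")
  p2 <- scorePresence(buildNetwork(g, at2, snapTol = 0), "nps")
  expect_equal(unname(p2[1:2]), c(0, 0))
})

test_that("weighted score reproduces the 0-8 scale and rejects zero weights", {
  expect_equal(totalScore(2, 2, 2, 2), 8)
  expect_equal(totalScore(0, 0, 0, 0), 0)
  expect_equal(totalScore(2, 1, 1, 0), 4)
  # unequal weights: normalized weighted mean scaled by 4
  w <- priorityWeights(barrier = 0.5, ec = 0.5, nps = 0, hdas = 0)
  expect_equal(totalScore(2, 1, 0, 0, w), 4 * (0.5 * 2 + 0.5 * 1))
  expect_error(priorityWeights(0, 0, 0, 0), "positive")
  expect_equal(totalScore(2, 2, NA, 2), NA_real_)
})

test_that("categorization precedence and default bins", {
  expect_equal(classifyScore(8), "very_high")
  expect_equal(classifyScore(0), "very_low")
  expect_equal(classifyScore(c(1, 1.01, 3, 5, 7, 7.5)),
               c("very_low", "low", "low", "moderate", "high", "very_high"))
  expect_equal(classifyScore(8, restored = TRUE), "already_restored")
  expect_equal(classifyScore(NA_real_), "unknown")
  expect_equal(classifyScore(NA_real_, restored = TRUE), "already_restored")
  expect_error(classifyScore(9), "outside")
  expect_error(priorityBins(c(0, 4, 9), c("a", "b")), "partition")
})

test_that("the worked fixture reproduces its hand-computed score table", {
  fx <- makeWorkedFixture()
  sc <- scoreNetwork(fx$network)
  expect_equal(sc$segment_id, fx$expected$segment_id)
  for (col in c("p_barrier", "p_ec", "p_nps", "p_hdas", "score"))
    expect_equal(sc[[col]], fx$expected[[col]], info = col)
  expect_equal(as.character(sc$category), fx$expected$category)
})

test_that("equal weights make the score the exact integer point sum", {
  net <- makeNetwork(networkSpec(nSegments = 60, seed = 21))
  sc <- scoreNetwork(net)
  ok <- !is.na(sc$score)
  expect_identical(sc$score[ok],
                   sc$p_barrier[ok] + sc$p_ec[ok] + sc$p_nps[ok] + sc$p_hdas[ok])
})

test_that("raising one criterion never lowers score or category", {
  catRank <- function(x) match(x, priorityCategories())
  set.seed(5)
  for (k in 1:20) {
    p <- sample(0:2, 4, replace = TRUE)
    w <- priorityWeights(runif(1), runif(1), runif(1), runif(1))
    base <- totalScore(p[1], p[2], p[3], p[4], w)
    i <- sample(1:4, 1)
    if (p[i] == 2) next
    p2 <- p; p2[i] <- p2[i] + 1
    up <- totalScore(p2[1], p2[2], p2[3], p2[4], w)
    expect_gte(up, base)
    expect_gte(catRank(classifyScore(min(up, 8))),
               catRank(classifyScore(min(base, 8))))
  }
})

test_that("adjacency symmetry: mutual neighbors mirror each other's bonus", {
  g <- list(rbind(c(0, 0), c(300, 0)), rbind(c(300, 0), c(600, 0)))
  mk <- function(npsA, npsB)
    buildNetwork(g, data.frame(id = c("X", "Y"), nps = c(npsA, npsB)),
                 snapTol = 0)
  pY <- scorePresence(mk("present", "absent"), "nps")
  pX <- scorePresence(mk("absent", "present"), "nps")
  expect_equal(unname(pY[["Y"]]), 2)
  expect_equal(unname(pX[["X"]]), 2)
})

test_that("every complete non-restored segment gets exactly one priority class", {
  net <- makeNetwork(networkSpec(nSegments = 150, seed = 13))
  sc <- scoreNetwork(net)
  complete <- !segmentTable(net)$restored & !is.na(sc$score)
  expect_true(all(as.character(sc$category[complete]) %in% priorityCategories()))
  expect_true(all(as.character(sc$category[segmentTable(net)$restored]) ==
                    "already_restored"))
  expect_true(all(as.character(sc$category[!segmentTable(net)$restored &
                                             is.na(sc$score)]) == "unknown"))
})

test_that("euclidean and node adjacency modes behave as documented", {
  # two parallel segments 100 m apart, connected only via a long detour
  g <- list(rbind(c(0, 0), c(300, 0)),
            rbind(c(0, 100), c(300, 100)),
            rbind(c(300, 0), c(2000, 0)), rbind(c(2000, 0), c(2000, 100)),
            rbind(c(2000, 100), c(300, 100)))
  at <- data.frame(id = c("A", "B", "c1", "c2", "c3"),
                   nps = c("present", "absent", "absent", "absent", "absent"))
  net <- buildNetwork(g, at, snapTol = 0)
  expect_false(adjacentToFlagged(net, "nps", 500, mode = "network")[["B"]])
  expect_true(adjacentToFlagged(net, "nps", 500, mode = "euclidean")[["B"]])
  nodeAdj <- adjacentToFlagged(net, "nps", 500, mode = "node")
  expect_true(nodeAdj[["c1"]])
  expect_false(nodeAdj[["c2"]])
})
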