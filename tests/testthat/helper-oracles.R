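# Independent oracles and small fixture builders. All math here is written
# from first principles, deliberately separate from the package internals it
# cross-checks.

# axis-aligned square ring
sq <- function(x0, y0, s) {
  cbind(c(x0, x0 + s, x0 + s, x0), c(y0, y0, y0 + s, y0 + s))
}

# --- all-pairs node distances by Floyd-Warshall ----------------------------

fwNodeDistances <- function(net) {
  seg <- segmentTable(net)
  nn <- nrow(nodeCoords(net))
  D <- matrix(Inf, nn, nn)
  diag(D) <- 0
  for (k in seq_len(nrow(seg))) {
    i <- seg$from[k]; j <- seg$to[k]
    D[i, j] <- min(D[i, j], seg$length_m[k])
    D[j, i] <- D[i, j]
  }
  for (k in seq_len(nn))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# adjacency of every segment to flagged segments by exhaustive shortest paths
oracleAdjacent <- function(net, flag, maxDist) {
  seg <- segmentTable(net)
  flagged <- which(seg[[flag]] == "present")
  if (length(flagged) == 0L) return(rep(FALSE, nrow(seg)))
  D <- fwNodeDistances(net)
  fnodes <- unique(c(seg$from[flagged], seg$to[flagged]))
  vapply(seq_len(nrow(seg)), function(i)
    min(D[c(seg$from[i], seg$to[i]), fnodes]) <= maxDist, logical(1))
}

# full scoring by direct rule application on top of the adjacency oracle
oracleScores <- function(net, maxDist = 500) {
  seg <- segmentTable(net)
  pts <- function(v, map) unname(map[v])
  pb <- pts(seg$barrier, c(yes = 2, no = 0, unknown = NA))
  pe <- pts(seg$ec, c(natural = 0, semi_natural = 1, artificial = 2,
                      unknown = NA))
  presence <- function(flag) {
    adj <- oracleAdjacent(net, flag, maxDist)
    v <- seg[[flag]]
    ifelse(v == "present", 0, ifelse(v == "unknown", NA, ifelse(adj, 2, 1)))
  }
  pn <- presence("nps"); ph <- presence("hdas")
  score <- pb + pe + pn + ph
  list(p = cbind(pb, pe, pn, ph), score = score)
}

# --- brute-force endpoint clustering ---------------------------------------

# transitive closure of the within-tol endpoint graph; returns the number of
# distinct endpoint clusters
oracleNodeCount <- function(geoms, tol) {
  ends <- do.call(rbind, lapply(geoms, function(g)
    rbind(g[1, ], g[nrow(g), ])))
  n <- nrow(ends)
  A <- as.matrix(stats::dist(ends)) <= max(tol, 0)
  if (tol <= 0) A <- as.matrix(stats::dist(ends)) == 0
  diag(A) <- TRUE
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  nrow(unique(A))
}

# --- exhaustive pairwise patch distances -----------------------------------

# nearest edge-to-edge distance, O(n^2) over all boundary segment pairs,
# with its own point/segment math
oraclePointSeg <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx^2 + dy^2
  t <- if (l2 == 0) 0 else min(1, max(0, ((px - ax) * dx + (py - ay) * dy) / l2))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

oracleCross <- function(p1, p2, p3, p4) {
  o <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o(p1, p2, p3) * o(p1, p2, p4) < 0 && o(p3, p4, p1) * o(p3, p4, p2) < 0
}

oracleEdgeDist <- function(ea, eb) {
  best <- Inf
  for (i in seq_len(nrow(ea))) for (j in seq_len(nrow(eb))) {
    if (oracleCross(c(ea$x1[i], ea$y1[i]), c(ea$x2[i], ea$y2[i]),
                    c(eb$x1[j], eb$y1[j]), c(eb$x2[j], eb$y2[j])))
      return(0)
    best <- min(best,
      oraclePointSeg(ea$x1[i], ea$y1[i], eb$x1[j], eb$y1[j], eb$x2[j], eb$y2[j]),
      oraclePointSeg(ea$x2[i], ea$y2[i], eb$x1[j], eb$y1[j], eb$x2[j], eb$y2[j]),
      oraclePointSeg(eb$x1[j], eb$y1[j], ea$x1[i], ea$y1[i], ea$x2[i], ea$y2[i]),
      oraclePointSeg(eb$x2[j], eb$y2[j], ea$x1[i], ea$y1[i], ea$x2[i], ea$y2[i]))
  }
  best
}

oracleMNND <- function(patches) {
  n <- length(patches)
  if (n < 2L) return(NA_real_)
  nnd <- vapply(seq_len(n), function(i) {
    min(vapply(setdiff(seq_len(n), i), function(j)
      oracleEdgeDist(patches[[i]]$edges, patches[[j]]$edges), numeric(1)))
  }, numeric(1))
  mean(nnd)
}

# --- flood fill over a class grid ------------------------------------------

# connected components of TRUE cells in a logical matrix under queen or rook
# contiguity
oracleFloodCount <- function(mask, queen = TRUE) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nbr <- if (queen)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  comp <- 0L
  for (i0 in seq_len(nrow(mask))) for (j0 in seq_len(ncol(mask))) {
    if (!mask[i0, j0] || lab[i0, j0] > 0L) next
    comp <- comp + 1L
    queue <- list(c(i0, j0)); lab[i0, j0] <- comp
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbr))) {
        i <- p[1] + nbr[k, 1]; j <- p[2] + nbr[k, 2]
        if (i >= 1 && j >= 1 && i <= nrow(mask) && j <= ncol(mask) &&
            mask[i, j] && lab[i, j] == 0L) {
          lab[i, j] <- comp
          queue[[length(queue) + 1L]] <- c(i, j)
        }
      }
    }
  }
  comp
}

# grid mosaic with prescribed classes (matrix of class codes), unit cells
gridMosaic <- function(clsMatrix, cellM = 1, origin = c(0, 0),
                       epoch = "test") {
  nx <- nrow(clsMatrix); ny <- ncol(clsMatrix)
  polys <- list(); cls <- character(0)
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    polys[[length(polys) + 1L]] <-
      sq(origin[1] + (i - 1) * cellM, origin[2] + (j - 1) * cellM, cellM)
    cls <- c(cls, clsMatrix[i, j])
  }
  landCoverMap(polys, cls, epoch)
}
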