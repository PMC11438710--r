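# Planar geometry primitives.
#
# All coordinates are planar metric (meters). Polygons are lists of rings;
# each ring is an n x 2 numeric matrix, not necessarily closed (the closing
# edge last->first is implied). Ring 1 is the exterior shell, rings 2..k are
# holes. Polylines are n x 2 matrices of consecutive vertices.

# ---- polylines ---------------------------------------------------------

polylineLength <- function(coords) {
  if (!is.matrix(coords) || nrow(coords) < 2L) return(0)
  sum(sqrt(diff(coords[, 1])^2 + diff(coords[, 2])^2))
}

# decompose a polyline into straight edges: data.frame(x1,y1,x2,y2)
polylineEdges <- function(coords) {
  n <- nrow(coords)
  data.frame(x1 = coords[-n, 1], y1 = coords[-n, 2],
             x2 = coords[-1, 1], y2 = coords[-1, 2])
}

closeRing <- function(ring) {
  n <- nrow(ring)
  if (n >= 2L && (ring[1, 1] != ring[n, 1] || ring[1, 2] != ring[n, 2]))
    ring <- rbind(ring, ring[1, , drop = FALSE])
  ring
}

ringEdges <- function(ring) polylineEdges(closeRing(ring))

polygonEdges <- function(rings) do.call(rbind, lapply(rings, ringEdges))

# ---- area / perimeter --------------------------------------------------

ringSignedArea <- function(ring) {
  ring <- closeRing(ring)
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

# area of shell minus holes; orientation of input rings is irrelevant
polygonArea <- function(rings) {
  a <- vapply(rings, function(r) abs(ringSignedArea(r)), numeric(1))
  if (length(a) == 0L) return(0)
  a[1] - sum(a[-1])
}

# hole boundaries count as edges of the polygon
polygonPerimeter <- function(rings) {
  sum(vapply(rings, function(r) polylineLength(closeRing(r)), numeric(1)))
}

polygonBBox <- function(rings) {
  xs <- unlist(lapply(rings, function(r) r[, 1]))
  ys <- unlist(lapply(rings, function(r) r[, 2]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

bboxesIntersect <- function(a, b, tol = 0) {
  a["xmin"] <= b["xmax"] + tol && b["xmin"] <= a["xmax"] + tol &&
    a["ymin"] <= b["ymax"] + tol && b["ymin"] <= a["ymax"] + tol
}

# ---- point-in-polygon --------------------------------------------------

# even-odd ray cast, vectorized over points; holes flip parity because all
# rings contribute crossings
pointInPolygon <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (ring in rings) {
    ring <- closeRing(ring)
    n <- nrow(ring)
    x1 <- ring[-n, 1]; y1 <- ring[-n, 2]
    x2 <- ring[-1, 1]; y2 <- ring[-1, 2]
    for (e in seq_len(n - 1L)) {
      crosses <- ((y1[e] > py) != (y2[e] > py))
      if (any(crosses)) {
        xin <- x1[e] + (py[crosses] - y1[e]) / (y2[e] - y1[e]) * (x2[e] - x1[e])
        flip <- rep(FALSE, length(px))
        flip[crosses] <- px[crosses] < xin
        inside <- xor(inside, flip)
      }
    }
  }
  inside
}

# ---- distances ---------------------------------------------------------

# distance from points (px,py) to one segment (ax,ay)-(bx,by); vectorized
# over points
distPointSegment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx * dx + dy * dy
  if (l2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / l2))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

# minimum distance from points to a set of segments (edges data.frame);
# vectorized over points, loops over edges
distPointsToEdges <- function(px, py, edges) {
  d <- rep(Inf, length(px))
  for (e in seq_len(nrow(edges))) {
    d <- pmin(d, distPointSegment(px, py, edges$x1[e], edges$y1[e],
                                  edges$x2[e], edges$y2[e]))
  }
  d
}

orient2d <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

# do segments p1-p2 and p3-p4 intersect (including touching)?
segmentsIntersect <- function(p1, p2, p3, p4, eps = 1e-12) {
  d1 <- orient2d(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
  d2 <- orient2d(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
  d3 <- orient2d(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
  d4 <- orient2d(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
  if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
      ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))) return(TRUE)
  onSeg <- function(d, p, q, r) {
    abs(d) <= eps && min(p[1], q[1]) - eps <= r[1] && r[1] <= max(p[1], q[1]) + eps &&
      min(p[2], q[2]) - eps <= r[2] && r[2] <= max(p[2], q[2]) + eps
  }
  onSeg(d1, p3, p4, p1) || onSeg(d2, p3, p4, p2) ||
    onSeg(d3, p1, p2, p3) || onSeg(d4, p1, p2, p4)
}

# strict interior crossing (not mere touching at endpoints/collinear contact)
segmentsCross <- function(p1, p2, p3, p4, eps = 1e-9) {
  d1 <- orient2d(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
  d2 <- orient2d(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
  d3 <- orient2d(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
  d4 <- orient2d(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
  (d1 > eps && d2 < -eps || d1 < -eps && d2 > eps) &&
    (d3 > eps && d4 < -eps || d3 < -eps && d4 > eps)
}

# distance from one point to many segments; vectorized over edges
distOnePointToEdges <- function(px, py, edges) {
  dx <- edges$x2 - edges$x1; dy <- edges$y2 - edges$y1
  l2 <- pmax(dx * dx + dy * dy, 1e-300)
  t <- pmin(1, pmax(0, ((px - edges$x1) * dx + (py - edges$y1) * dy) / l2))
  sqrt((px - (edges$x1 + t * dx))^2 + (py - (edges$y1 + t * dy))^2)
}

# minimum distance between two segment sets (edges data.frames); 0 if any
# pair crosses. For non-crossing segments the minimum is always attained at
# an endpoint of one against the body of the other.
edgeSetDistance <- function(ea, eb) {
  d <- Inf
  for (i in seq_len(nrow(ea))) {
    d <- min(d, distOnePointToEdges(ea$x1[i], ea$y1[i], eb),
             distOnePointToEdges(ea$x2[i], ea$y2[i], eb))
  }
  for (j in seq_len(nrow(eb))) {
    d <- min(d, distOnePointToEdges(eb$x1[j], eb$y1[j], ea),
             distOnePointToEdges(eb$x2[j], eb$y2[j], ea))
  }
  if (d > 0) {
    for (i in seq_len(nrow(ea))) {
      p1 <- c(ea$x1[i], ea$y1[i]); p2 <- c(ea$x2[i], ea$y2[i])
      for (j in seq_len(nrow(eb))) {
        if (segmentsCross(p1, p2, c(eb$x1[j], eb$y1[j]), c(eb$x2[j], eb$y2[j])))
          return(0)
      }
    }
  }
  d
}

# minimum boundary-to-boundary distance between two polygons
polygonBoundaryDistance <- function(ringsA, ringsB) {
  edgeSetDistance(polygonEdges(ringsA), polygonEdges(ringsB))
}

# ---- validity ----------------------------------------------------------

# does a ring self-intersect (edges crossing or non-adjacent edges touching)?
ringSelfIntersects <- function(ring) {
  ring <- closeRing(ring)
  e <- ringEdges(ring)
  n <- nrow(e)
  if (n < 3L) return(TRUE)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      p1 <- c(e$x1[i], e$y1[i]); p2 <- c(e$x2[i], e$y2[i])
      p3 <- c(e$x1[j], e$y1[j]); p4 <- c(e$x2[j], e$y2[j])
      if (adjacent) {
        if (segmentsCross(p1, p2, p3, p4)) return(TRUE)
      } else if (segmentsIntersect(p1, p2, p3, p4)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# do two polygons share interior area? Mere boundary contact (shared edges or
# corners, as between neighbors of a mosaic) does not count.
polygonsOverlap <- function(ringsA, ringsB, tol = 1e-9) {
  if (!bboxesIntersect(polygonBBox(ringsA), polygonBBox(ringsB))) return(FALSE)
  ea <- polygonEdges(ringsA); eb <- polygonEdges(ringsB)
  for (i in seq_len(nrow(ea))) {
    p1 <- c(ea$x1[i], ea$y1[i]); p2 <- c(ea$x2[i], ea$y2[i])
    for (j in seq_len(nrow(eb))) {
      if (segmentsCross(p1, p2, c(eb$x1[j], eb$y1[j]), c(eb$x2[j], eb$y2[j])))
        return(TRUE)
    }
  }
  strictlyInside <- function(ring, rings, otherEdges) {
    v <- unique(closeRing(ring))
    inside <- pointInPolygon(v[, 1], v[, 2], rings)
    if (!any(inside)) return(FALSE)
    dv <- distPointsToEdges(v[inside, 1], v[inside, 2], otherEdges)
    any(dv > tol)
  }
  strictlyInside(ringsA[[1]], ringsB, eb) || strictlyInside(ringsB[[1]], ringsA, ea)
}
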