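# Class-level vector landscape metrics (NP, MPS, ED, MNND, MSI) and
# epoch-to-epoch change tables.

#' Dissolve the polygons of one class into patches
#'
#' A patch is a maximal set of same-class polygons connected by boundary
#' contact. By default corner-only contact merges too (queen contiguity, the
#' natural vector-union semantics); `contiguity = "rook"` requires a shared
#' boundary of positive length. Patch area is the sum of member areas
#' (mosaic polygons are interior-disjoint); the patch perimeter is obtained
#' by noding all member boundary edges at each other's vertices and dropping
#' the pieces shared by two members, so internal walls cancel and hole
#' boundaries remain.
#'
#' @param map a [LandCoverMap-class].
#' @param cls one of [landCoverClasses()].
#' @param contiguity `"queen"` (default: shared edge or corner) or `"rook"`
#'   (shared edge only).
#' @param tol contact tolerance in meters (default 1e-6).
#' @return list of patches; each is a list with `members` (polygon indices
#'   into the map), `area_m2`, `perimeter_m` and `edges` (the outer/hole
#'   boundary pieces as a data.frame `x1,y1,x2,y2`, used for edge-to-edge
#'   distances). Empty list when the class is absent.
#' @export
dissolvePatches <- function(map, cls, contiguity = c("queen", "rook"),
                            tol = 1e-6) {
  stopifnot(is(map, "LandCoverMap"))
  contiguity <- match.arg(contiguity)
  idx <- which(map@cls == cls)
  if (length(idx) == 0L) return(list())
  polys <- map@polygons[idx]
  boxes <- lapply(polys, polygonBBox)
  n <- length(polys)

  # contact graph
  pairs <- NULL
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (!bboxesIntersect(boxes[[i]], boxes[[j]], tol)) next
        touch <- polygonsTouch(polys[[i]], polys[[j]], tol, contiguity)
        if (touch) pairs <- rbind(pairs, c(i, j))
      }
    }
  }
  member <- componentsFromPairs(n, pairs)

  patches <- lapply(split(seq_len(n), member), function(ix) {
    edges <- dissolveBoundary(polys[ix], tol)
    list(members = idx[ix],
         area_m2 = sum(vapply(polys[ix], polygonArea, numeric(1))),
         perimeter_m = sum(sqrt((edges$x2 - edges$x1)^2 +
                                (edges$y2 - edges$y1)^2)),
         edges = edges)
  })
  unname(patches)
}

# do two interior-disjoint polygons touch under the chosen contiguity rule?
polygonsTouch <- function(a, b, tol, contiguity) {
  d <- polygonBoundaryDistance(a, b)
  if (d > tol) return(FALSE)
  if (contiguity == "queen") return(TRUE)
  sharedEdgeLength(polygonEdges(a), polygonEdges(b), tol) > tol
}

# total length of collinear overlap between two edge sets
sharedEdgeLength <- function(ea, eb, tol) {
  total <- 0
  for (i in seq_len(nrow(ea))) {
    ax <- ea$x1[i]; ay <- ea$y1[i]; bx <- ea$x2[i]; by <- ea$y2[i]
    ux <- bx - ax; uy <- by - ay
    L <- sqrt(ux^2 + uy^2)
    if (L == 0) next
    ux <- ux / L; uy <- uy / L
    for (j in seq_len(nrow(eb))) {
      # both endpoints of eb edge close to the line of ea edge?
      d1 <- abs((eb$x1[j] - ax) * uy - (eb$y1[j] - ay) * ux)
      d2 <- abs((eb$x2[j] - ax) * uy - (eb$y2[j] - ay) * ux)
      if (d1 > tol || d2 > tol) next
      t1 <- (eb$x1[j] - ax) * ux + (eb$y1[j] - ay) * uy
      t2 <- (eb$x2[j] - ax) * ux + (eb$y2[j] - ay) * uy
      lo <- max(0, min(t1, t2)); hi <- min(L, max(t1, t2))
      if (hi > lo) total <- total + (hi - lo)
    }
  }
  total
}

componentsFromPairs <- function(n, pairs) {
  if (is.null(pairs))
    return(seq_len(n))
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(n)]
}

# node all member boundary edges at each other's vertices (handles
# T-junctions), then drop pieces traced by two members: what remains is the
# dissolved patch boundary (outer shell and holes)
dissolveBoundary <- function(polys, tol) {
  edges <- do.call(rbind, lapply(polys, polygonEdges))
  verts <- unique(do.call(rbind, lapply(polys, function(p)
    do.call(rbind, lapply(p, closeRing)))))
  pieces <- list()
  for (e in seq_len(nrow(edges))) {
    ax <- edges$x1[e]; ay <- edges$y1[e]; bx <- edges$x2[e]; by <- edges$y2[e]
    L2 <- (bx - ax)^2 + (by - ay)^2
    if (L2 == 0) next
    t <- ((verts[, 1] - ax) * (bx - ax) + (verts[, 2] - ay) * (by - ay)) / L2
    px <- ax + t * (bx - ax); py <- ay + t * (by - ay)
    on <- t > tol & t < 1 - tol &
      (verts[, 1] - px)^2 + (verts[, 2] - py)^2 <= tol^2
    ts <- sort(unique(c(0, t[on], 1)))
    pieces[[e]] <- data.frame(
      x1 = ax + ts[-length(ts)] * (bx - ax), y1 = ay + ts[-length(ts)] * (by - ay),
      x2 = ax + ts[-1] * (bx - ax), y2 = ay + ts[-1] * (by - ay))
  }
  pieces <- do.call(rbind, pieces)
  # canonical key: order endpoints, quantize to tolerance
  q <- function(v) round(v / max(tol, 1e-9))
  swap <- (q(pieces$x1) > q(pieces$x2)) |
    (q(pieces$x1) == q(pieces$x2) & q(pieces$y1) > q(pieces$y2))
  kx1 <- ifelse(swap, pieces$x2, pieces$x1)
  ky1 <- ifelse(swap, pieces$y2, pieces$y1)
  kx2 <- ifelse(swap, pieces$x1, pieces$x2)
  ky2 <- ifelse(swap, pieces$y1, pieces$y2)
  key <- paste(q(kx1), q(ky1), q(kx2), q(ky2))
  keep <- !(key %in% key[duplicated(key)])
  pieces[keep, , drop = FALSE]
}

#' Class-level landscape metrics
#'
#' The five class-level metrics over a list of patches (from
#' [dissolvePatches()]):
#' \describe{
#'   \item{NP}{number of patches.}
#'   \item{MPS}{mean patch size: total class area (m^2) / NP / 10,000, in
#'     hectares.}
#'   \item{ED}{edge density: total length of all edge segments involving the
#'     class (m) / landscape area (m^2) x 10,000, in m/ha. All patch
#'     perimeters count, including stretches on the landscape boundary;
#'     `includeBoundary = FALSE` excludes pieces lying on the supplied
#'     landscape boundary for sensitivity analysis.}
#'   \item{MNND}{mean nearest-neighbor distance: mean over patches of the
#'     nearest edge-to-edge distance to another patch of the same class, in
#'     meters; undefined (`NA`) when NP < 2.}
#'   \item{MSI}{mean shape index: mean over patches of
#'     perimeter / (2 * sqrt(pi * area)), the perimeter normalized by that of
#'     an equal-area circle; >= 1, equal to 1 for a circle.}
#' }
#'
#' @param patches list of patches from [dissolvePatches()].
#' @param landscapeAreaM2 total landscape area in m^2 (for ED).
#' @param includeBoundary logical; count perimeter pieces on the landscape
#'   boundary (default TRUE).
#' @param landscapeBoundary optional data.frame of boundary edges
#'   (`x1,y1,x2,y2`) used when `includeBoundary = FALSE`.
#' @param tol tolerance in meters for boundary-piece matching.
#' @return the metric value (`metricNP` integer; others numeric, `NA` when
#'   undefined).
#' @export
#' @examples
#' sq <- function(x0, y0, s) cbind(c(x0, x0 + s, x0 + s, x0),
#'                                 c(y0, y0, y0 + s, y0 + s))
#' m <- landCoverMap(list(sq(0, 0, 100)), "Forest", "2019")
#' p <- dissolvePatches(m, "Forest")
#' metricNP(p); metricMPS(p); metricMSI(p)   # 1, 1 ha, 2/sqrt(pi)
metricNP <- function(patches) length(patches)

#' @rdname metricNP
#' @export
metricMPS <- function(patches) {
  if (length(patches) == 0L) return(NA_real_)
  sum(vapply(patches, `[[`, numeric(1), "area_m2")) / length(patches) / 10000
}

#' @rdname metricNP
#' @export
metricED <- function(patches, landscapeAreaM2, includeBoundary = TRUE,
                     landscapeBoundary = NULL, tol = 1e-6) {
  if (landscapeAreaM2 <= 0) stop("landscapeAreaM2 must be > 0")
  if (length(patches) == 0L) return(0)
  per <- vapply(patches, function(p) {
    if (includeBoundary || is.null(landscapeBoundary)) return(p$perimeter_m)
    e <- p$edges
    keep <- !edgesOnBoundary(e, landscapeBoundary, tol)
    sum(sqrt((e$x2 - e$x1)^2 + (e$y2 - e$y1)^2)[keep])
  }, numeric(1))
  sum(per) / landscapeAreaM2 * 10000
}

# is each edge piece collinear-on and inside some boundary edge?
edgesOnBoundary <- function(e, boundary, tol) {
  mx <- (e$x1 + e$x2) / 2; my <- (e$y1 + e$y2) / 2
  d1 <- distPointsToEdges(e$x1, e$y1, boundary)
  d2 <- distPointsToEdges(e$x2, e$y2, boundary)
  dm <- distPointsToEdges(mx, my, boundary)
  d1 <= tol & d2 <= tol & dm <= tol
}

#' @rdname metricNP
#' @export
metricMNND <- function(patches) {
  n <- length(patches)
  if (n < 2L) return(NA_real_)
  boxes <- lapply(patches, function(p)
    c(xmin = min(p$edges$x1, p$edges$x2), ymin = min(p$edges$y1, p$edges$y2),
      xmax = max(p$edges$x1, p$edges$x2), ymax = max(p$edges$y1, p$edges$y2)))
  bboxDist <- function(a, b) {
    dx <- max(0, max(a["xmin"], b["xmin"]) - min(a["xmax"], b["xmax"]))
    dy <- max(0, max(a["ymin"], b["ymin"]) - min(a["ymax"], b["ymax"]))
    sqrt(dx^2 + dy^2)
  }
  nnd <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    # bbox separation is a lower bound on edge-to-edge distance: scan
    # candidates nearest-first and stop once the bound exceeds the best
    lb <- vapply(seq_len(n), function(j)
      if (j == i) Inf else unname(bboxDist(boxes[[i]], boxes[[j]])), numeric(1))
    for (j in order(lb)) {
      if (lb[j] >= best) break
      best <- min(best, edgeSetDistance(patches[[i]]$edges, patches[[j]]$edges))
    }
    nnd[i] <- best
  }
  mean(nnd)
}

#' @rdname metricNP
#' @export
metricMSI <- function(patches) {
  if (length(patches) == 0L) return(NA_real_)
  mean(vapply(patches, function(p)
    p$perimeter_m / (2 * sqrt(pi * p$area_m2)), numeric(1)))
}

#' Per-class metric table for one map epoch
#'
#' Dissolves each land-cover class into patches and reports the class-level
#' metric set: class area share of the landscape plus NP, MPS, ED, MNND and
#' MSI (see [metricNP()]).
#'
#' @param map a [LandCoverMap-class].
#' @inheritParams dissolvePatches
#' @inheritParams metricNP
#' @return data.frame with one row per class present: `cls`, `epoch`,
#'   `area_pct`, `mps_ha`, `msi`, `np`, `mnnd_m`, `ed_m_per_ha`.
#' @export
classMetrics <- function(map, contiguity = c("queen", "rook"),
                         includeBoundary = TRUE, landscapeBoundary = NULL) {
  stopifnot(is(map, "LandCoverMap"))
  contiguity <- match.arg(contiguity)
  A <- landscapeAreaM2(map)
  rows <- lapply(landCoverClasses(), function(cl) {
    patches <- dissolvePatches(map, cl, contiguity)
    if (length(patches) == 0L) return(NULL)
    data.frame(
      cls = cl, epoch = map@epoch,
      area_pct = sum(vapply(patches, `[[`, numeric(1), "area_m2")) / A * 100,
      mps_ha = metricMPS(patches),
      msi = metricMSI(patches),
      np = metricNP(patches),
      mnnd_m = metricMNND(patches),
      ed_m_per_ha = metricED(patches, A, includeBoundary, landscapeBoundary),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Land-cover change between two epochs
#'
#' Per-class area change between two mosaics (or two per-class area
#' summaries): the difference in km^2 and in percentage points of the
#' landscape. Inputs can be [LandCoverMap-class] objects or data.frames with
#' columns `cls`, `area_km2` and optionally `area_pct` (e.g. a published
#' area table); when `area_pct` is absent, shares of the summed area are
#' used.
#'
#' @param a,b the earlier and later epoch.
#' @return data.frame `cls`, `d_area_km2`, `d_area_pct` (percentage points),
#'   ordered as [landCoverClasses()].
#' @export
#' @examples
#' a <- data.frame(cls = c("Farmland", "Settlement"), area_km2 = c(4.85, 0.06),
#'                 area_pct = c(84.98, 0.98))
#' b <- data.frame(cls = c("Farmland", "Settlement"), area_km2 = c(3.94, 0.43),
#'                 area_pct = c(69.03, 7.52))
#' changeTable(a, b)   # Farmland -0.91 km2, Settlement +0.37 km2
changeTable <- function(a, b) {
  ta <- classAreaSummary(a)
  tb <- classAreaSummary(b)
  if (!setequal(ta$cls, tb$cls))
    stop("class schemas differ between the two epochs")
  cls <- intersect(landCoverClasses(), ta$cls)
  ia <- match(cls, ta$cls); ib <- match(cls, tb$cls)
  data.frame(cls = cls,
             d_area_km2 = tb$area_km2[ib] - ta$area_km2[ia],
             d_area_pct = tb$area_pct[ib] - ta$area_pct[ia],
             stringsAsFactors = FALSE)
}

classAreaSummary <- function(x) {
  if (is(x, "LandCoverMap")) {
    a <- vapply(x@polygons, polygonArea, numeric(1))
    byClass <- tapply(a, x@cls, sum, default = 0)
    byClass <- byClass[!is.na(byClass) & byClass > 0]
    data.frame(cls = names(byClass),
               area_km2 = as.numeric(byClass) / 1e6,
               area_pct = as.numeric(byClass) / sum(a) * 100,
               stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(x), all(c("cls", "area_km2") %in% names(x)))
    x$area_pct <- x$area_pct %||% (x$area_km2 / sum(x$area_km2) * 100)
    x[, c("cls", "area_km2", "area_pct")]
  }
}
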