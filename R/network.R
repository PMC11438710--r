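# Network topology construction: endpoint snapping and node incidence.

#' Build a river network from attributed polyline segments
#'
#' Unifies segment endpoints into shared nodes: endpoints closer than
#' `snapTol` (transitively) are collapsed to one node, so segments digitized
#' with small gaps still connect. Geometry is never moved; nodes are abstract
#' endpoint clusters, which makes construction idempotent. Node construction
#' is order-independent (clusters are the connected components of the
#' within-tolerance endpoint graph, and nodes are sorted by coordinate).
#'
#' @param geometry list of polyline coordinate matrices (n x 2, planar
#'   meters), one per segment.
#' @param attributes data.frame with one row per segment. Recognized columns:
#'   `id` (unique; defaults to `"s1"..."sn"`), `state`, `barrier`, `ec`,
#'   `nps`, `hdas`, `restored`. Missing attribute columns default to
#'   `"unknown"` (and `restored` to `FALSE`).
#' @param snapTol endpoint snapping tolerance in meters (default 1).
#' @return a [RiverNetwork-class].
#' @export
#' @examples
#' g <- list(rbind(c(0, 0), c(100, 0)), rbind(c(100, 0), c(200, 0)))
#' net <- buildNetwork(g, data.frame(barrier = c("yes", "no")))
#' nSegments(net); totalLengthKm(net)
buildNetwork <- function(geometry, attributes = NULL, snapTol = 1) {
  if (!is.list(geometry) || length(geometry) == 0L)
    stop("geometry must be a non-empty list of coordinate matrices")
  if (snapTol < 0) stop("snapTol must be >= 0")
  geometry <- lapply(geometry, function(g) {
    g <- as.matrix(g)
    storage.mode(g) <- "double"
    g
  })
  n <- length(geometry)

  attributes <- attributes %||% data.frame(row.names = seq_len(n))
  if (nrow(attributes) != n)
    stop("attributes must have one row per segment")
  id <- as.character(attributes$id %||% paste0("s", seq_len(n)))
  if (anyDuplicated(id))
    stop("duplicate segment id: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))

  len <- vapply(geometry, polylineLength, numeric(1))
  if (any(len <= 0))
    stop("zero-length geometry for segment ",
         paste(id[len <= 0], collapse = ", "))

  norm <- function(x, levels, default = "unknown") {
    x <- tolower(trimws(as.character(x %||% rep(default, n))))
    x[is.na(x) | !(x %in% levels)] <- "unknown"
    x
  }
  seg <- data.frame(
    id = id,
    state = as.character(attributes$state %||% rep("unspecified", n)),
    barrier = norm(attributes$barrier, barrierLevels()),
    ec = norm(attributes$ec, ecLevels()),
    nps = norm(attributes$nps, flagLevels()),
    hdas = norm(attributes$hdas, flagLevels()),
    restored = as.logical(attributes$restored %||% rep(FALSE, n)),
    length_m = len,
    stringsAsFactors = FALSE
  )
  seg$restored[is.na(seg$restored)] <- FALSE

  ends <- do.call(rbind, lapply(geometry, function(g)
    rbind(g[1, ], g[nrow(g), ])))
  cl <- clusterPoints(ends, snapTol)
  # one representative coordinate per cluster, nodes ordered by coordinate
  reps <- do.call(rbind, lapply(split(seq_len(nrow(ends)), cl$member),
                                function(ix) colMeans(ends[ix, , drop = FALSE])))
  ord <- order(reps[, 1], reps[, 2])
  rank <- integer(nrow(reps)); rank[ord] <- seq_along(ord)
  nodes <- reps[ord, , drop = FALSE]
  dimnames(nodes) <- list(NULL, c("x", "y"))
  nodeOf <- rank[cl$member]
  seg$from <- nodeOf[seq(1L, 2L * n, by = 2L)]
  seg$to <- nodeOf[seq(2L, 2L * n, by = 2L)]

  new("RiverNetwork", segments = seg, geometry = geometry, nodes = nodes,
      snapTol = snapTol)
}

# cluster points whose transitive within-tol graph connects them; returns
# list(member = integer cluster id per point). Grid hashing keeps candidate
# generation near-linear; union-find merges candidates within tol.
clusterPoints <- function(pts, tol) {
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  if (tol <= 0) {
    key <- paste(pts[, 1], pts[, 2])
    first <- match(key, key)
    for (i in seq_len(n)) if (first[i] != i) unite(first[i], i)
  } else {
    cx <- floor(pts[, 1] / tol); cy <- floor(pts[, 2] / tol)
    key <- paste(cx, cy)
    buckets <- split(seq_len(n), key)
    bkey <- do.call(rbind, strsplit(names(buckets), " ", fixed = TRUE))
    bx <- as.numeric(bkey[, 1]); by <- as.numeric(bkey[, 2])
    lookup <- new.env(hash = TRUE, parent = emptyenv())
    for (b in seq_along(buckets)) assign(names(buckets)[b], b, envir = lookup)
    for (b in seq_along(buckets)) {
      here <- buckets[[b]]
      for (dx in -1:1) for (dy in -1:1) {
        nb <- paste(bx[b] + dx, by[b] + dy)
        ob <- mget(nb, envir = lookup, ifnotfound = list(NULL))[[1]]
        if (is.null(ob) || ob < b) next
        there <- buckets[[ob]]
        for (i in here) {
          d <- sqrt((pts[there, 1] - pts[i, 1])^2 +
                    (pts[there, 2] - pts[i, 2])^2)
          for (j in there[d <= tol]) if (j != i) unite(i, j)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  list(member = match(roots, sort(unique(roots))))
}

# igraph view of the node graph, segments as weighted edges; multi-edges and
# loops are legitimate (parallel channels, ring ditches)
networkGraph <- function(net) {
  seg <- net@segments
  igraph::graph_from_data_frame(
    data.frame(from = seg$from, to = seg$to, weight = seg$length_m,
               segment = seg$id),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(net@nodes))))
}
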