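#' @import methods
NULL

# canonical attribute vocabularies -------------------------------------------

#' Canonical attribute levels and category labels
#'
#' The scoring model uses a fixed vocabulary: `barrier` in yes/no/unknown,
#' ecomorphological condition `ec` in natural/semi_natural/artificial/unknown,
#' species flags `nps`/`hdas` in present/absent/unknown. `"unknown"` is an
#' explicit level, not a missing value: it propagates to the `unknown`
#' priority category. `priorityCategories()` returns the five priority
#' classes in increasing order of restoration need; `reportCategories()`
#' additionally includes `already_restored` and `unknown`, which are reported
#' as their own categories.
#'
#' @return character vectors of levels.
#' @export
barrierLevels <- function() c("yes", "no", "unknown")

#' @rdname barrierLevels
#' @export
ecLevels <- function() c("natural", "semi_natural", "artificial", "unknown")

#' @rdname barrierLevels
#' @export
flagLevels <- function() c("present", "absent", "unknown")

#' @rdname barrierLevels
#' @export
priorityCategories <- function()
  c("very_low", "low", "moderate", "high", "very_high")

#' @rdname barrierLevels
#' @export
reportCategories <- function()
  c(priorityCategories(), "unknown", "already_restored")

#' Land-cover class codes
#'
#' The five-class schema used for digitized land-cover mosaics: Ecological
#' Infrastructure (`EI`), `Farmland`, `Forest`, `Settlement` and Traffic
#' Infrastructure (`TI`).
#'
#' @return character vector of the five class codes.
#' @export
landCoverClasses <- function()
  c("EI", "Farmland", "Forest", "Settlement", "TI")

# RiverNetwork ---------------------------------------------------------------

#' RiverNetwork class
#'
#' An attributed river network in a planar metric CRS. Segments are the
#' atomic scoring units ("river sequences"): each carries a polyline
#' geometry, its four criterion attributes (`barrier`, `ec`, `nps`, `hdas`),
#' a `restored` flag and an administrative `state` label. Segment endpoints
#' are unified into shared nodes by [buildNetwork()], which enables
#' along-network (fish-migration) distance queries.
#'
#' @slot segments data.frame with columns `id`, `state`, `barrier`, `ec`,
#'   `nps`, `hdas`, `restored`, `length_m`, `from`, `to` (node indices).
#' @slot geometry list of n x 2 coordinate matrices, one polyline per segment.
#' @slot nodes numeric matrix (nNodes x 2) of node coordinates.
#' @slot snapTol numeric, the endpoint snapping tolerance in meters used to
#'   build the node set.
#'
#' @seealso [buildNetwork()], [scoreNetwork()], [totalLengthKm()]
#' @export
setClass("RiverNetwork",
  representation(segments = "data.frame", geometry = "list",
                 nodes = "matrix", snapTol = "numeric"))

setValidity("RiverNetwork", function(object) {
  seg <- object@segments
  msgs <- character(0)
  need <- c("id", "state", "barrier", "ec", "nps", "hdas", "restored",
            "length_m", "from", "to")
  if (!all(need %in% names(seg)))
    msgs <- c(msgs, paste("segments must have columns:",
                          paste(setdiff(need, names(seg)), collapse = ", ")))
  else {
    if (anyDuplicated(seg$id))
      msgs <- c(msgs, paste("duplicate segment id:",
                            paste(unique(seg$id[duplicated(seg$id)]), collapse = ", ")))
    if (any(seg$length_m <= 0))
      msgs <- c(msgs, paste("zero-length segment:",
                            paste(seg$id[seg$length_m <= 0], collapse = ", ")))
    if (nrow(seg) != length(object@geometry))
      msgs <- c(msgs, "one geometry per segment required")
    nn <- nrow(object@nodes)
    if (nrow(seg) && (any(seg$from < 1 | seg$from > nn) ||
                      any(seg$to < 1 | seg$to > nn)))
      msgs <- c(msgs, "segment endpoints must map to nodes")
    badB <- setdiff(unique(seg$barrier), barrierLevels())
    badE <- setdiff(unique(seg$ec), ecLevels())
    badF <- setdiff(unique(c(seg$nps, seg$hdas)), flagLevels())
    if (length(c(badB, badE, badF)))
      msgs <- c(msgs, paste("non-canonical attribute values:",
                            paste(c(badB, badE, badF), collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn RiverNetwork-class number of segments
#' @param x,object a `RiverNetwork`.
#' @export
nSegments <- function(x) nrow(x@segments)

#' Segment attribute table, geometry and nodes of a network
#'
#' Accessors for the `RiverNetwork` slots. `segmentTable()` returns the
#' per-segment attribute data.frame (one row per river sequence),
#' `segmentGeometry()` the list of polyline coordinate matrices, and
#' `nodeCoords()` the unified node coordinates.
#'
#' @param x a [RiverNetwork-class].
#' @return data.frame, list of matrices, or matrix respectively.
#' @export
segmentTable <- function(x) x@segments

#' @rdname segmentTable
#' @export
segmentGeometry <- function(x) x@geometry

#' @rdname segmentTable
#' @export
nodeCoords <- function(x) x@nodes

#' Total network length in kilometers
#'
#' @param x a [RiverNetwork-class].
#' @return numeric, the sum of planar segment lengths in km.
#' @export
totalLengthKm <- function(x) sum(x@segments$length_m) / 1000

setMethod("show", "RiverNetwork", function(object) {
  seg <- object@segments
  cat("RiverNetwork:", nrow(seg), "segments,", nrow(object@nodes), "nodes,",
      sprintf("%.2f km", totalLengthKm(object)), "\n")
  cat("  states:", paste(sort(unique(seg$state)), collapse = ", "), "\n")
  cat("  restored:", sum(seg$restored),
      " | attribute unknowns (barrier/ec/nps/hdas):",
      paste(c(sum(seg$barrier == "unknown"), sum(seg$ec == "unknown"),
              sum(seg$nps == "unknown"), sum(seg$hdas == "unknown")),
            collapse = "/"), "\n")
  invisible(object)
})

# LandCoverMap ---------------------------------------------------------------

#' LandCoverMap class
#'
#' A polygonal land-cover mosaic for one epoch (e.g. one digitized aerial
#' survey year). Polygons are pairwise interior-disjoint and each carries one
#' of the five classes of [landCoverClasses()]. Coordinates are planar
#' meters; polygons may contain holes (first ring shell, following rings
#' holes).
#'
#' @slot polygons list; each element is a polygon, i.e. a list of rings
#'   (n x 2 coordinate matrices).
#' @slot cls factor of polygon classes with levels [landCoverClasses()].
#' @slot epoch character label (typically the survey year).
#'
#' @seealso [landCoverMap()], [validateLandCover()], [classMetrics()]
#' @export
setClass("LandCoverMap",
  representation(polygons = "list", cls = "factor", epoch = "character"))

setValidity("LandCoverMap", function(object) {
  msgs <- character(0)
  if (length(object@polygons) != length(object@cls))
    msgs <- c(msgs, "one class per polygon required")
  if (!identical(levels(object@cls), landCoverClasses()))
    msgs <- c(msgs, "cls levels must be the five land-cover classes")
  if (anyNA(object@cls))
    msgs <- c(msgs, "every polygon needs a class")
  if (length(msgs)) msgs else TRUE
})

#' Construct a LandCoverMap
#'
#' @param polygons list of polygons; each polygon is a list of rings (n x 2
#'   matrices, shell first) or a single matrix (shell only).
#' @param cls character or factor of classes, one of [landCoverClasses()].
#' @param epoch label for the map epoch, e.g. `"2019"`.
#' @return a [LandCoverMap-class].
#' @export
#' @examples
#' sq <- function(x0, y0, s) cbind(c(x0, x0 + s, x0 + s, x0),
#'                                 c(y0, y0, y0 + s, y0 + s))
#' m <- landCoverMap(list(sq(0, 0, 10), sq(10, 0, 10)),
#'                   c("Farmland", "Forest"), epoch = "2019")
#' landscapeAreaM2(m)
landCoverMap <- function(polygons, cls, epoch = "unknown") {
  polygons <- lapply(polygons, function(p) if (is.matrix(p)) list(p) else p)
  cls <- factor(as.character(cls), levels = landCoverClasses())
  if (anyNA(cls))
    stop("land-cover class must be one of: ",
         paste(landCoverClasses(), collapse = ", "))
  new("LandCoverMap", polygons = polygons, cls = cls,
      epoch = as.character(epoch))
}

#' @describeIn LandCoverMap-class number of polygons
#' @param x,object a `LandCoverMap`.
#' @export
nPolygons <- function(x) length(x@polygons)

#' @rdname landCoverMap
#' @param x a [LandCoverMap-class].
#' @export
mapPolygons <- function(x) x@polygons

#' @rdname landCoverMap
#' @export
mapClasses <- function(x) x@cls

#' @rdname landCoverMap
#' @export
mapEpoch <- function(x) x@epoch

#' Total landscape area of a mosaic in square meters
#'
#' The polygons of a valid mosaic are interior-disjoint, so the landscape
#' area is the sum of polygon areas (holes subtracted).
#'
#' @param x a [LandCoverMap-class].
#' @return numeric, area in m^2.
#' @export
landscapeAreaM2 <- function(x)
  sum(vapply(x@polygons, polygonArea, numeric(1)))

setMethod("show", "LandCoverMap", function(object) {
  a <- vapply(object@polygons, polygonArea, numeric(1))
  cat("LandCoverMap (epoch ", object@epoch, "): ", length(a),
      " polygons, ", sprintf("%.3f km2", sum(a) / 1e6), "\n", sep = "")
  tab <- tapply(a, object@cls, sum, default = 0) / sum(a) * 100
  cat("  ", paste(sprintf("%s %.1f%%", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  invisible(object)
})

# PriorityWeights ------------------------------------------------------------

#' PriorityWeights class
#'
#' Nonnegative weights for the four scoring criteria. The default is equal
#' weighting (0.25 each), under which the weighted 0-8 score equals the raw
#' sum of the four 0-2 criterion points. Weights need not sum to one; the
#' score is normalized by their sum.
#'
#' @slot w named numeric of length 4 (`barrier`, `ec`, `nps`, `hdas`).
#' @seealso [priorityWeights()], [totalScore()]
#' @export
setClass("PriorityWeights", representation(w = "numeric"))

setValidity("PriorityWeights", function(object) {
  w <- object@w
  if (!identical(names(w), c("barrier", "ec", "nps", "hdas")))
    return("weights must be named barrier, ec, nps, hdas")
  if (any(!is.finite(w)) || any(w < 0)) return("weights must be finite and >= 0")
  if (sum(w) <= 0) return("at least one weight must be positive")
  TRUE
})

#' Construct criterion weights
#'
#' @param barrier,ec,nps,hdas nonnegative criterion weights; default equal
#'   (0.25 each).
#' @return a [PriorityWeights-class].
#' @export
#' @examples
#' priorityWeights()                       # the equal-weight base model
#' priorityWeights(barrier = 0.4, ec = 0.3, nps = 0.2, hdas = 0.1)
priorityWeights <- function(barrier = 0.25, ec = 0.25, nps = 0.25,
                            hdas = 0.25) {
  new("PriorityWeights",
      w = c(barrier = barrier, ec = ec, nps = nps, hdas = hdas))
}

#' @rdname priorityWeights
#' @param x a `PriorityWeights`.
#' @export
weightValues <- function(x) x@w

setMethod("show", "PriorityWeights", function(object) {
  cat("PriorityWeights:",
      paste(sprintf("%s=%.3g", names(object@w), object@w), collapse = ", "),
      "\n")
  invisible(object)
})

# PriorityBins ---------------------------------------------------------------

#' PriorityBins class
#'
#' An ordered partition of the score range \[0, 8\] into priority categories.
#' Intervals are right-closed, `(b[i], b[i+1]]`, with the lowest interval
#' also closed at 0, so every score in \[0, 8\] falls in exactly one bin.
#' The default anchors the two extremes as published (8 points is very high,
#' 0-1 points very low) and splits the unspecified middle evenly:
#' very_low \[0,1\], low (1,3\], moderate (3,5\], high (5,7\],
#' very_high (7,8\].
#'
#' @slot breaks strictly increasing numeric from 0 to 8.
#' @slot labels category label per interval.
#' @seealso [priorityBins()], [classifyScore()]
#' @export
setClass("PriorityBins",
  representation(breaks = "numeric", labels = "character"))

setValidity("PriorityBins", function(object) {
  b <- object@breaks
  if (length(b) < 2L || is.unsorted(b, strictly = TRUE))
    return("breaks must be strictly increasing")
  if (b[1] != 0 || b[length(b)] != 8)
    return("breaks must partition [0, 8] exactly (start 0, end 8)")
  if (length(object@labels) != length(b) - 1L)
    return("one label per interval required")
  if (anyDuplicated(object@labels)) return("labels must be unique")
  TRUE
})

#' Construct a score-to-category bin map
#'
#' @param breaks strictly increasing numeric partition of \[0, 8\].
#' @param labels category label per interval.
#' @return a [PriorityBins-class].
#' @export
#' @examples
#' priorityBins()  # the default five-class partition
priorityBins <- function(breaks = c(0, 1, 3, 5, 7, 8),
                         labels = priorityCategories()) {
  new("PriorityBins", breaks = breaks, labels = labels)
}

#' @rdname priorityBins
#' @param x a `PriorityBins`.
#' @export
binBreaks <- function(x) x@breaks

#' @rdname priorityBins
#' @export
binLabels <- function(x) x@labels

setMethod("show", "PriorityBins", function(object) {
  b <- object@breaks
  iv <- paste0(ifelse(seq_along(object@labels) == 1L, "[", "("),
               b[-length(b)], ", ", b[-1], "]")
  cat("PriorityBins:", paste(paste(iv, object@labels), collapse = "; "), "\n")
  invisible(object)
})
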