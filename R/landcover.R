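# Land-cover mosaic validation.

#' Validate a land-cover mosaic
#'
#' Checks the structural rules a digitized mosaic must satisfy before metrics
#' are computed: every polygon at least as large as the minimum mapping unit
#' (50 m^2 by default), no self-intersecting or degenerate rings, and no pair
#' of polygons sharing interior area (boundary contact between neighbors is
#' allowed). The validator reports findings instead of stopping, so a map can
#' be triaged in one pass.
#'
#' @param map a [LandCoverMap-class].
#' @param mmuM2 minimum mapping unit in m^2 (default 50).
#' @return data.frame with columns `type` (`"below_mmu"`,
#'   `"invalid_geometry"`, `"overlap"`), `index` and `other` (polygon
#'   indices; `other` is `NA` except for overlaps) and `detail`. Zero rows
#'   iff the map conforms.
#' @export
#' @examples
#' sq <- function(x0, y0, s) cbind(c(x0, x0 + s, x0 + s, x0),
#'                                 c(y0, y0, y0 + s, y0 + s))
#' m <- landCoverMap(list(sq(0, 0, 10), sq(20, 0, 6)),
#'                   c("Farmland", "EI"), "2019")
#' validateLandCover(m)            # 6 m square is below the 50 m^2 MMU
validateLandCover <- function(map, mmuM2 = 50) {
  stopifnot(is(map, "LandCoverMap"))
  if (mmuM2 <= 0) stop("mmuM2 must be > 0")
  polys <- map@polygons
  n <- length(polys)
  out <- list()
  add <- function(type, index, other, detail)
    out[[length(out) + 1L]] <<- data.frame(type = type, index = index,
                                           other = other, detail = detail)

  areas <- vapply(polys, polygonArea, numeric(1))
  valid <- rep(TRUE, n)
  for (i in seq_len(n)) {
    bad <- vapply(polys[[i]], function(r)
      nrow(unique(closeRing(r))) < 3L || ringSelfIntersects(r), logical(1))
    if (any(bad) || areas[i] <= 0) {
      valid[i] <- FALSE
      add("invalid_geometry", i, NA_integer_,
          if (areas[i] <= 0) "non-positive area" else "self-intersecting ring")
    }
  }
  for (i in which(valid & areas < mmuM2))
    add("below_mmu", i, NA_integer_,
        sprintf("area %.1f m2 < MMU %.1f m2", areas[i], mmuM2))

  idx <- which(valid)
  if (length(idx) > 1L) {
    boxes <- lapply(polys, polygonBBox)
    for (a in seq_along(idx)[-length(idx)]) {
      i <- idx[a]
      for (j in idx[(a + 1L):length(idx)]) {
        if (!bboxesIntersect(boxes[[i]], boxes[[j]])) next
        if (polygonsOverlap(polys[[i]], polys[[j]]))
          add("overlap", i, j, "polygons share interior area")
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(type = character(0), index = integer(0),
                  other = integer(0), detail = character(0))
}
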