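# Seeded synthetic generators: river networks with attribute marginals and
# land-cover mosaics, so every module is testable without external data.

#' Specification for a synthetic river network
#'
#' Defaults emulate the structure the model was designed for: a drained-plain
#' side-river network of a few hundred pre-segmented sequences totalling
#' roughly 85 km, administered by three states, with roughly half the
#' sequences in unnatural ecomorphological condition, modest priority-species
#' and hotspot coverage, about a tenth already restored and about an eighth
#' lacking secondary data.
#'
#' @param nSegments number of segments (> 0).
#' @param lengthRangeM min/max segment length in meters.
#' @param pBranch probability a new segment starts a branch at a random
#'   existing node rather than extending a tip (tree mode).
#' @param pBarrier probability a segment contains a barrier.
#' @param pEc probabilities of (natural, semi_natural, artificial); must sum
#'   to 1.
#' @param pNps,pHdas probability the species flag is present.
#' @param pRestored probability a segment is already restored.
#' @param pUnknown probability a segment lacks secondary data: for such a
#'   segment one randomly chosen criterion attribute is set to `unknown`,
#'   which routes the segment to the `unknown` priority category. Data
#'   availability is a per-segment property (a sequence either was or was
#'   not covered by the secondary datasets), so the share of
#'   category-`unknown` sequences tracks `pUnknown`.
#' @param nStates number of administrative units (assigned as contiguous
#'   west-to-east blocks).
#' @param mode `"tree"` (default, random dendritic growth) or `"grid"`
#'   (rectangular ditch lattice).
#' @param origin coordinate offset of the network, planar meters.
#' @param seed integer seed; identical seeds give identical networks.
#' @return a `networkSpec` list.
#' @export
networkSpec <- function(nSegments = 400, lengthRangeM = c(80, 340),
                        pBranch = 0.25, pBarrier = 0.4,
                        pEc = c(natural = 0.2, semi_natural = 0.3,
                                artificial = 0.5),
                        pNps = 0.15, pHdas = 0.10, pRestored = 0.10,
                        pUnknown = 0.13, nStates = 3,
                        mode = c("tree", "grid"),
                        origin = c(2710000, 1220000), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(nSegments > 0, length(lengthRangeM) == 2L,
            lengthRangeM[1] > 0, diff(lengthRangeM) >= 0,
            length(pEc) == 3L, abs(sum(pEc) - 1) < 1e-9)
  probs <- c(pBranch, pBarrier, pEc, pNps, pHdas, pRestored, pUnknown)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(nSegments = as.integer(nSegments),
                 lengthRangeM = lengthRangeM, pBranch = pBranch,
                 pBarrier = pBarrier, pEc = pEc, pNps = pNps, pHdas = pHdas,
                 pRestored = pRestored, pUnknown = pUnknown,
                 nStates = as.integer(nStates), mode = mode, origin = origin,
                 seed = seed),
            class = "networkSpec")
}

#' Generate a synthetic river network
#'
#' Tree mode grows a connected dendritic network: each new segment extends
#' the current tip with a small random heading change, or (with probability
#' `pBranch`) starts a branch at a random existing node. Grid mode lays out
#' a rectangular ditch lattice, the geometry typical of drained plains.
#' Criterion attributes are drawn independently per segment from the spec
#' marginals; a `pUnknown` share of segments is then marked data-deficient
#' (one criterion set to `unknown`). States are contiguous west-to-east blocks of
#' roughly equal segment count. All randomness flows from the single spec
#' seed.
#'
#' @param spec a [networkSpec()].
#' @param snapTol endpoint snapping tolerance passed to [buildNetwork()].
#' @return a [RiverNetwork-class].
#' @export
#' @examples
#' net <- makeNetwork(networkSpec(nSegments = 50, seed = 7))
#' net
makeNetwork <- function(spec = networkSpec(), snapTol = 0.5) {
  stopifnot(inherits(spec, "networkSpec"))
  withSeed(spec$seed, {
    n <- spec$nSegments
    geom <- vector("list", n)
    if (spec$mode == "tree") {
      nodes <- matrix(spec$origin, ncol = 2)
      heading <- stats::runif(1, 0, 2 * pi)
      nodeHeading <- heading
      tip <- 1L
      for (i in seq_len(n)) {
        branch <- i > 1L && stats::runif(1) < spec$pBranch
        at <- if (branch) sample.int(nrow(nodes), 1L) else tip
        h <- if (branch) stats::runif(1, 0, 2 * pi)
             else nodeHeading[at] + stats::rnorm(1, 0, pi / 7)
        len <- stats::runif(1, spec$lengthRangeM[1], spec$lengthRangeM[2])
        to <- nodes[at, ] + len * c(cos(h), sin(h))
        geom[[i]] <- rbind(nodes[at, ], to)
        nodes <- rbind(nodes, to)
        nodeHeading <- c(nodeHeading, h)
        tip <- nrow(nodes)
      }
    } else {
      # ditch lattice: alternate horizontal/vertical edges of a nx x ny grid
      sp <- mean(spec$lengthRangeM)
      nx <- max(2L, ceiling(sqrt(n / 2) * 1.2))
      hEdges <- expand.grid(i = seq_len(nx - 1L), j = seq_len(nx))
      vEdges <- expand.grid(i = seq_len(nx), j = seq_len(nx - 1L))
      mk <- rbind(
        cbind(hEdges$i, hEdges$j, hEdges$i + 1L, hEdges$j),
        cbind(vEdges$i, vEdges$j, vEdges$i, vEdges$j + 1L))
      mk <- mk[seq_len(min(n, nrow(mk))), , drop = FALSE]
      if (nrow(mk) < n)
        stop("grid mode cannot produce ", n, " segments at this lattice size")
      geom <- lapply(seq_len(n), function(k)
        rbind(spec$origin + sp * c(mk[k, 1] - 1L, mk[k, 2] - 1L),
              spec$origin + sp * c(mk[k, 3] - 1L, mk[k, 4] - 1L)))
    }

    draw <- function(levels, p) levels[1L + (stats::runif(n) >= p)]
    barrier <- draw(c("yes", "no"), spec$pBarrier)
    ec <- sample(c("natural", "semi_natural", "artificial"), n, replace = TRUE,
                 prob = spec$pEc)
    nps <- draw(c("present", "absent"), spec$pNps)
    hdas <- draw(c("present", "absent"), spec$pHdas)
    restored <- stats::runif(n) < spec$pRestored
    # data-deficient segments: one randomly chosen criterion unknown
    deficient <- which(stats::runif(n) < spec$pUnknown)
    whichAttr <- sample(c("barrier", "ec", "nps", "hdas"),
                        length(deficient), replace = TRUE)
    for (a in c("barrier", "ec", "nps", "hdas")) {
      v <- get(a); v[deficient[whichAttr == a]] <- "unknown"; assign(a, v)
    }

    midx <- vapply(geom, function(g) mean(g[, 1]), numeric(1))
    stateIdx <- cut(rank(midx, ties.method = "first"),
                    breaks = spec$nStates, labels = FALSE)
    attributes <- data.frame(
      id = sprintf("seg_%04d", seq_len(n)),
      state = paste0("state_", stateIdx),
      barrier = barrier, ec = ec, nps = nps, hdas = hdas,
      restored = restored, stringsAsFactors = FALSE)
    buildNetwork(geom, attributes, snapTol = snapTol)
  })
}

#' Specification for a synthetic land-cover mosaic
#'
#' A grid mosaic of square cells with a class mixture over the five
#' land-cover classes and a spatial clustering parameter. Defaults emulate a
#' farmland-dominated riparian plain: the published 2019 composition
#' (Farmland ~69%, EI ~12%, TI ~9%, Settlement ~7.5%, Forest ~3%) with
#' moderate spatial clumping. The default 25 m cell (625 m^2) is comfortably
#' above the 50 m^2 minimum mapping unit.
#'
#' @param nx,ny grid dimensions in cells.
#' @param cellM cell side length in meters.
#' @param mixture named class probabilities summing to 1 (names from
#'   [landCoverClasses()]).
#' @param clustering in \[0, 1\): probability a cell copies the class of an
#'   already-assigned neighbor instead of drawing from the mixture. Copying
#'   preserves the marginal mixture while clumping same-class cells.
#' @param origin coordinate offset, planar meters.
#' @param epoch epoch label.
#' @param seed integer seed.
#' @return a `mosaicSpec` list.
#' @export
mosaicSpec <- function(nx = 40, ny = 40, cellM = 25,
                       mixture = c(EI = 0.12, Farmland = 0.69, Forest = 0.03,
                                   Settlement = 0.07, TI = 0.09),
                       clustering = 0.4, origin = c(2710000, 1220000),
                       epoch = "2019", seed = 1L) {
  stopifnot(nx > 0, ny > 0, cellM > 0,
            setequal(names(mixture), landCoverClasses()),
            abs(sum(mixture) - 1) < 1e-9,
            clustering >= 0, clustering < 1)
  structure(list(nx = as.integer(nx), ny = as.integer(ny), cellM = cellM,
                 mixture = mixture[landCoverClasses()],
                 clustering = clustering, origin = origin,
                 epoch = as.character(epoch), seed = seed),
            class = "mosaicSpec")
}

#' Generate a synthetic land-cover mosaic
#'
#' Produces an exhaustive, interior-disjoint grid of square class-labelled
#' cells. Cells are assigned in raster order: with probability `clustering`
#' a cell copies the class of a random already-assigned neighbor (west or
#' south), otherwise it draws from the mixture — so class marginals follow
#' the mixture while same-class cells clump into multi-cell patches. The
#' output always passes [validateLandCover()] at the default MMU.
#'
#' @param spec a [mosaicSpec()].
#' @return a [LandCoverMap-class].
#' @export
#' @examples
#' m <- makeMosaic(mosaicSpec(nx = 12, ny = 12, seed = 3))
#' nrow(validateLandCover(m))   # 0
makeMosaic <- function(spec = mosaicSpec()) {
  stopifnot(inherits(spec, "mosaicSpec"))
  withSeed(spec$seed, {
    nx <- spec$nx; ny <- spec$ny
    cls <- matrix(NA_character_, nx, ny)
    classes <- landCoverClasses()
    for (j in seq_len(ny)) {
      for (i in seq_len(nx)) {
        nb <- c(if (i > 1L) cls[i - 1L, j], if (j > 1L) cls[i, j - 1L])
        if (length(nb) && stats::runif(1) < spec$clustering)
          cls[i, j] <- nb[sample.int(length(nb), 1L)]
        else
          cls[i, j] <- sample(classes, 1L, prob = spec$mixture)
      }
    }
    s <- spec$cellM
    polys <- vector("list", nx * ny)
    k <- 0L
    for (j in seq_len(ny)) for (i in seq_len(nx)) {
      k <- k + 1L
      x0 <- spec$origin[1] + (i - 1L) * s
      y0 <- spec$origin[2] + (j - 1L) * s
      polys[[k]] <- cbind(c(x0, x0 + s, x0 + s, x0), c(y0, y0, y0 + s, y0 + s))
    }
    landCoverMap(polys, as.vector(cls), epoch = spec$epoch)
  })
}

#' Hand-built worked scoring fixture
#'
#' A six-segment network exercising every branch of the priority model, with
#' hand-computed expected points, scores and categories frozen alongside it:
#'
#' * `wf1`: barrier, artificial bed, both species flags absent but bordering
#'   the flagged segment — points (2,2,2,2), score 8, `very_high`.
#' * `wf2`: all-favorable (no barrier, natural bed, both flags present) —
#'   points (0,0,0,0), score 0, `very_low`.
#' * `wf3`: semi-natural, absent flags at 300 m network distance from the
#'   flagged segment (within 500 m) — points (0,1,2,2), score 5, `moderate`.
#' * `wf4`: barrier, artificial, absent flags at 900 m (beyond 500 m) —
#'   points (2,2,1,1), score 6, `high`.
#' * `wf5`: restored — `already_restored` regardless of attributes.
#' * `wf6`: unknown ecomorphology — `unknown`.
#'
#' @return list with `network` (a [RiverNetwork-class]) and `expected`
#'   (data.frame of the hand-computed score table).
#' @export
#' @examples
#' fx <- makeWorkedFixture()
#' all.equal(scoreNetwork(fx$network)$score, fx$expected$score)
makeWorkedFixture <- function() {
  o <- c(2710000, 1220000)
  p <- function(x, y) o + c(x, y)
  geom <- list(
    wf1 = rbind(p(0, 0), p(300, 0)),      # n1 (0,0) - n2 (300,0)
    wf2 = rbind(p(-200, 0), p(0, 0)),     # flagged; shares n1 with wf1
    wf3 = rbind(p(300, 0), p(900, 0)),    # n2 - n3, 600 m
    wf4 = rbind(p(900, 0), p(1100, 0)),   # n3 - n4, 200 m
    wf5 = rbind(p(1100, 0), p(1250, 0)),  # n4 -, restored
    wf6 = rbind(p(1100, 0), p(1100, 250)) # n4 -, ec unknown
  )
  attributes <- data.frame(
    id = names(geom),
    state = c("state_1", "state_1", "state_2", "state_2", "state_3", "state_3"),
    barrier = c("yes", "no", "no", "yes", "no", "yes"),
    ec = c("artificial", "natural", "semi_natural", "artificial",
           "natural", "unknown"),
    nps = c("absent", "present", "absent", "absent", "absent", "absent"),
    hdas = c("absent", "present", "absent", "absent", "absent", "absent"),
    restored = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  expected <- data.frame(
    segment_id = names(geom),
    p_barrier = c(2, 0, 0, 2, NA, 2),
    p_ec = c(2, 0, 1, 2, NA, NA),
    p_nps = c(2, 0, 2, 1, NA, 1),
    p_hdas = c(2, 0, 2, 1, NA, 1),
    score = c(8, 0, 5, 6, NA, NA),
    category = c("very_high", "very_low", "moderate", "high",
                 "already_restored", "unknown"),
    stringsAsFactors = FALSE)
  list(network = buildNetwork(geom, attributes, snapTol = 0),
       expected = expected)
}
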