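# The restoration-priority model: per-criterion points, 500 m along-network
# adjacency, weighted aggregation to a 0-8 score, category assignment.

#' Criterion points for migration barriers and ecomorphological condition
#'
#' Barrier: a sequence containing a barrier has a high need for restoration
#' (2 points), one without none (0 points); the barrier criterion has no
#' intermediate 1-point level. Ecomorphological condition: natural 0,
#' semi-natural 1, artificial 2. `"unknown"` propagates as `NA` points and
#' ultimately yields the `unknown` category.
#'
#' @param barrier character vector in [barrierLevels()].
#' @param ec character vector in [ecLevels()].
#' @return numeric points in \{0, 1, 2\} or `NA` for unknown.
#' @export
#' @examples
#' scoreBarrier(c("yes", "no", "unknown"))   # 2 0 NA
#' scoreEc(c("natural", "semi_natural", "artificial"))  # 0 1 2
scoreBarrier <- function(barrier) {
  stopifnot(all(barrier %in% barrierLevels()))
  unname(c(yes = 2, no = 0, unknown = NA_real_)[barrier])
}

#' @rdname scoreBarrier
#' @export
scoreEc <- function(ec) {
  stopifnot(all(ec %in% ecLevels()))
  unname(c(natural = 0, semi_natural = 1, artificial = 2,
           unknown = NA_real_)[ec])
}

#' Along-network adjacency to flagged sequences
#'
#' A segment is adjacent to a priority-species (`nps`) or diversity-hotspot
#' (`hdas`) sequence when the along-network distance from its nearest point
#' to the nearest point of some flagged segment is at most `maxDist`
#' (default 500 m, a minimum migration distance). Because distance is
#' measured along the channel network (the rationale is fish migration), a
#' segment sharing a node with a flagged segment is adjacent at any
#' `maxDist >= 0`. Two alternative rules are available for sensitivity
#' analysis: `"euclidean"` (straight-line distance between geometries) and
#' `"node"` (only immediately node-adjacent segments count).
#'
#' @param net a [RiverNetwork-class].
#' @param flag `"nps"` or `"hdas"`.
#' @param maxDist adjacency distance in meters (default 500).
#' @param mode `"network"` (default), `"euclidean"` or `"node"`.
#' @param segId optional segment id(s); default all segments.
#' @return named logical vector (by segment id): adjacent to a flagged
#'   segment? Flagged segments themselves are trivially adjacent (distance
#'   0); [scorePresence()] lets presence dominate adjacency.
#' @export
adjacentToFlagged <- function(net, flag = c("nps", "hdas"), maxDist = 500,
                              mode = c("network", "euclidean", "node"),
                              segId = NULL) {
  flag <- match.arg(flag)
  mode <- match.arg(mode)
  if (maxDist < 0) stop("maxDist must be >= 0")
  seg <- net@segments
  if (is.null(segId)) segId <- seg$id
  missing <- setdiff(segId, seg$id)
  if (length(missing))
    stop("segment not in network: ", paste(missing, collapse = ", "))

  flagged <- seg[[flag]] == "present"
  adj <- stats::setNames(rep(FALSE, nrow(seg)), seg$id)
  if (any(flagged)) {
    if (mode == "network") {
      d <- nodeDistToFlagged(net, flagged)
      adj[] <- pmin(d[seg$from], d[seg$to]) <= maxDist
    } else if (mode == "euclidean") {
      fedges <- do.call(rbind, lapply(net@geometry[flagged], polylineEdges))
      for (i in seq_len(nrow(seg))) {
        g <- net@geometry[[i]]
        dmin <- min(vapply(seq_len(nrow(g)), function(k)
          min(distOnePointToEdges(g[k, 1], g[k, 2], fedges)), numeric(1)))
        if (dmin > 0) {
          e <- polylineEdges(g)
          dmin <- min(dmin, edgeSetDistance(e, fedges))
        }
        adj[i] <- dmin <= maxDist
      }
    } else { # node: immediate neighbors (and flagged segments themselves)
      fn <- unique(c(seg$from[flagged], seg$to[flagged]))
      adj[] <- flagged | seg$from %in% fn | seg$to %in% fn
    }
  }
  adj[segId]
}

# shortest along-network distance from every node to the nearest node of a
# flagged segment: single-source Dijkstra from a zero-weight virtual source
nodeDistToFlagged <- function(net, flagged) {
  seg <- net@segments
  nn <- nrow(net@nodes)
  fn <- unique(c(seg$from[flagged], seg$to[flagged]))
  edges <- data.frame(from = c(seg$from, rep(nn + 1L, length(fn))),
                      to = c(seg$to, fn),
                      weight = c(seg$length_m, rep(0, length(fn))))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE, vertices = data.frame(name = seq_len(nn + 1L)))
  d <- igraph::distances(g, v = as.character(nn + 1L), weights = igraph::E(g)$weight)
  d[1, as.character(seq_len(nn))]
}

#' Criterion points for species presence (NPS / HDAS)
#'
#' A sequence where the species flag is present scores 0 (its existing
#' quality argues against intervention); an absent sequence scores 2 when it
#' is adjacent to a flagged sequence (restoring it extends habitat and
#' spawning grounds next to existing populations) and 1 otherwise. Presence
#' dominates adjacency: a flagged segment scores 0 even when it also borders
#' another flagged segment. `"unknown"` gives `NA`.
#'
#' @inheritParams adjacentToFlagged
#' @return named numeric vector of points per segment.
#' @export
scorePresence <- function(net, flag = c("nps", "hdas"), maxDist = 500,
                          mode = c("network", "euclidean", "node")) {
  flag <- match.arg(flag)
  mode <- match.arg(mode)
  seg <- net@segments
  value <- seg[[flag]]
  adj <- adjacentToFlagged(net, flag, maxDist, mode)
  p <- ifelse(value == "present", 0,
              ifelse(value == "absent", ifelse(adj, 2, 1), NA_real_))
  stats::setNames(p, seg$id)
}

#' Weighted total restoration-priority score
#'
#' Aggregates the four criterion points with weights `w` as
#' `score = 4 * sum(w_i * p_i) / sum(w_i)`, which maps onto the published
#' 0-8 point scale: under equal weights the score equals the raw sum of the
#' four 0-2 point criteria. `NA` in any criterion gives `NA` (the segment is
#' categorized `unknown`).
#'
#' @param pBarrier,pEc,pNps,pHdas numeric criterion points (0-2 or `NA`).
#' @param weights a [PriorityWeights-class] (default equal).
#' @return numeric scores in \[0, 8\] (or `NA`).
#' @export
#' @examples
#' totalScore(2, 2, 2, 2)              # 8: very high priority
#' totalScore(2, 1, 1, 0)              # 4
totalScore <- function(pBarrier, pEc, pNps, pHdas,
                       weights = priorityWeights()) {
  stopifnot(is(weights, "PriorityWeights"))
  validObject(weights)
  w <- weights@w
  unname(4 * (w[["barrier"]] * pBarrier + w[["ec"]] * pEc +
                w[["nps"]] * pNps + w[["hdas"]] * pHdas) / sum(w))
}

#' Assign the priority category
#'
#' Categorization precedence: a restored segment is `already_restored`
#' whatever its attributes; a segment with any unknown criterion (`NA`
#' score) is `unknown`; otherwise the bin of [priorityBins()] containing the
#' score. Non-integer weighted scores are classified by the real-valued bin
#' map without rounding.
#'
#' @param score numeric in \[0, 8\] or `NA`.
#' @param restored logical (recycled).
#' @param bins a [PriorityBins-class].
#' @return character vector of categories (see [reportCategories()]).
#' @export
#' @examples
#' classifyScore(c(8, 0, 4.5))           # very_high, very_low, moderate
#' classifyScore(8, restored = TRUE)     # already_restored
classifyScore <- function(score, restored = FALSE, bins = priorityBins()) {
  stopifnot(is(bins, "PriorityBins"))
  validObject(bins)
  n <- max(length(score), length(restored))
  score <- rep_len(score, n)
  restored <- rep_len(restored, n)
  if (any(!is.na(score) & (score < 0 | score > 8)))
    stop("score outside [0, 8]")
  ix <- findInterval(score, bins@breaks, rightmost.closed = TRUE,
                     left.open = TRUE)
  ix[!is.na(score) & score == 0] <- 1L
  cat <- bins@labels[ix]
  cat[is.na(score)] <- "unknown"
  cat[restored] <- "already_restored"
  cat
}

#' Score and categorize every segment of a network
#'
#' Runs the full priority model: the four criterion point rules, the
#' along-network adjacency rule for the two species criteria, weighted
#' aggregation and category assignment. Restored segments are excluded from
#' scoring (their points and score are `NA`) and reported as
#' `already_restored`.
#'
#' @param net a [RiverNetwork-class].
#' @param weights a [PriorityWeights-class].
#' @param bins a [PriorityBins-class].
#' @param maxDist adjacency distance in meters (default 500).
#' @param mode adjacency rule, see [adjacentToFlagged()].
#' @return data.frame with one row per segment: `segment_id`, `state`,
#'   `length_m`, points `p_barrier`, `p_ec`, `p_nps`, `p_hdas`, `score`,
#'   `category` (factor over [reportCategories()]).
#' @export
#' @examples
#' fx <- makeWorkedFixture()
#' scoreNetwork(fx$network)
scoreNetwork <- function(net, weights = priorityWeights(),
                         bins = priorityBins(), maxDist = 500,
                         mode = c("network", "euclidean", "node")) {
  stopifnot(is(net, "RiverNetwork"))
  validObject(net)
  mode <- match.arg(mode)
  seg <- net@segments
  p <- data.frame(
    p_barrier = scoreBarrier(seg$barrier),
    p_ec = scoreEc(seg$ec),
    p_nps = unname(scorePresence(net, "nps", maxDist, mode)),
    p_hdas = unname(scorePresence(net, "hdas", maxDist, mode))
  )
  score <- totalScore(p$p_barrier, p$p_ec, p$p_nps, p$p_hdas, weights)
  category <- classifyScore(score, seg$restored, bins)
  p[seg$restored, ] <- NA_real_
  score[seg$restored] <- NA_real_
  data.frame(segment_id = seg$id, state = seg$state, length_m = seg$length_m,
             p, score = score,
             category = factor(category, levels = reportCategories()),
             stringsAsFactors = FALSE)
}
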