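# GeoJSON and table I/O plus attribute normalization.
#
# GeoJSON is the supported geometry exchange format (features with
# LineString/MultiLineString for networks, Polygon/MultiPolygon for land
# cover). Coordinates must be planar meters; files declaring a geographic
# CRS are rejected rather than silently reprojected.

#' Default configuration
#'
#' All tunable model, geometry and I/O settings with their defaults:
#' attribute-name mapping for readers; criterion weights; score bins;
#' adjacency rule (`mode`, `max_dist_m`); buffer widths and cap style;
#' endpoint snapping tolerance; minimum mapping unit; dissolution
#' contiguity; ED boundary handling; rounding precision; whether the
#' five-level ecomorphology vocabulary (high/good/moderate/poor/bad) is
#' mapped onto the three model levels; and whether coordinates may be
#' assumed planar when a file carries no CRS declaration.
#'
#' @return nested list of settings.
#' @export
defaultConfig <- function() {
  list(
    attributes = list(barrier = "barrier", ec = "ec", nps = "nps",
                      hdas = "hdas", restored = "restored", state = "state",
                      id = "id"),
    weights = list(barrier = 0.25, ec = 0.25, nps = 0.25, hdas = 0.25),
    bins = list(breaks = c(0, 1, 3, 5, 7, 8),
                labels = priorityCategories()),
    adjacency = list(mode = "network", max_dist_m = 500),
    buffer = list(main_width_m = 60, side_width_m = 40, cap_style = "round"),
    snap_tol_m = 1,
    mmu_m2 = 50,
    contiguity = "queen",
    ed_include_boundary = TRUE,
    rounding = list(area_dp = 2, pct_dp = 1),
    muhar_ec_mapping = TRUE,
    assume_planar = TRUE
  )
}

#' Read a configuration file
#'
#' Reads a YAML configuration and merges it over [defaultConfig()]. Unknown
#' keys are rejected (they are almost always typos of known settings);
#' values are validated on load.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
readConfig <- function(path) {
  user <- yaml::read_yaml(path)
  mergeConfig(defaultConfig(), user, "config")
}

mergeConfig <- function(base, user, where) {
  if (is.null(user)) return(base)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown config key", if (length(unknown) > 1) "s", " in ", where,
         ": ", paste(unknown, collapse = ", "))
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && !is.null(names(base[[k]])) &&
                     is.list(user[[k]]))
      mergeConfig(base[[k]], user[[k]], paste0(where, "$", k))
    else user[[k]]
  }
  if (where == "config") validateConfig(base)
  base
}

validateConfig <- function(cfg) {
  stopifnot(cfg$adjacency$mode %in% c("network", "euclidean", "node"),
            cfg$adjacency$max_dist_m >= 0,
            cfg$buffer$main_width_m > 0, cfg$buffer$side_width_m > 0,
            cfg$buffer$cap_style %in% c("round", "flat"),
            cfg$snap_tol_m >= 0, cfg$mmu_m2 > 0,
            cfg$contiguity %in% c("queen", "rook"))
  # constructors enforce the detailed invariants
  do.call(priorityWeights, cfg$weights)
  priorityBins(as.numeric(cfg$bins$breaks), as.character(cfg$bins$labels))
  invisible(cfg)
}

# ---- attribute normalization ----------------------------------------------

# normalize raw attribute values to the canonical vocabulary; the optional
# five-level ecomorphology scheme (high/good -> natural, moderate ->
# semi_natural, poor/bad -> artificial) is folded in when muhar = TRUE
normalizeAttribute <- function(x, attr, muhar = TRUE) {
  raw <- tolower(trimws(as.character(x)))
  raw[is.na(raw) | raw == ""] <- "unknown"
  maps <- list(
    barrier = c(yes = "yes", y = "yes", "true" = "yes", "1" = "yes",
                no = "no", n = "no", "false" = "no", "0" = "no",
                unknown = "unknown"),
    ec = c(natural = "natural", semi_natural = "semi_natural",
           "semi-natural" = "semi_natural", seminatural = "semi_natural",
           artificial = "artificial", unknown = "unknown"),
    nps = c(present = "present", yes = "present", "true" = "present",
            "1" = "present", absent = "absent", no = "absent",
            "false" = "absent", "0" = "absent", unknown = "unknown"))
  maps$hdas <- maps$nps
  map <- maps[[attr]]
  if (attr == "ec" && muhar)
    map <- c(map, c(high = "natural", good = "natural",
                    moderate = "semi_natural", poor = "artificial",
                    bad = "artificial"))
  out <- unname(map[raw])
  bad <- is.na(out)
  if (any(bad)) {
    warning("unmapped ", attr, " value(s) treated as unknown: ",
            paste(unique(raw[bad]), collapse = ", "), call. = FALSE)
    out[bad] <- "unknown"
  }
  out
}

# ---- GeoJSON --------------------------------------------------------------

readGeoJSON <- function(path, assumePlanar = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection in ", path)
  crsName <- tryCatch(gj$crs$properties$name, error = function(e) NULL)
  if (!is.null(crsName) &&
      grepl("4326|CRS84", crsName, ignore.case = TRUE))
    stop("geographic CRS (", crsName, ") is not supported; ",
         "supply coordinates in a planar CRS in meters")
  if (is.null(crsName) && !assumePlanar)
    stop("file carries no CRS declaration and assume_planar is FALSE")
  gj$features
}

coordsToMatrix <- function(coords)
  do.call(rbind, lapply(coords, function(p)
    c(as.numeric(p[[1]]), as.numeric(p[[2]]))))

#' Read an attributed river network from GeoJSON
#'
#' Reads LineString features, maps the configured attribute names onto the
#' canonical model attributes, normalizes values to the canonical vocabulary
#' (unmapped values become `unknown` with a warning) and builds the network
#' topology.
#'
#' @param path GeoJSON file.
#' @param config configuration list (see [defaultConfig()]); governs the
#'   attribute-name mapping, ecomorphology vocabulary mapping and snapping
#'   tolerance.
#' @return a [RiverNetwork-class].
#' @export
readNetwork <- function(path, config = defaultConfig()) {
  feats <- readGeoJSON(path, isTRUE(config$assume_planar))
  if (length(feats) == 0L) stop("no features in ", path)
  geom <- lapply(feats, function(f) {
    g <- f$geometry
    if (is.null(g)) stop("feature without geometry in ", path)
    if (identical(g$type, "LineString")) coordsToMatrix(g$coordinates)
    else if (identical(g$type, "MultiLineString") &&
             length(g$coordinates) == 1L) coordsToMatrix(g$coordinates[[1]])
    else stop("unsupported geometry type for a river segment: ", g$type)
  })
  am <- config$attributes
  pull <- function(key) vapply(feats, function(f) {
    v <- f$properties[[am[[key]]]]
    if (is.null(v) || length(v) == 0L) NA_character_ else as.character(v)
  }, character(1))
  n <- length(feats)
  muhar <- isTRUE(config$muhar_ec_mapping)
  restoredRaw <- tolower(trimws(pull("restored")))
  attributes <- data.frame(
    id = { v <- pull("id"); ifelse(is.na(v), paste0("s", seq_len(n)), v) },
    state = { v <- pull("state"); ifelse(is.na(v), "unspecified", v) },
    barrier = normalizeAttribute(pull("barrier"), "barrier"),
    ec = normalizeAttribute(pull("ec"), "ec", muhar),
    nps = normalizeAttribute(pull("nps"), "nps"),
    hdas = normalizeAttribute(pull("hdas"), "hdas"),
    restored = restoredRaw %in% c("true", "yes", "1"),
    stringsAsFactors = FALSE)
  allXY <- do.call(rbind, geom)
  if (all(abs(allXY[, 1]) <= 180) && all(abs(allXY[, 2]) <= 90))
    warning("all coordinates lie within longitude/latitude ranges; ",
            "verify the data are planar meters", call. = FALSE)
  buildNetwork(geom, attributes, snapTol = config$snap_tol_m)
}

#' Read a land-cover mosaic from GeoJSON
#'
#' Reads Polygon/MultiPolygon features carrying a `class` property with one
#' of [landCoverClasses()] (MultiPolygons are split into their parts).
#'
#' @param path GeoJSON file.
#' @param classProperty property holding the land-cover class.
#' @param epoch epoch label; default from an `epoch` property of the first
#'   feature, else `"unknown"`.
#' @param config configuration list.
#' @return a [LandCoverMap-class].
#' @export
readLandCover <- function(path, classProperty = "class", epoch = NULL,
                          config = defaultConfig()) {
  feats <- readGeoJSON(path, isTRUE(config$assume_planar))
  if (length(feats) == 0L) stop("no features in ", path)
  polys <- list(); cls <- character(0)
  for (f in feats) {
    g <- f$geometry
    k <- as.character(f$properties[[classProperty]])
    rings <- switch(g$type,
      Polygon = list(lapply(g$coordinates, coordsToMatrix)),
      MultiPolygon = lapply(g$coordinates, function(pp)
        lapply(pp, coordsToMatrix)),
      stop("unsupported geometry type for land cover: ", g$type))
    polys <- c(polys, rings)
    cls <- c(cls, rep(k, length(rings)))
  }
  epoch <- epoch %||% (feats[[1]]$properties$epoch %||% "unknown")
  landCoverMap(polys, cls, epoch = epoch)
}

# ---- writers --------------------------------------------------------------

featureCollection <- function(features)
  list(type = "FeatureCollection", features = features)

lineFeature <- function(coords, properties) {
  list(type = "Feature",
       geometry = list(type = "LineString",
                       coordinates = lapply(seq_len(nrow(coords)),
                                            function(i) coords[i, ])),
       properties = properties)
}

writeGeoJSON <- function(obj, path) {
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                           na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Write and re-read a scored network
#'
#' `writeScored()` writes one LineString feature per segment with its
#' attributes, criterion points, score and category; geometry is written
#' back unchanged and numbers at full precision, so
#' `readScored(writeScored(...))` reproduces scores and categories exactly.
#'
#' @param net a [RiverNetwork-class].
#' @param scored score table from [scoreNetwork()].
#' @param path output GeoJSON file.
#' @return `writeScored()` the path, invisibly; `readScored()` a data.frame
#'   shaped like the [scoreNetwork()] output.
#' @export
writeScored <- function(net, scored, path) {
  stopifnot(nrow(scored) == nSegments(net),
            all(scored$segment_id == net@segments$id))
  seg <- net@segments
  feats <- lapply(seq_len(nrow(scored)), function(i) {
    lineFeature(net@geometry[[i]], list(
      id = scored$segment_id[i], state = scored$state[i],
      barrier = seg$barrier[i], ec = seg$ec[i], nps = seg$nps[i],
      hdas = seg$hdas[i], restored = seg$restored[i],
      length_m = scored$length_m[i],
      p_barrier = scored$p_barrier[i], p_ec = scored$p_ec[i],
      p_nps = scored$p_nps[i], p_hdas = scored$p_hdas[i],
      score = scored$score[i], category = as.character(scored$category[i])))
  })
  writeGeoJSON(featureCollection(feats), path)
}

#' @rdname writeScored
#' @param path GeoJSON file written by `writeScored()`.
#' @export
readScored <- function(path) {
  feats <- readGeoJSON(path)
  num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  rows <- lapply(feats, function(f) {
    p <- f$properties
    data.frame(segment_id = p$id, state = p$state, length_m = num(p$length_m),
               p_barrier = num(p$p_barrier), p_ec = num(p$p_ec),
               p_nps = num(p$p_nps), p_hdas = num(p$p_hdas),
               score = num(p$score),
               category = factor(p$category, levels = reportCategories()),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a land-cover mosaic to GeoJSON
#'
#' @param map a [LandCoverMap-class].
#' @param path output file.
#' @export
writeLandCover <- function(map, path) {
  feats <- lapply(seq_along(map@polygons), function(i) {
    rings <- lapply(map@polygons[[i]], function(r) {
      r <- closeRing(r)
      lapply(seq_len(nrow(r)), function(k) r[k, ])
    })
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = rings),
         properties = list(class = as.character(map@cls[i]),
                           epoch = map@epoch))
  })
  writeGeoJSON(featureCollection(feats), path)
}

#' Write report tables to CSV
#'
#' Deterministic CSV output (no row names, no quoting surprises) for the
#' tables produced by [lengthByCategory()], [classMetrics()],
#' [changeTable()] and [bufferComposition()].
#'
#' @param tab data.frame.
#' @param path output file.
#' @export
writeTable <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
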