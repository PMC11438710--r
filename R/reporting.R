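# Length-by-category summaries and printed-precision report formatting.

#' Summarize scored network length by priority category
#'
#' Sums segment lengths per priority category — including `unknown` and
#' `already_restored`, which are part of the denominator — and expresses
#' each as a percentage of the total analyzed length. With
#' `perState = TRUE` the summary is computed per administrative unit, with
#' percentages relative to that unit's total river length.
#'
#' @param scored score table from [scoreNetwork()] (columns `category`,
#'   `length_m`, `state`).
#' @param perState logical; break the report down by state.
#' @param totalKm optional explicit denominator in km (e.g. a published
#'   network total); default the summed length of `scored`. Ignored when
#'   `perState = TRUE`.
#' @return data.frame with `category`, `length_km`, `pct` (and `state` when
#'   `perState`), one row per category in [reportCategories()] order;
#'   categories without members report 0.
#' @export
#' @examples
#' fx <- makeWorkedFixture()
#' lengthByCategory(scoreNetwork(fx$network))
lengthByCategory <- function(scored, perState = FALSE, totalKm = NULL) {
  stopifnot(nrow(scored) > 0)
  cats <- reportCategories()
  one <- function(df, denomKm) {
    km <- tapply(df$length_m, factor(as.character(df$category), levels = cats),
                 sum, default = 0) / 1000
    data.frame(category = factor(cats, levels = cats),
               length_km = as.numeric(km),
               pct = as.numeric(km) / denomKm * 100,
               stringsAsFactors = FALSE)
  }
  if (!perState)
    return(one(scored, totalKm %||% (sum(scored$length_m) / 1000)))
  parts <- lapply(split(scored, scored$state), function(df)
    cbind(state = df$state[1], one(df, sum(df$length_m) / 1000)))
  out <- do.call(rbind, parts[order(names(parts))])
  rownames(out) <- NULL
  out
}

#' Category report from published per-category lengths
#'
#' The arithmetic core of [lengthByCategory()] for when only a length table
#' is available (e.g. reproducing a published summary): given per-category
#' lengths in km and an optional explicit total, computes each category's
#' percentage share.
#'
#' @param lengthsKm named numeric, length in km per category.
#' @param totalKm denominator in km (default `sum(lengthsKm)`).
#' @return data.frame `category`, `length_km`, `pct`.
#' @export
#' @examples
#' categoryReport(c(moderate = 30.6, high = 19.7), totalKm = 84.5)
categoryReport <- function(lengthsKm, totalKm = sum(lengthsKm)) {
  stopifnot(length(lengthsKm) > 0, !is.null(names(lengthsKm)))
  data.frame(category = names(lengthsKm),
             length_km = as.numeric(lengthsKm),
             pct = as.numeric(lengthsKm) / totalKm * 100,
             stringsAsFactors = FALSE)
}

#' Format a category report at printed precision
#'
#' Deterministic text rendering of a report table: lengths and percentages
#' at one decimal, rounding half away from zero, byte-identical for
#' identical inputs.
#'
#' @param report data.frame from [lengthByCategory()] or [categoryReport()].
#' @param style `"csv"` or `"markdown"`.
#' @return character scalar, the formatted table.
#' @export
formatReport <- function(report, style = c("csv", "markdown")) {
  style <- match.arg(style)
  cols <- intersect(c("state", "category", "length_km", "pct"), names(report))
  stopifnot(all(c("category", "length_km", "pct") %in% cols))
  cells <- lapply(cols, function(cn) {
    v <- report[[cn]]
    if (is.numeric(v)) formatFixed(v, 1L) else as.character(v)
  })
  header <- c(state = "state", category = "category",
              length_km = "length_km", pct = "pct")[cols]
  rows <- do.call(paste, c(cells, sep = if (style == "csv") "," else " | "))
  if (style == "csv") {
    paste(c(paste(header, collapse = ","), rows), collapse = "\n")
  } else {
    paste(c(paste("|", paste(header, collapse = " | "), "|"),
            paste("|", paste(rep("---", length(cols)), collapse = " | "), "|"),
            paste("|", rows, "|")),
          collapse = "\n")
  }
}
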