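#' Read an age-share table into a compositional series
#'
#' Accepts the two common layouts of published share tables: wide (a year
#' column plus one column per group) and long (year, group, value). Units
#' are auto-detected from the row sums: values summing to about 100 are
#' percentages, to about 1 proportions; anything else is rejected with the
#' offending row. Rows are re-closed to exact unit sum, with a message when
#' the deviation exceeds 1e-6.
#'
#' @param path CSV file path.
#' @param layout `"auto"`, `"wide"` or `"long"`.
#' @param unit `"auto"`, `"percent"` or `"proportion"`.
#' @return A `coda_series`.
#' @export
read_series_csv <- function(path, layout = c("auto", "wide", "long"),
                            unit = c("auto", "percent", "proportion")) {
  layout <- match.arg(layout)
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (nrow(df) < 1 || ncol(df) < 2) {
    stop("table must have a header, at least one row and two columns",
         call. = FALSE)
  }
  nms <- tolower(names(df))
  if (layout == "auto") {
    layout <- if (ncol(df) == 3 &&
                  (all(c("group", "value") %in% nms) ||
                   all(c("component", "value") %in% nms))) "long"
              else "wide"
  }
  ycol <- which(nms == "year")
  if (length(ycol) == 0) ycol <- 1L else ycol <- ycol[1]
  if (layout == "long") {
    gcol <- which(nms %in% c("group", "component", "part"))[1]
    vcol <- which(nms %in% c("value", "share", "proportion"))[1]
    if (is.na(gcol) || is.na(vcol)) {
      stop("long layout needs 'group' and 'value' columns; found: ",
           paste(names(df), collapse = ", "), call. = FALSE)
    }
    groups <- unique(df[[gcol]])
    years <- sort(unique(df[[ycol]]))
    wide <- matrix(NA_real_, length(years), length(groups),
                   dimnames = list(NULL, groups))
    for (i in seq_len(nrow(df))) {
      r <- match(df[[ycol]][i], years)
      c <- match(df[[gcol]][i], groups)
      if (!is.na(wide[r, c])) {
        stop("duplicate (year, group) pair at input row ", i, call. = FALSE)
      }
      wide[r, c] <- df[[vcol]][i]
    }
    if (anyNA(wide)) {
      stop("long table is not complete: some (year, group) cells missing",
           call. = FALSE)
    }
    values <- wide
  } else {
    years <- df[[ycol]]
    values <- as.matrix(df[, -ycol, drop = FALSE])
    if (!is.numeric(values)) {
      stop("non-numeric group column in wide table", call. = FALSE)
    }
  }
  if (any(years != round(years))) {
    stop("years must be integers", call. = FALSE)
  }
  if (anyDuplicated(years)) {
    stop("duplicate year: ", years[anyDuplicated(years)], call. = FALSE)
  }
  ord <- order(years)
  years <- as.integer(years[ord])
  values <- values[ord, , drop = FALSE]
  rs <- rowSums(values)
  resolved <- switch(unit,
    percent = "percent", proportion = "proportion",
    auto = if (all(rs >= 98 & rs <= 102)) "percent"
           else if (all(rs >= 0.98 & rs <= 1.02)) "proportion"
           else {
             bad <- which(!(rs >= 98 & rs <= 102) &
                          !(rs >= 0.98 & rs <= 1.02))[1]
             stop("cannot infer units: row ", bad, " (year ", years[bad],
                  ") sums to ", format(rs[bad]),
                  ", neither ~100 nor ~1", call. = FALSE)
           })
  if (resolved == "percent") values <- values / 100
  rs <- rowSums(values)
  tolerance <- 0.02                      # matches the auto-detection band
  bad <- which(abs(rs - 1) > tolerance)
  if (length(bad)) {
    stop("row ", bad[1], " (year ", years[bad[1]], ") sums to ",
         format(rs[bad[1]]), " in proportion units; outside tolerance",
         call. = FALSE)
  }
  drift <- which(abs(rs - 1) > 1e-6)
  if (length(drift)) {
    message("renormalised ", length(drift),
            " row(s) whose shares did not sum exactly to 1 (max deviation ",
            format(max(abs(rs - 1))), ")")
  }
  values <- values / rs
  coda_series(years, values, tol = 1e-6)
}

#' Write a compositional series as a wide CSV
#'
#' Writes the dialect [read_series_csv()] consumes (Year column plus one
#' column per group), so simulated fixtures can exercise the full I/O
#' path.
#'
#' @param series A `coda_series`.
#' @param path Output CSV path.
#' @param unit `"percent"` (default) or `"proportion"`.
#' @param digits Rounding applied to the written values.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path, unit = c("percent",
                                                    "proportion"),
                             digits = 6) {
  stopifnot(inherits(series, "coda_series"))
  unit <- match.arg(unit)
  vals <- series$parts * if (unit == "percent") 100 else 1
  df <- data.frame(Year = series$years, round(vals, digits),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a forecast table with a full-precision JSON companion
#'
#' Writes the forecast as a CSV of percentages rounded to two decimals
#' (Year plus one column per group; invalid rows carry a `flag` column),
#' and a JSON companion holding the unrounded proportions and full
#' provenance: transform, model family, horizon, configuration (including
#' seeds) and any validity or clamping warnings.
#'
#' @param result A `coda_forecast`.
#' @param path Output CSV path.
#' @param json_path Companion JSON path; default replaces the `.csv`
#'   suffix with `.json`.
#' @return `path`, invisibly.
#' @export
write_forecast_table <- function(result, path, json_path = NULL) {
  stopifnot(inherits(result, "coda_forecast"))
  if (is.null(json_path)) json_path <- sub("\\.csv$", ".json", path)
  if (identical(json_path, path)) json_path <- paste0(path, ".json")
  df <- data.frame(Year = result$years,
                   round(result$parts * 100, 2), check.names = FALSE)
  if (!all(result$valid)) df$flag <- ifelse(result$valid, "", "invalid")
  utils::write.csv(df, path, row.names = FALSE)
  payload <- list(
    transform = result$transform,
    model = result$model,
    horizon = result$horizon,
    config = unclass(result$config),
    years = result$years,
    labels = result$labels,
    compositions = unname(apply(result$parts, 1, as.numeric,
                                simplify = FALSE)),
    valid = result$valid,
    n_clamped = result$n_clamped)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
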