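#' Close a nonnegative vector to unit sum
#'
#' Renormalises a vector of nonnegative amounts to proportions summing to 1
#' (the closure operation of compositional data analysis).
#'
#' @param raw Numeric vector of length >= 2, all entries nonnegative, at
#'   least one positive.
#' @return Numeric vector of the same length summing to 1.
#' @examples
#' closure(c(2, 1, 1))
#' @export
closure <- function(raw) {
  if (!is.numeric(raw) || length(raw) < 2) {
    stop("closure() needs a numeric vector of length >= 2", call. = FALSE)
  }
  if (any(!is.finite(raw))) {
    stop("closure(): non-finite entry at index ",
         which(!is.finite(raw))[1], call. = FALSE)
  }
  neg <- which(raw < 0)
  if (length(neg)) {
    stop("closure(): negative part at index ", neg[1],
         " (value ", format(raw[neg[1]]), ")", call. = FALSE)
  }
  s <- sum(raw)
  if (s <= 0) {
    stop("closure(): all parts are zero; composition undefined", call. = FALSE)
  }
  raw / s
}

#' Validate a composition
#'
#' Checks that `x` is a D-part composition: D >= 2, all parts nonnegative,
#' unit sum within `tol`.
#'
#' @param x Numeric vector.
#' @param tol Tolerance on the unit-sum constraint.
#' @return `x`, invisibly, after validation.
#' @export
validate_composition <- function(x, tol = 1e-9) {
  if (!is.numeric(x) || length(x) < 2) {
    stop("a composition needs at least 2 parts", call. = FALSE)
  }
  neg <- which(x < 0)
  if (length(neg)) {
    stop("composition has a negative part at index ", neg[1], call. = FALSE)
  }
  if (abs(sum(x) - 1) > tol) {
    stop("composition parts sum to ", format(sum(x)),
         ", not 1 (tolerance ", tol, ")", call. = FALSE)
  }
  invisible(x)
}

#' Multiplicative zero replacement
#'
#' Replaces zero parts of a composition by a small value `epsilon`, scales
#' the nonzero parts down proportionally, and re-closes the result. This is
#' the standard multiplicative replacement strategy used before log-ratio
#' operations, which are undefined at zero.
#'
#' @param x Composition (nonnegative, unit sum).
#' @param epsilon Replacement value for zero parts, in proportion units.
#'   `NULL` disables replacement, so a zero part raises an error.
#' @param quiet Suppress the replacement message.
#' @return A strictly positive composition.
#' @export
replace_zeros <- function(x, epsilon = 1e-6, quiet = TRUE) {
  zero <- x <= 0
  if (!any(zero)) return(x)
  if (is.null(epsilon) || !is.numeric(epsilon) || epsilon <= 0) {
    stop("composition has a zero part at index ", which(zero)[1],
         " and zero replacement is disabled; log-ratio transforms need ",
         "strictly positive parts", call. = FALSE)
  }
  n0 <- sum(zero)
  out <- x
  out[zero] <- epsilon
  out[!zero] <- x[!zero] * (1 - n0 * epsilon)
  if (!quiet) {
    message("replaced ", n0, " zero part(s) by epsilon = ", epsilon)
  }
  closure(out)
}

#' Construct a compositional time series
#'
#' Bundles strictly increasing integer years with one composition per year
#' (rows of `parts`). All rows must satisfy the unit-sum constraint within
#' `tol`; rows are re-closed so the stored values sum to 1 exactly.
#'
#' @param years Integer vector, strictly increasing.
#' @param parts Numeric matrix, one row per year, one column per component.
#' @param labels Optional component names; defaults to the column names of
#'   `parts`, or `young`/`middle`/`old` for 3 parts.
#' @param tol Unit-sum tolerance applied per row.
#' @return An object of class `coda_series` with elements `years`, `parts`
#'   (rows closed to sum 1) and `labels`.
#' @export
coda_series <- function(years, parts, labels = NULL, tol = 1e-9) {
  parts <- as.matrix(parts)
  if (!is.numeric(years) || length(years) < 1) {
    stop("years must be a non-empty integer vector", call. = FALSE)
  }
  years <- as.integer(years)
  if (length(years) >= 2 && any(diff(years) <= 0)) {
    stop("years must be strictly increasing", call. = FALSE)
  }
  if (nrow(parts) != length(years)) {
    stop("parts has ", nrow(parts), " rows but there are ",
         length(years), " years", call. = FALSE)
  }
  if (ncol(parts) < 2) stop("need at least 2 components", call. = FALSE)
  if (is.null(labels)) {
    labels <- colnames(parts)
    if (is.null(labels)) {
      labels <- if (ncol(parts) == 3) c("young", "middle", "old")
                else paste0("part", seq_len(ncol(parts)))
    }
  }
  if (length(labels) != ncol(parts)) {
    stop("labels length does not match the number of components",
         call. = FALSE)
  }
  for (i in seq_along(years)) {
    ok <- try(validate_composition(parts[i, ], tol = tol), silent = TRUE)
    if (inherits(ok, "try-error")) {
      stop("row for year ", years[i], ": ",
           conditionMessage(attr(ok, "condition")), call. = FALSE)
    }
    parts[i, ] <- parts[i, ] / sum(parts[i, ])
  }
  colnames(parts) <- labels
  structure(list(years = years, parts = parts, labels = labels),
            class = "coda_series")
}

#' @export
print.coda_series <- function(x, ...) {
  cat("<coda_series> ", length(x$years), " years (",
      x$years[1], "-", x$years[length(x$years)], "), ",
      ncol(x$parts), " components: ",
      paste(x$labels, collapse = ", "), "\n", sep = "")
  n <- length(x$years)
  show <- unique(c(seq_len(min(3, n)), n))
  df <- data.frame(year = x$years[show],
                   round(x$parts[show, , drop = FALSE], 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
length.coda_series <- function(x) length(x$years)

#' Subset a compositional series by index
#'
#' @param series A `coda_series`.
#' @param idx Integer indices (in year order) to keep.
#' @return A `coda_series` with the selected years.
#' @export
subset_series <- function(series, idx) {
  stopifnot(inherits(series, "coda_series"))
  coda_series(series$years[idx], series$parts[idx, , drop = FALSE],
              labels = series$labels)
}
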