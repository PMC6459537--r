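# centred log-ratio of a strictly positive composition
clr <- function(x) {
  lx <- log(x)
  lx - mean(lx)
}

#' Aitchison distance between two compositions
#'
#' The Euclidean distance between the centred log-ratio representations,
#' \deqn{d_S(x, \hat x) = \sqrt{ \sum_d \big( \ln(x_d/g(x)) -
#'   \ln(\hat x_d/g(\hat x)) \big)^2 },}
#' with \eqn{g} the geometric mean. Identical to the Euclidean distance
#' between ILR coordinates (the transform is an isometry).
#'
#' @param x,xhat Compositions of equal length. Zero parts are replaced via
#'   [replace_zeros()].
#' @param epsilon Zero-replacement value.
#' @return Nonnegative scalar.
#' @export
aitchison_distance <- function(x, xhat, epsilon = 1e-6) {
  if (length(x) != length(xhat)) {
    stop("compositions have different numbers of parts (", length(x),
         " vs ", length(xhat), ")", call. = FALSE)
  }
  validate_composition(x)
  validate_composition(xhat)
  x <- replace_zeros(x, epsilon)
  xhat <- replace_zeros(xhat, epsilon)
  sqrt(sum((clr(x) - clr(xhat))^2))
}

#' Aitchison norm of a composition
#'
#' \deqn{\lVert x \rVert_S = \sqrt{\sum_d \ln^2(x_d / g(x))},}
#' the Aitchison distance from the uniform (neutral) composition; measures
#' how far a composition lies from equal shares.
#'
#' @inheritParams aitchison_distance
#' @return Nonnegative scalar; 0 iff all parts are equal.
#' @export
coda_norm <- function(x, epsilon = 1e-6) {
  validate_composition(x)
  x <- replace_zeros(x, epsilon)
  sqrt(sum(clr(x)^2))
}

#' Compositional forecast accuracy: CoDa-RMSE and CoDa-MAPE
#'
#' Scores predicted against observed compositions over a test window.
#' CoDa-RMSE is the mean Aitchison distance between observed and predicted
#' compositions (a mean of distances, which is how the measure is defined
#' in the literature this package follows, despite the "RMSE" name; set
#' `root_mean_square = TRUE` for a true root-mean-square variant).
#' CoDa-MAPE normalises each distance by the Aitchison norm of the
#' observation and reports the mean as a percentage.
#'
#' @param observed,predicted `coda_series` objects with identical years and
#'   component counts, or plain matrices of aligned composition rows.
#' @param epsilon Zero-replacement value for the log-ratio operations.
#' @param root_mean_square If `TRUE`, return `sqrt(mean(d^2))` instead of
#'   `mean(d)` for the RMSE component.
#' @return List with `coda_rmse` and `coda_mape` (percent).
#' @export
coda_errors <- function(observed, predicted, epsilon = 1e-6,
                        root_mean_square = FALSE) {
  if (inherits(observed, "coda_series") &&
      inherits(predicted, "coda_series")) {
    if (!identical(observed$years, predicted$years)) {
      stop("observed and predicted series cover different years",
           call. = FALSE)
    }
    years <- observed$years
    obs <- observed$parts
    pred <- predicted$parts
  } else {
    obs <- as.matrix(observed)
    pred <- as.matrix(predicted)
    years <- seq_len(nrow(obs))
  }
  if (!all(dim(obs) == dim(pred))) {
    stop("observed and predicted have different dimensions", call. = FALSE)
  }
  if (nrow(obs) < 1) stop("empty test window", call. = FALSE)
  n <- nrow(obs)
  d <- numeric(n)
  nrm <- numeric(n)
  for (i in seq_len(n)) {
    d[i] <- aitchison_distance(obs[i, ], pred[i, ], epsilon)
    nrm[i] <- coda_norm(obs[i, ], epsilon)
    if (nrm[i] < 1e-12) {
      stop("observation for year ", years[i], " is the uniform composition ",
           "(Aitchison norm 0); CoDa-MAPE is undefined there", call. = FALSE)
    }
  }
  list(coda_rmse = if (root_mean_square) sqrt(mean(d^2)) else mean(d),
       coda_mape = mean(d / nrm) * 100)
}
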