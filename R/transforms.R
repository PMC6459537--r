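#' Isometric log-ratio (ILR) transform, pivot basis
#'
#' Maps a strictly positive D-part composition to D-1 unconstrained
#' coordinates
#' \deqn{w_d = \sqrt{d/(d+1)} \, \ln\!\big( g(x_1,\dots,x_d) / x_{d+1} \big),}
#' where \eqn{g} is the geometric mean. The map is an isometry between the
#' simplex with the Aitchison metric and Euclidean space, which is the basis
#' of the metric cross-checks used in the test suite.
#'
#' @param x Composition (nonnegative parts, unit sum). Zero parts are
#'   handled by [replace_zeros()] with `epsilon`.
#' @param epsilon Zero-replacement value; `NULL` forbids zeros.
#' @return Numeric vector of length D-1 (log-ratio units).
#' @seealso [ilr_inverse()]
#' @export
ilr_forward <- function(x, epsilon = 1e-6) {
  validate_composition(x)
  x <- replace_zeros(x, epsilon)
  D <- length(x)
  lx <- log(x)
  cm <- cumsum(lx)
  d <- seq_len(D - 1)
  sqrt(d / (d + 1)) * (cm[d] / d - lx[d + 1])
}

# clr vector from pivot-ILR coordinates: v_d = sum_{i>=d} w_i/sqrt(i(i+1))
#                                              - sqrt((d-1)/d) w_{d-1}
# (w_0 = w_D = 0); entries sum to 0 by construction.
clr_from_ilr <- function(w) {
  if (any(!is.finite(w))) {
    stop("ILR coordinates must be finite", call. = FALSE)
  }
  D <- length(w) + 1
  i <- seq_len(D - 1)
  scaled <- w / sqrt(i * (i + 1))
  tail_sum <- rev(cumsum(rev(scaled)))        # tail_sum[d] = sum_{i>=d}
  v <- numeric(D)
  v[seq_len(D - 1)] <- tail_sum
  v[2:D] <- v[2:D] - sqrt((1:(D - 1)) / (2:D)) * w
  v
}

#' Inverse ILR transform
#'
#' Reconstructs a composition from pivot-basis ILR coordinates. The
#' coordinates are first expanded to a centred log-ratio (clr) vector whose
#' entries sum to zero, then mapped to the simplex by exponentiation and
#' closure.
#'
#' @param w Numeric vector of finite ILR coordinates (length D-1).
#' @return A strictly positive composition of length D.
#' @seealso [ilr_forward()]
#' @export
ilr_inverse <- function(w) {
  v <- clr_from_ilr(w)
  e <- exp(v - max(v))   # guard against overflow; closure removes the shift
  e / sum(e)
}

#' Hyperspherical (DRHT) forward transform
#'
#' Encodes a D-part composition as D-1 angles. The square roots
#' \eqn{y_d = \sqrt{x_d}} lie on the unit hypersphere
#' (\eqn{\sum y_d^2 = 1}) and are written in spherical coordinates:
#' \eqn{\theta_D = \arccos y_D} and, descending to d = 2,
#' \eqn{\theta_d = \arccos( y_d / \prod_{i>d} \sin\theta_i )}.
#' Zero parts are allowed. When the running product of sines vanishes
#' (no mass left for the leading parts) the remaining angles are set to 0;
#' any value would reproduce the same composition under the inverse map.
#'
#' @param x Composition (nonnegative parts, unit sum).
#' @return Numeric vector of D-1 angles in `[0, pi/2]`, representing
#'   `theta_2 .. theta_D`.
#' @seealso [drht_inverse()]
#' @export
drht_forward <- function(x) {
  validate_composition(x)
  D <- length(x)
  y <- sqrt(x / sum(x))
  theta <- numeric(D - 1)            # theta[j] holds theta_{j+1}
  sinprod <- 1
  for (d in D:2) {
    if (sinprod < 1e-12) {
      theta[seq_len(d - 1)] <- 0
      break
    }
    arg <- min(max(y[d] / sinprod, 0), 1)
    th <- acos(arg)
    theta[d - 1] <- th
    sinprod <- sinprod * sin(th)
  }
  theta
}

#' Inverse hyperspherical (DRHT) transform
#'
#' Maps D-1 angles back to a composition:
#' \eqn{x_1 = (\prod_{i=2}^D \sin\theta_i)^2},
#' \eqn{x_d = (\cos\theta_d \prod_{i>d} \sin\theta_i)^2} for 1 < d < D, and
#' \eqn{x_D = (\cos\theta_D)^2}. The output sums to 1 identically (sum of
#' squared spherical coordinates), so forecasted angles always yield a
#' valid composition. Angles outside `[0, pi/2]` should be clipped by the
#' caller before back-transforming.
#'
#' @param theta Numeric vector of D-1 angles (radians) in `[0, pi/2]`.
#' @return Composition of length D.
#' @seealso [drht_forward()]
#' @export
drht_inverse <- function(theta) {
  if (any(!is.finite(theta))) stop("angles must be finite", call. = FALSE)
  if (any(theta < -1e-12 | theta > pi / 2 + 1e-12)) {
    stop("angles must lie in [0, pi/2]; clip forecasted angles first",
         call. = FALSE)
  }
  theta <- pmin(pmax(theta, 0), pi / 2)
  D <- length(theta) + 1
  x <- numeric(D)
  sinprod <- 1
  for (d in D:2) {
    th <- theta[d - 1]
    x[d] <- (cos(th) * sinprod)^2
    sinprod <- sinprod * sin(th)
  }
  x[1] <- sinprod^2
  x
}

#' Complete a linear-combined-component (LCC) forecast
#'
#' In the LCC approach one component is treated as the complement of the
#' others: the D-1 retained parts are forecast directly and the dropped
#' part is defined as 1 minus their sum. The result may leave the unit
#' simplex (negative or >1 parts); such rows are returned with
#' `valid = FALSE` rather than raising, and any repair is left to the
#' metric layer.
#'
#' @param retained Numeric vector of D-1 forecast parts.
#' @param dropped_index Position (1..D) at which the complement is inserted.
#' @return List with `parts` (length D, summing to 1) and `valid` (logical).
#' @export
lcc_complete <- function(retained, dropped_index) {
  if (!is.numeric(retained) || length(retained) < 1) {
    stop("retained must be a numeric vector of length >= 1", call. = FALSE)
  }
  D <- length(retained) + 1
  if (dropped_index < 1 || dropped_index > D) {
    stop("dropped_index must be in 1..", D, call. = FALSE)
  }
  parts <- append(retained, 1 - sum(retained), after = dropped_index - 1)
  list(parts = parts, valid = all(parts >= 0 & parts <= 1))
}

#' Repair an invalid composition forecast
#'
#' Clips parts to `[epsilon, 1]` and re-closes. Used at metric-computation
#' time on flagged LCC or raw-scale forecasts; raw values are preserved in
#' the forecast objects themselves.
#'
#' @param parts Numeric vector (possibly outside the simplex).
#' @param epsilon Lower clip bound.
#' @return A valid composition.
#' @export
repair_composition <- function(parts, epsilon = 1e-6) {
  closure(pmin(pmax(parts, epsilon), 1))
}
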