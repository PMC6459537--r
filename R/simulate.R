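#' Parameters for the synthetic age-structure generator
#'
#' The generator draws ILR coordinates along a linear trend with AR(1)
#' noise, \eqn{w_t = a + b t + e_t}, \eqn{e_t = \phi e_{t-1} +
#' \varepsilon_t}, \eqn{\varepsilon_t \sim N(0, \sigma^2)}, \eqn{e_0 = 0},
#' and maps them to the simplex with [ilr_inverse()]. A linear drift in
#' log-ratio space is the smooth, monotone-ish secular change typical of
#' national age-share series; the AR(1) term adds the serial dependence
#' annual demographic data display.
#'
#' @param D Number of parts (default 3: young/middle/old).
#' @param a,b ILR intercepts and slopes per year, length D-1.
#' @param phi AR(1) coefficient, |phi| < 1.
#' @param sigma Innovation standard deviation (log-ratio units).
#' @param n Number of annual observations (>= 2).
#' @param start_year First calendar year.
#' @param seed Random seed.
#' @return Object of class `scenario_params`.
#' @export
scenario_params <- function(D = 3, a, b, phi = 0.5, sigma = 0.05, n = 57,
                            start_year = 1960, seed = 20190411) {
  stopifnot(D >= 2, length(a) == D - 1, length(b) == D - 1,
            abs(phi) < 1, sigma >= 0, n >= 2)
  structure(list(D = as.integer(D), a = as.numeric(a), b = as.numeric(b),
                 phi = phi, sigma = sigma, n = as.integer(n),
                 start_year = as.integer(start_year),
                 seed = as.integer(seed)),
            class = "scenario_params")
}

#' Simulate a compositional age-structure series
#'
#' Draws the generative model of [scenario_params()]: per-coordinate linear
#' ILR trend plus AR(1) noise (initialised at 0 so short series are exactly
#' reproducible), back-transformed to compositions. With `sigma = 0` the
#' output is exactly `ilr_inverse(a + b t)` for every t.
#'
#' @param params A `scenario_params`.
#' @return A `coda_series` of `params$n` strictly positive compositions.
#' @export
simulate_coda_series <- function(params) {
  stopifnot(inherits(params, "scenario_params"))
  n <- params$n
  Dm1 <- params$D - 1
  set.seed(params$seed)
  eps <- matrix(stats::rnorm(n * Dm1, 0, params$sigma), n, Dm1)
  e <- matrix(0, n, Dm1)
  e[1, ] <- eps[1, ]
  if (n > 1) {
    for (t in 2:n) e[t, ] <- params$phi * e[t - 1, ] + eps[t, ]
  }
  W <- outer(seq_len(n), params$b) + matrix(params$a, n, Dm1, byrow = TRUE) +
    e
  parts <- t(apply(W, 1, ilr_inverse))
  labels <- if (params$D == 3) c("young", "middle", "old")
            else paste0("part", seq_len(params$D))
  coda_series(params$start_year + 0:(n - 1), parts, labels = labels)
}

# noiseless mean path of a scenario (used by tests and docs)
scenario_mean_path <- function(params) {
  noiseless <- params
  noiseless$sigma <- 0
  simulate_coda_series(noiseless)
}

#' Preset synthetic scenarios
#'
#' Fixed parameter sets emulating the qualitative trend shapes of three
#' national age-structure series over 57 years: a steep ageing path
#' (`"china-like"`: young share falls fast, old share rises), a younger
#' profile with a rising middle share (`"india-like"`), and a moderate
#' intermediate path (`"vietnam-like"`). The ILR intercepts and slopes are
#' derived from stylised start and end compositions; they are library
#' constants, not estimates from any published series.
#'
#' @param name One of `"china-like"`, `"india-like"`, `"vietnam-like"`.
#' @param n,seed Overridable series length and seed.
#' @return A `scenario_params`.
#' @export
scenario_presets <- function(name, n = 57, seed = 20190411) {
  presets <- list(
    "china-like" = list(start = c(0.40, 0.56, 0.04),
                        end = c(0.18, 0.72, 0.10)),
    "india-like" = list(start = c(0.41, 0.56, 0.03),
                        end = c(0.28, 0.66, 0.06)),
    "vietnam-like" = list(start = c(0.40, 0.55, 0.05),
                          end = c(0.23, 0.70, 0.07)))
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; valid names: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  p <- presets[[name]]
  w0 <- ilr_forward(p$start)
  w1 <- ilr_forward(p$end)
  b <- (w1 - w0) / (n - 1)
  a <- w0 - b           # so the mean path hits w0 at t = 1, w1 at t = n
  scenario_params(D = 3, a = a, b = b, phi = 0.5, sigma = 0.05, n = n,
                  seed = seed)
}

#' Recover generator parameters from a simulated series
#'
#' Per ILR coordinate, ordinary least squares of the coordinate on time
#' gives the intercept and slope; the AR(1) coefficient and innovation
#' standard deviation are estimated from the regression residuals
#' (conditional least squares), then averaged over coordinates. Serves as
#' the ground-truth check that the pipeline's input representation is
#' identifiable.
#'
#' @param series A strictly positive `coda_series` with >= 10 years.
#' @param epsilon Zero-replacement value for the ILR map.
#' @return List with `a_hat`, `b_hat` (length D-1), scalar `phi_hat`,
#'   `sigma_hat`, and the per-coordinate estimates.
#' @export
recover_parameters <- function(series, epsilon = 1e-6) {
  stopifnot(inherits(series, "coda_series"))
  n <- length(series$years)
  if (n < 10) stop("need at least 10 observations, got ", n, call. = FALSE)
  W <- t(apply(series$parts, 1, ilr_forward, epsilon = epsilon))
  tt <- seq_len(n)
  Dm1 <- ncol(W)
  a_hat <- b_hat <- phi_co <- sigma_co <- numeric(Dm1)
  for (j in seq_len(Dm1)) {
    fit <- stats::lm(W[, j] ~ tt)
    a_hat[j] <- stats::coef(fit)[1]
    b_hat[j] <- stats::coef(fit)[2]
    e <- stats::residuals(fit)
    den <- sum(e[-n]^2)
    if (den < 1e-16) {
      phi_co[j] <- 0
      sigma_co[j] <- 0
    } else {
      phi_co[j] <- sum(e[-1] * e[-n]) / den
      innov <- e[-1] - phi_co[j] * e[-n]
      sigma_co[j] <- stats::sd(innov)
    }
  }
  list(a_hat = a_hat, b_hat = b_hat, phi_hat = mean(phi_co),
       sigma_hat = mean(sigma_co), phi_by_coordinate = phi_co,
       sigma_by_coordinate = sigma_co)
}
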