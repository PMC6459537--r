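#' Configure a forecasting backend
#'
#' Builds a validated configuration for one of the four model families.
#' Family-specific fields are kept only for the requested family.
#'
#' @param family One of `"ARIMA"`, `"ETS"`, `"VAR"`, `"NNETTS"`.
#' @param arima_order `NULL` for automatic order selection by corrected AIC
#'   over p <= 3, d <= 2, q <= 3 (a drift term is included when d = 1), or a
#'   fixed `c(p, d, q)`.
#' @param ets_form `"auto"` (choose between simple and trend-corrected
#'   exponential smoothing by corrected AIC), `"ses"` or `"holt"`.
#' @param var_max_lag Maximum VAR lag order searched by AIC.
#' @param m Number of lagged inputs of the neural autoregression.
#' @param hidden Number of hidden units of the neural autoregression.
#' @param restarts Number of seeded random restarts for neural-network
#'   training; the best in-sample fit is kept.
#' @param seed Base random seed for stochastic training.
#' @return An object of class `model_config`.
#' @export
model_config <- function(family = c("ARIMA", "ETS", "VAR", "NNETTS"),
                         arima_order = NULL, ets_form = "auto",
                         var_max_lag = 5, m = 1, hidden = 1,
                         restarts = 20, seed = 20190411) {
  family <- match.arg(family)
  cfg <- list(family = family, seed = as.integer(seed))
  if (family == "ARIMA") {
    if (!is.null(arima_order)) {
      stopifnot(is.numeric(arima_order), length(arima_order) == 3,
                all(arima_order >= 0))
      cfg$arima_order <- as.integer(arima_order)
    } else {
      cfg$arima_order <- NULL
    }
  } else if (family == "ETS") {
    cfg$ets_form <- match.arg(ets_form, c("auto", "ses", "holt"))
  } else if (family == "VAR") {
    stopifnot(var_max_lag >= 1)
    cfg$var_max_lag <- as.integer(var_max_lag)
  } else {
    stopifnot(m >= 1, hidden >= 1, restarts >= 1)
    cfg$m <- as.integer(m)
    cfg$hidden <- as.integer(hidden)
    cfg$restarts <- as.integer(restarts)
  }
  structure(cfg, class = "model_config")
}

# ---- degenerate (constant-series) model -----------------------------------

constant_model <- function(x, family) {
  list(family = family, constant = TRUE, value = x[length(x)],
       fitted_values = x, residuals = rep(0, length(x)))
}

is_constant <- function(x) stats::sd(x) < 1e-10

# ---- ARIMA ----------------------------------------------------------------

aicc_from_aic <- function(aic, npar, n) {
  denom <- n - npar - 1
  if (denom <= 0) return(Inf)
  aic + 2 * npar * (npar + 1) / denom
}

fit_arima <- function(x, k, order = NULL) {
  n <- length(x)
  if (is_constant(x)) {
    mod <- constant_model(x, "ARIMA")
    return(list(model = mod, forecast = rep(mod$value, k)))
  }
  grid <- if (is.null(order)) {
    expand.grid(p = 0:3, d = 0:2, q = 0:3)
  } else {
    data.frame(p = order[1], d = order[2], q = order[3])
  }
  best <- NULL
  best_aicc <- Inf
  tt <- matrix(seq_len(n), ncol = 1, dimnames = list(NULL, "drift"))
  for (i in seq_len(nrow(grid))) {
    p <- grid$p[i]; d <- grid$d[i]; q <- grid$q[i]
    xreg <- if (d == 1) tt else NULL
    fit <- try(suppressWarnings(
      stats::arima(x, order = c(p, d, q), xreg = xreg)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    npar <- length(stats::coef(fit)) + 1          # + innovation variance
    aicc <- aicc_from_aic(fit$aic, npar, n)
    if (is.finite(aicc) && aicc < best_aicc - 1e-12) {
      best_aicc <- aicc
      best <- list(fit = fit, order = c(p, d, q), drift = d == 1)
    }
  }
  if (is.null(best)) {
    stop("no ARIMA candidate could be fitted to the series", call. = FALSE)
  }
  # predict.Arima re-evaluates the recorded `xreg` expression here, so the
  # variable must hold the training regressor of the *selected* model
  xreg <- if (best$drift) tt else NULL
  newxreg <- if (best$drift) {
    matrix(n + seq_len(k), ncol = 1, dimnames = list(NULL, "drift"))
  } else NULL
  fc <- if (k >= 1) {
    as.numeric(stats::predict(best$fit, n.ahead = k,
                              newxreg = newxreg)$pred)
  } else numeric(0)
  res <- as.numeric(stats::residuals(best$fit))
  mod <- list(family = "ARIMA", order = best$order, drift = best$drift,
              aicc = best_aicc, fit = best$fit,
              fitted_values = x - res, residuals = res)
  list(model = mod, forecast = fc)
}

# ---- ETS (exponential smoothing) ------------------------------------------

fit_ets <- function(x, k, form = "auto") {
  n <- length(x)
  if (is_constant(x)) {
    mod <- constant_model(x, "ETS")
    return(list(model = mod, forecast = rep(mod$value, k)))
  }
  cands <- switch(form, auto = c("ses", "holt"), ses = "ses", holt = "holt")
  xt <- stats::ts(x)
  best <- NULL
  best_aicc <- Inf
  for (cand in cands) {
    hw <- try(suppressWarnings(
      stats::HoltWinters(xt, beta = cand == "holt", gamma = FALSE)),
      silent = TRUE)
    if (inherits(hw, "try-error")) next
    ne <- nrow(hw$fitted)                 # one-step errors available
    npar <- if (cand == "holt") 4L else 2L  # smoothing + initial states
    sigma2 <- max(hw$SSE / ne, 1e-300)   # SSE = 0 on a perfect fit
    aicc <- aicc_from_aic(ne * log(sigma2) + 2 * (npar + 1), npar + 1, ne)
    if (is.finite(aicc) && aicc < best_aicc - 1e-12) {
      best_aicc <- aicc
      best <- list(hw = hw, form = cand, offset = n - ne)
    }
  }
  if (is.null(best)) {
    stop("exponential smoothing failed on the series", call. = FALSE)
  }
  fitted_full <- rep(NA_real_, n)
  fitted_full[(best$offset + 1):n] <- as.numeric(best$hw$fitted[, "xhat"])
  fc <- if (k >= 1) {
    as.numeric(stats::predict(best$hw, n.ahead = k))
  } else numeric(0)
  mod <- list(family = "ETS", form = best$form, aicc = best_aicc,
              fit = best$hw, fitted_values = fitted_full,
              residuals = x - fitted_full)
  list(model = mod, forecast = fc)
}

# ---- NNETTS: single-hidden-layer autoregressive neural net ----------------

#' Train a neural autoregression (NNETTS)
#'
#' Fits the single-hidden-layer nonlinear autoregression
#' \deqn{x_{t+1} = \beta_0 + \sum_{j} \beta_j \,
#'   g\big(\gamma_{0j} + \sum_{i=1}^{m} \gamma_{ij} x_{t-i+1}\big) + e_t}
#' with logistic activation \eqn{g}, by least squares on the standardised
#' series. Training runs `restarts` seeded random initialisations
#' (weights uniform in (-0.5, 0.5)) and keeps the fit with the lowest
#' in-sample squared error, making the result a deterministic function of
#' `(series, m, hidden, restarts, seed)`.
#'
#' @param x Numeric series, length > m + hidden.
#' @param m Number of lagged inputs.
#' @param hidden Number of hidden units.
#' @param restarts Seeded random restarts; best fit kept.
#' @param seed Base seed; restart r uses `seed + r - 1`.
#' @param maxit Optimiser iteration cap per restart.
#' @return An object of class `nnetts_model` with the fitted network,
#'   coefficients (`beta`, `gamma`), in-sample `fitted_values` and
#'   `residuals` (leading `m` entries `NA`), and a `training_log`.
#' @export
train_nnetts <- function(x, m, hidden, restarts = 20, seed = 20190411,
                         maxit = 500) {
  n <- length(x)
  if (any(!is.finite(x))) stop("series contains non-finite values",
                               call. = FALSE)
  stopifnot(m >= 1, hidden >= 1, restarts >= 1)
  if (n <= m + hidden) {
    stop("series too short (", n, ") for m = ", m, " lags and ", hidden,
         " hidden units", call. = FALSE)
  }
  if (is_constant(x)) {
    mod <- constant_model(x, "NNETTS")
    mod$m <- m; mod$hidden <- hidden
    mod$training_log <- list(seed = seed, restarts = 0, loss = 0)
    class(mod) <- "nnetts_model"
    return(mod)
  }
  mu <- mean(x)
  sdev <- stats::sd(x)
  xs <- (x - mu) / sdev
  E <- stats::embed(xs, m + 1)
  y <- E[, 1]
  X <- E[, -1, drop = FALSE]     # columns: lag 1 .. lag m
  best <- NULL
  losses <- numeric(restarts)
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1)
    fit <- nnet::nnet(X, y, size = hidden, linout = TRUE, trace = FALSE,
                      maxit = maxit, rang = 0.5)
    losses[r] <- fit$value
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  fitted_s <- as.numeric(best$fitted.values)
  fitted_full <- c(rep(NA_real_, m), fitted_s * sdev + mu)
  # unpack weights: per hidden unit (bias, m input weights), then output
  # (bias, hidden weights) -- nnet's storage order
  wts <- best$wts
  gamma <- matrix(wts[seq_len(hidden * (m + 1))], nrow = m + 1)
  beta <- wts[hidden * (m + 1) + seq_len(hidden + 1)]
  mod <- list(family = "NNETTS", m = m, hidden = hidden,
              net = best, gamma = gamma, beta = beta,
              mu = mu, sd = sdev, state = rev(utils::tail(xs, m)),
              fitted_values = fitted_full, residuals = x - fitted_full,
              training_log = list(seed = seed, restarts = restarts,
                                  loss = best$value, losses = losses))
  class(mod) <- "nnetts_model"
  mod
}

#' Forecast from a trained neural autoregression
#'
#' Produces k-step-ahead forecasts by iterating the one-step map on its own
#' outputs (recursive strategy).
#'
#' @param model A `nnetts_model` from [train_nnetts()].
#' @param k Forecast horizon (>= 0).
#' @return Numeric vector of length `k`.
#' @export
predict_nnetts <- function(model, k) {
  stopifnot(inherits(model, "nnetts_model"), k >= 0)
  if (k == 0) return(numeric(0))
  if (isTRUE(model$constant)) return(rep(model$value, k))
  state <- model$state            # lag 1 .. lag m (standardised)
  out <- numeric(k)
  for (i in seq_len(k)) {
    nxt <- as.numeric(stats::predict(model$net,
                                     matrix(state, nrow = 1)))
    out[i] <- nxt
    state <- c(nxt, state)[seq_along(state)]
  }
  out * model$sd + model$mu
}

#' Fit and forecast a univariate backend
#'
#' Dispatches to ARIMA, ETS or NNETTS on a single unconstrained coordinate
#' series and returns the fitted model together with its k-step-ahead point
#' forecasts. All backends are deterministic functions of
#' `(series, config)`.
#'
#' @param x Numeric series.
#' @param config A `model_config` with family ARIMA, ETS or NNETTS.
#' @param k Forecast horizon (>= 1; 0 returns the fitted model only).
#' @return List with `model` and `forecast` (length `k`).
#' @export
fit_forecast_univariate <- function(x, config, k) {
  stopifnot(inherits(config, "model_config"))
  if (any(!is.finite(x))) stop("series contains non-finite values",
                               call. = FALSE)
  fam <- config$family
  if (fam %in% c("ARIMA", "ETS") && length(x) < 10) {
    stop(fam, " needs at least 10 observations, got ", length(x),
         call. = FALSE)
  }
  switch(fam,
    ARIMA = fit_arima(x, k, config$arima_order),
    ETS = fit_ets(x, k, config$ets_form),
    NNETTS = {
      if (length(x) < config$m + 5) {
        stop("NNETTS needs at least m + 5 = ", config$m + 5,
             " observations, got ", length(x), call. = FALSE)
      }
      mod <- train_nnetts(x, config$m, config$hidden, config$restarts,
                          config$seed)
      list(model = mod, forecast = predict_nnetts(mod, k))
    },
    stop("fit_forecast_univariate does not handle family ", fam,
         call. = FALSE)
  )
}

# ---- VAR ------------------------------------------------------------------

#' Fit and forecast a vector autoregression
#'
#' Least-squares VAR with intercept on a multivariate series; the lag order
#' is chosen by AIC up to `config$var_max_lag`. Forecasts are dynamic
#' (iterated) k-step-ahead predictions for all variables jointly.
#'
#' If every column is constant the constants are returned as forecasts
#' without fitting; a constant column alongside varying ones makes the
#' design singular and raises an error naming the column.
#'
#' @param Y Numeric matrix, one column per variable (>= 2 columns).
#' @param config A `model_config` with family `"VAR"`.
#' @param k Forecast horizon (0 allowed: fitted model only).
#' @return List with `model` (coefficients, lag order, fitted values and
#'   residuals aligned to `Y` with leading `NA` rows) and `forecast`
#'   (k x ncol(Y) matrix).
#' @export
fit_forecast_var <- function(Y, config, k) {
  stopifnot(inherits(config, "model_config"), config$family == "VAR")
  Y <- as.matrix(Y)
  n <- nrow(Y); K <- ncol(Y)
  if (K < 2) stop("VAR needs at least 2 variables", call. = FALSE)
  if (any(!is.finite(Y))) stop("series contains non-finite values",
                               call. = FALSE)
  const_col <- apply(Y, 2, stats::sd) < 1e-10
  if (all(const_col)) {
    mod <- list(family = "VAR", constant = TRUE, p = 0,
                fitted_values = Y, residuals = Y * 0)
    fc <- matrix(rep(Y[n, ], each = k), nrow = k,
                 dimnames = list(NULL, colnames(Y)))
    return(list(model = mod, forecast = fc))
  }
  if (any(const_col)) {
    nm <- colnames(Y)[const_col][1]
    if (is.null(nm)) nm <- paste0("column ", which(const_col)[1])
    stop("VAR design is singular: constant series in ", nm, call. = FALSE)
  }
  pmax_feasible <- max(1, floor((n - 2) / (K + 1)) - 1)
  pmax <- min(config$var_max_lag, pmax_feasible)
  if (n < pmax + K * pmax + 2) pmax <- 1
  best <- NULL
  best_aic <- Inf
  for (p in seq_len(pmax)) {
    neff <- n - p
    Z <- cbind(1, do.call(cbind, lapply(seq_len(p), function(l) {
      Y[(p - l + 1):(n - l), , drop = FALSE]
    })))
    Yr <- Y[(p + 1):n, , drop = FALSE]
    qrz <- qr(Z)
    B <- qr.coef(qrz, Yr)
    # exactly collinear regressors (e.g. raw unit-sum shares plus the
    # intercept) get NA coefficients from the pivoted QR; dropping them is
    # equivalent to fitting the reduced system
    B[is.na(B)] <- 0
    res <- Yr - Z %*% B
    Sigma <- crossprod(res) / neff
    # per-equation Gaussian criterion (product of equation variances);
    # unlike log det it stays usable when the residual covariance is
    # singular, as with jointly fitted unit-sum series
    aic <- sum(log(pmax(diag(Sigma), 1e-300))) +
      2 * (qrz$rank * K) / neff
    if (aic < best_aic - 1e-12) {
      best_aic <- aic
      best <- list(p = p, B = B, res = res, Z = Z)
    }
  }
  if (is.null(best)) stop("VAR fit failed for every candidate lag order",
                          call. = FALSE)
  p <- best$p
  fitted <- rbind(matrix(NA_real_, p, K), Y[(p + 1):n, ] - best$res)
  fc <- matrix(NA_real_, k, K, dimnames = list(NULL, colnames(Y)))
  hist <- Y
  for (i in seq_len(k)) {
    z <- c(1, as.vector(t(hist[nrow(hist) - seq_len(p) + 1, ,
                               drop = FALSE])))
    fc[i, ] <- z %*% best$B
    hist <- rbind(hist, fc[i, ])
  }
  mod <- list(family = "VAR", p = p, coefficients = best$B, aic = best_aic,
              fitted_values = fitted, residuals = Y - fitted)
  list(model = mod, forecast = fc)
}
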