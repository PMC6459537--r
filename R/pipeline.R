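TRANSFORMS <- c("ILR", "DRHT", "LCC.Y", "LCC.M", "LCC.O", "Base")
FAMILIES <- c("ARIMA", "ETS", "VAR", "NNETTS")

#' Split a compositional series into training and test windows
#'
#' Partitions by calendar year: training years are `<= train_end_year`,
#' test years follow. The boundary is a year rather than an index, so a
#' series with missing years fails loudly instead of silently shifting the
#' split.
#'
#' @param series A `coda_series`.
#' @param train_end_year Last year of the training window; must leave both
#'   windows non-empty.
#' @return List of class `coda_split` with `train` and `test`
#'   (`coda_series`) and `train_end_year`.
#' @export
split_series <- function(series, train_end_year) {
  stopifnot(inherits(series, "coda_series"))
  idx_train <- which(series$years <= train_end_year)
  idx_test <- which(series$years > train_end_year)
  if (length(idx_train) == 0) {
    stop("empty training window: no years <= ", train_end_year,
         call. = FALSE)
  }
  if (length(idx_test) == 0) {
    stop("empty test window: no years > ", train_end_year, call. = FALSE)
  }
  structure(list(train = subset_series(series, idx_train),
                 test = subset_series(series, idx_test),
                 train_end_year = as.integer(train_end_year)),
            class = "coda_split")
}

# forward transform of a whole series -> unconstrained coordinate matrix
coords_forward <- function(series, transform, epsilon = 1e-6) {
  stopifnot(inherits(series, "coda_series"))
  transform <- match.arg(transform, TRANSFORMS)
  P <- series$parts
  D <- ncol(P)
  if (transform == "ILR") {
    co <- t(apply(P, 1, ilr_forward, epsilon = epsilon))
    colnames(co) <- paste0("w", seq_len(D - 1))
  } else if (transform == "DRHT") {
    co <- t(apply(P, 1, drht_forward))
    colnames(co) <- paste0("theta", 2:D)
  } else if (transform == "Base") {
    co <- P
  } else {
    j <- match(transform, c("LCC.Y", "LCC.M", "LCC.O"))
    if (j > D) stop("transform ", transform, " needs at least ", j,
                    " components", call. = FALSE)
    co <- P[, -j, drop = FALSE]
    attr(co, "dropped_index") <- j
  }
  co
}

# back-transform a matrix of forecast coordinates to composition rows
coords_backward <- function(fc, transform, epsilon = 1e-6) {
  transform <- match.arg(transform, TRANSFORMS)
  n <- nrow(fc)
  n_clamped <- 0L
  if (transform == "ILR") {
    parts <- t(apply(fc, 1, ilr_inverse))
    valid <- rep(TRUE, n)
  } else if (transform == "DRHT") {
    lo <- fc < 0
    hi <- fc > pi / 2
    n_clamped <- sum(lo | hi)
    if (n_clamped > 0) {
      warning("clamped ", n_clamped, " forecasted angle(s) to [0, pi/2]",
              call. = FALSE)
      fc[lo] <- 0
      fc[hi] <- pi / 2
    }
    parts <- t(apply(fc, 1, drht_inverse))
    valid <- rep(TRUE, n)
  } else if (transform == "Base") {
    valid <- apply(fc, 1, function(r) all(r >= 0 & r <= 1))
    parts <- fc
    for (i in which(valid)) parts[i, ] <- parts[i, ] / sum(parts[i, ])
  } else {
    j <- attr(fc, "dropped_index")
    if (is.null(j)) j <- match(transform, c("LCC.Y", "LCC.M", "LCC.O"))
    parts <- matrix(NA_real_, n, ncol(fc) + 1)
    valid <- logical(n)
    for (i in seq_len(n)) {
      cc <- lcc_complete(fc[i, ], j)
      parts[i, ] <- cc$parts
      valid[i] <- cc$valid
    }
  }
  list(parts = parts, valid = valid, n_clamped = n_clamped)
}

#' Forecast a compositional series through a transform-model pair
#'
#' The three-step procedure: (1) map the training compositions to
#' unconstrained coordinates with the chosen transform, (2) forecast each
#' coordinate k steps ahead (univariate backends per coordinate; VAR
#' jointly on all coordinates), (3) back-transform the forecasts to
#' compositions. `"Base"` fits each raw component share directly and
#' re-closes the forecasts. ILR and DRHT forecasts always satisfy the
#' unit-sum constraint; LCC (and out-of-range Base) rows are flagged
#' invalid rather than repaired, preserving the raw values.
#'
#' @param train A `coda_series` (the training window, or a full series when
#'   forecasting the future).
#' @param transform One of `"ILR"`, `"DRHT"`, `"LCC.Y"`, `"LCC.M"`,
#'   `"LCC.O"`, `"Base"`. Component order is fixed as
#'   young/middle/old = 1/2/3; `LCC.Y` drops component 1, etc.
#' @param config A [model_config()].
#' @param k Forecast horizon in years (>= 1).
#' @param epsilon Zero-replacement value for log-ratio transforms.
#' @return Object of class `coda_forecast`: `years`, `parts` (k rows),
#'   `valid` flags, `transform`, `model`, `horizon`, `config`, fitted
#'   per-coordinate `models`, and `n_clamped`.
#' @export
forecast_composition <- function(train, transform, config, k,
                                 epsilon = 1e-6) {
  stopifnot(inherits(train, "coda_series"),
            inherits(config, "model_config"), k >= 1)
  transform <- match.arg(transform, TRANSFORMS)
  co <- coords_forward(train, transform, epsilon)
  if (config$family == "VAR") {
    vr <- tryCatch(fit_forecast_var(co, config, k), error = function(e) {
      stop("backend VAR failed on ", transform, " coordinates: ",
           conditionMessage(e), call. = FALSE)
    })
    models <- list(vr$model)
    fc <- vr$forecast
  } else {
    models <- vector("list", ncol(co))
    fc <- matrix(NA_real_, k, ncol(co))
    for (j in seq_len(ncol(co))) {
      r <- tryCatch(fit_forecast_univariate(co[, j], config, k),
                    error = function(e) {
        stop("backend ", config$family, " failed on ", transform,
             " coordinate ", j, ": ", conditionMessage(e), call. = FALSE)
      })
      models[[j]] <- r$model
      fc[, j] <- r$forecast
    }
    colnames(fc) <- colnames(co)
  }
  attr(fc, "dropped_index") <- attr(co, "dropped_index")
  back <- coords_backward(fc, transform, epsilon)
  colnames(back$parts) <- train$labels
  ny <- train$years[length(train$years)]
  structure(list(years = ny + seq_len(k), parts = back$parts,
                 valid = back$valid, transform = transform,
                 model = config$family, horizon = k, config = config,
                 models = models, n_clamped = back$n_clamped,
                 labels = train$labels),
            class = "coda_forecast")
}

#' @export
print.coda_forecast <- function(x, ...) {
  cat("<coda_forecast> ", x$transform, " + ", x$model, ", horizon ",
      x$horizon, " (", x$years[1], "-", x$years[length(x$years)], ")\n",
      sep = "")
  if (!all(x$valid)) {
    cat("  ", sum(!x$valid), " row(s) outside the simplex (flagged)\n",
        sep = "")
  }
  df <- data.frame(year = x$years, round(x$parts * 100, 2))
  print(utils::head(df, 6), row.names = FALSE)
  if (x$horizon > 6) cat("  ...\n")
  invisible(x)
}

#' Evaluate a transform-by-model grid out of sample
#'
#' Splits the series at `train_end_year`, forecasts the test window with
#' every requested transform-model combination and scores each cell with
#' CoDa-RMSE / CoDa-MAPE. Rows flagged invalid (LCC complements outside
#' the unit interval, negative raw-scale forecasts) are repaired for metric
#' computation by clipping to `[epsilon, 1]` and re-closing, with the
#' repair count recorded in the report. Cell-level failures are recorded,
#' not raised.
#'
#' @param series A `coda_series`.
#' @param train_end_year Split boundary (see [split_series()]).
#' @param transforms Character vector of transforms to run.
#' @param models Character vector of families, or a named list of
#'   [model_config()] objects keyed by family.
#' @param seed Seed used for configs built from family names.
#' @param nnetts_m,nnetts_hidden Lag and hidden-unit counts used when an
#'   NNETTS config is built from the family name.
#' @param epsilon Zero-replacement value.
#' @return Object of class `coda_evaluation` with an `entries` data frame
#'   (`transform`, `model`, `coda_rmse`, `coda_mape`, `n_invalid`,
#'   `n_clamped`, `error`), the split description and the configs used.
#' @export
evaluate_grid <- function(series, train_end_year, transforms = TRANSFORMS,
                          models = FAMILIES, seed = 20190411,
                          nnetts_m = 1, nnetts_hidden = 1,
                          epsilon = 1e-6) {
  sp <- split_series(series, train_end_year)
  k <- length(sp$test$years)
  if (is.character(models)) {
    fams <- match.arg(models, FAMILIES, several.ok = TRUE)
    configs <- lapply(fams, function(f) {
      model_config(f, seed = seed, m = nnetts_m, hidden = nnetts_hidden)
    })
    names(configs) <- fams
  } else {
    configs <- models
    stopifnot(all(vapply(configs, inherits, TRUE, "model_config")))
    if (is.null(names(configs))) {
      names(configs) <- vapply(configs, `[[`, "", "family")
    }
  }
  transforms <- match.arg(transforms, TRANSFORMS, several.ok = TRUE)
  rows <- list()
  for (tr in transforms) {
    for (fam in names(configs)) {
      cell <- tryCatch({
        fr <- suppressWarnings(
          forecast_composition(sp$train, tr, configs[[fam]], k, epsilon))
        pm <- fr$parts
        for (i in which(!fr$valid)) {
          pm[i, ] <- repair_composition(pm[i, ], epsilon)
        }
        pred <- coda_series(fr$years, pm, labels = series$labels)
        met <- coda_errors(sp$test, pred, epsilon)
        data.frame(transform = tr, model = fam,
                   coda_rmse = met$coda_rmse, coda_mape = met$coda_mape,
                   n_invalid = sum(!fr$valid), n_clamped = fr$n_clamped,
                   error = NA_character_, stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(transform = tr, model = fam, coda_rmse = NA_real_,
                   coda_mape = NA_real_, n_invalid = NA_integer_,
                   n_clamped = NA_integer_, error = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1]] <- cell
    }
  }
  structure(list(entries = do.call(rbind, rows),
                 split = list(train_end_year = sp$train_end_year,
                              n_train = length(sp$train$years),
                              n_test = k),
                 configs = configs, seed = seed),
            class = "coda_evaluation")
}

#' @export
print.coda_evaluation <- function(x, ...) {
  cat("<coda_evaluation> ", x$split$n_train, " training / ",
      x$split$n_test, " test years (boundary ", x$split$train_end_year,
      ")\n", sep = "")
  e <- x$entries
  e$coda_rmse <- round(e$coda_rmse, 4)
  e$coda_mape <- round(e$coda_mape, 2)
  print(e, row.names = FALSE)
  invisible(x)
}

#' Select the best transform-model combination
#'
#' Lexicographic argmin over the successful cells of an evaluation report:
#' lowest CoDa-RMSE first, CoDa-MAPE as tie-break, then the fixed transform
#' order ILR < DRHT < LCC.Y < LCC.M < LCC.O < Base and model order
#' ARIMA < ETS < VAR < NNETTS. Transform or model families can be excluded,
#' e.g. to restrict the choice to transforms whose forecasts are guaranteed
#' to stay on the simplex.
#'
#' @param report A `coda_evaluation`.
#' @param exclude_transforms,exclude_models Optional character vectors of
#'   grid rows/columns to ignore.
#' @return List with `transform`, `model`, `coda_rmse`, `coda_mape`.
#' @export
select_best <- function(report, exclude_transforms = NULL,
                        exclude_models = NULL) {
  stopifnot(inherits(report, "coda_evaluation"))
  e <- report$entries
  failed <- if (is.null(e$error)) rep(FALSE, nrow(e)) else !is.na(e$error)
  e <- e[!failed & is.finite(e$coda_rmse), , drop = FALSE]
  if (!is.null(exclude_transforms)) {
    e <- e[!(e$transform %in% exclude_transforms), , drop = FALSE]
  }
  if (!is.null(exclude_models)) {
    e <- e[!(e$model %in% exclude_models), , drop = FALSE]
  }
  if (nrow(e) == 0) {
    stop("no successful grid cell to select from", call. = FALSE)
  }
  t_rank <- c(ILR = 1, DRHT = 2, LCC.Y = 3, LCC.M = 4, LCC.O = 5, Base = 6)
  m_rank <- c(ARIMA = 1, ETS = 2, VAR = 3, NNETTS = 4)
  ord <- order(e$coda_rmse, e$coda_mape, t_rank[e$transform],
               m_rank[e$model])
  best <- e[ord[1], ]
  list(transform = best$transform, model = best$model,
       coda_rmse = best$coda_rmse, coda_mape = best$coda_mape)
}

#' Portmanteau white-noise tests on a residual series
#'
#' Box-Pierce and Ljung-Box statistics on the first `lags` residual
#' autocorrelations, with chi-square p-values on `lags` degrees of freedom.
#' A p-value above the significance level (conventionally 0.05) is
#' consistent with white-noise residuals, i.e. the model has extracted the
#' serial structure.
#'
#' @param residuals Numeric residual series (leading `NA`s are dropped).
#' @param lags Number of autocorrelation lags `h`.
#' @return List with `bp_stat`, `bp_p`, `lb_stat`, `lb_p`, `lags`, `n`.
#' @export
residual_white_noise <- function(residuals, lags) {
  res <- residuals[!is.na(residuals)]
  n <- length(res)
  stopifnot(lags >= 1)
  if (n < lags + 1) {
    stop("need more than ", lags, " residuals, got ", n, call. = FALSE)
  }
  if (stats::sd(res) < 1e-12) {
    stop("residual series is constant; white-noise tests are undefined",
         call. = FALSE)
  }
  bp <- stats::Box.test(res, lag = lags, type = "Box-Pierce")
  lb <- stats::Box.test(res, lag = lags, type = "Ljung-Box")
  list(bp_stat = unname(bp$statistic), bp_p = unname(bp$p.value),
       lb_stat = unname(lb$statistic), lb_p = unname(lb$p.value),
       lags = lags, n = n)
}

#' Residual diagnostics on the original proportion scale
#'
#' Fits the transform-model pair on the whole series, back-transforms the
#' in-sample fitted coordinate values to compositions, and runs the
#' portmanteau tests of [residual_white_noise()] on the per-component
#' residuals (observed minus fitted share).
#'
#' @param series A `coda_series`.
#' @param transform,config As in [forecast_composition()].
#' @param lags Autocorrelation lags; default `min(10, floor(n/5))` where n
#'   is the usable residual length.
#' @param epsilon Zero-replacement value.
#' @return Data frame with one row per component: test statistics,
#'   p-values, `lags` and `n`.
#' @export
residual_diagnostics <- function(series, transform, config, lags = NULL,
                                 epsilon = 1e-6) {
  stopifnot(inherits(series, "coda_series"))
  transform <- match.arg(transform, TRANSFORMS)
  co <- coords_forward(series, transform, epsilon)
  if (config$family == "VAR") {
    vr <- fit_forecast_var(co, config, 1)
    fitted_co <- vr$model$fitted_values
  } else {
    fitted_co <- matrix(NA_real_, nrow(co), ncol(co))
    for (j in seq_len(ncol(co))) {
      r <- fit_forecast_univariate(co[, j], config, 1)
      fitted_co[, j] <- r$model$fitted_values
    }
  }
  ok <- stats::complete.cases(fitted_co)
  attr(fitted_co, "dropped_index") <- attr(co, "dropped_index")
  back <- coords_backward(fitted_co[ok, , drop = FALSE], transform, epsilon)
  fitted_parts <- back$parts
  obs <- series$parts[ok, , drop = FALSE]
  resid <- obs - fitted_parts
  n_res <- nrow(resid)
  if (is.null(lags)) lags <- max(1, min(10, floor(n_res / 5)))
  out <- lapply(seq_len(ncol(resid)), function(d) {
    tst <- residual_white_noise(resid[, d], lags)
    data.frame(component = series$labels[d], transform = transform,
               model = config$family, bp_stat = tst$bp_stat,
               bp_p = tst$bp_p, lb_stat = tst$lb_stat, lb_p = tst$lb_p,
               lags = tst$lags, n = tst$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Forecast the future age structure
#'
#' Refits the chosen transform-model pair on the full observed series and
#' returns composition forecasts for the years following the last
#' observation (default horizon 18).
#'
#' @param series A `coda_series` (all observed years).
#' @param transform,config As in [forecast_composition()].
#' @param horizon Number of future years (>= 1).
#' @param epsilon Zero-replacement value.
#' @return A `coda_forecast`.
#' @export
forecast_future <- function(series, transform, config, horizon = 18,
                            epsilon = 1e-6) {
  stopifnot(horizon >= 1)
  forecast_composition(series, transform, config, horizon, epsilon)
}

#' Tune the neural autoregression over a lag-by-hidden-unit grid
#'
#' Mirrors the grid search used to pick the NNETTS settings before the
#' main model comparison: every `(m, hidden)` pair is scored out of sample
#' (CoDa-RMSE / CoDa-MAPE) for each requested transform, and the pair with
#' the lowest best-over-transforms CoDa-RMSE is returned (ties broken by
#' smaller m, then fewer hidden units).
#'
#' @param series A `coda_series`.
#' @param train_end_year Split boundary.
#' @param m_values,hidden_values Candidate lag counts and hidden-unit
#'   counts.
#' @param transforms Transforms to score each pair on.
#' @param restarts,seed Training settings (see [train_nnetts()]).
#' @param epsilon Zero-replacement value.
#' @return List with `m`, `hidden` (the selected pair) and `grid` (a data
#'   frame of all `(m, hidden, transform)` scores).
#' @export
nnetts_select <- function(series, train_end_year, m_values = 1:3,
                          hidden_values = 1:5,
                          transforms = c("LCC.Y", "LCC.M", "LCC.O",
                                         "ILR", "DRHT"),
                          restarts = 20, seed = 20190411, epsilon = 1e-6) {
  rows <- list()
  for (m in m_values) {
    for (h in hidden_values) {
      ev <- evaluate_grid(series, train_end_year, transforms = transforms,
                          models = list(NNETTS = model_config(
                            "NNETTS", m = m, hidden = h,
                            restarts = restarts, seed = seed)),
                          epsilon = epsilon)
      e <- ev$entries
      e$m <- m
      e$hidden <- h
      rows[[length(rows) + 1]] <- e
    }
  }
  grid <- do.call(rbind, rows)
  ok <- grid[is.na(grid$error), , drop = FALSE]
  if (nrow(ok) == 0) stop("every NNETTS grid cell failed", call. = FALSE)
  best_per_pair <- stats::aggregate(coda_rmse ~ m + hidden, data = ok, min)
  ord <- order(best_per_pair$coda_rmse, best_per_pair$m,
               best_per_pair$hidden)
  list(m = best_per_pair$m[ord[1]], hidden = best_per_pair$hidden[ord[1]],
       grid = grid)
}
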