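test_that("all univariate families extrapolate a constant series", {
  cc <- rep(3.7, 30)
  for (fam in c("ARIMA", "ETS")) {
    r <- fit_forecast_univariate(cc, model_config(fam), 5)
    expect_equal(r$forecast, rep(3.7, 5), tolerance = 1e-6)
  }
  r <- fit_forecast_univariate(cc, model_config("NNETTS", m = 2,
                                                hidden = 2), 5)
  expect_lt(max(abs(r$forecast - 3.7)), 0.05 * 3.7 + 0.01)
})

test_that("automatic ARIMA recovers a deterministic linear trend", {
  x <- 2 + 0.5 * (1:40)
  r <- fit_forecast_univariate(x, model_config("ARIMA"), 3)
  expect_lt(max(abs(r$forecast / c(22.5, 23.0, 23.5) - 1)), 0.05)
})

test_that("ETS with trend continues a linear series", {
  x <- 2 + 0.5 * (1:40)
  r <- fit_forecast_univariate(x, model_config("ETS"), 3)
  expect_equal(r$forecast, c(22.5, 23.0, 23.5), tolerance = 1e-4)
  expect_identical(r$model$form, "holt")
})

test_that("ARIMA/ETS forecasts of white noise stay near the mean", {
  set.seed(301)
  x <- stats::rnorm(200, mean = 5, sd = 1)
  se <- 1 / sqrt(200)
  for (fam in c("ARIMA", "ETS")) {
    r <- fit_forecast_univariate(x, model_config(fam), 5)
    expect_lt(max(abs(r$forecast - mean(x))), 3 * 1)  # within 3 sd
    expect_lt(abs(mean(r$forecast) - mean(x)), 10 * se)
  }
})

test_that("short or non-finite series are rejected", {
  expect_error(fit_forecast_univariate(1:5, model_config("ARIMA"), 2),
               "at least 10")
  expect_error(fit_forecast_univariate(c(1:20, NA), model_config("ETS"),
                                       2), "non-finite")
  expect_error(fit_forecast_univariate(1:6, model_config("NNETTS", m = 3),
                                       2), "m \\+ 5")
})

test_that("NNETTS training is deterministic and improves with restarts", {
  set.seed(302)
  x <- as.numeric(arima.sim(list(ar = 0.7), 80)) + 10
  m1 <- train_nnetts(x, m = 2, hidden = 2, restarts = 5, seed = 11)
  m2 <- train_nnetts(x, m = 2, hidden = 2, restarts = 5, seed = 11)
  expect_identical(predict_nnetts(m1, 6), predict_nnetts(m2, 6))
  r1 <- train_nnetts(x, m = 2, hidden = 2, restarts = 1, seed = 11)
  r20 <- train_nnetts(x, m = 2, hidden = 2, restarts = 20, seed = 11)
  expect_lte(r20$training_log$loss, r1$training_log$loss)
  # best-of loss is the minimum over the per-restart losses
  expect_equal(r20$training_log$loss, min(r20$training_log$losses))
  # provenance: seed recorded, different seed recorded faithfully
  m3 <- train_nnetts(x, m = 2, hidden = 2, restarts = 5, seed = 12)
  expect_identical(m3$training_log$seed, 12)
  expect_identical(m1$training_log$seed, 11)
})

test_that("NNETTS fits a series generated by its own model class", {
  g <- function(z) 1 / (1 + exp(-z))
  x <- numeric(200)
  x[1:2] <- c(0.1, -0.2)
  for (t in 3:200) {
    x[t] <- 0.3 + 0.8 * g(0.5 + 1.2 * x[t - 1] - 0.7 * x[t - 2])
  }
  m <- train_nnetts(x, m = 2, hidden = 1, restarts = 10, seed = 5)
  expect_lt(sqrt(mean(m$residuals^2, na.rm = TRUE)), 1e-3)
  # extracted coefficients reproduce the network output
  st <- m$state
  manual <- m$beta[1] +
    sum(m$beta[-1] * g(m$gamma[1, ] + colSums(m$gamma[-1, , drop = FALSE] *
                                                st)))
  expect_equal(predict_nnetts(m, 1), manual * m$sd + m$mu,
               tolerance = 1e-10)
})

test_that("VAR recovers known coefficients and honours its contracts", {
  set.seed(303)
  n <- 500
  A <- matrix(c(0.5, 0.0, 0.1, 0.4), 2)   # row-wise [[0.5, 0.1], [0, 0.4]]
  Y <- matrix(0, n, 2)
  for (t in 2:n) Y[t, ] <- A %*% Y[t - 1, ] + stats::rnorm(2, 0, 0.1)
  r <- fit_forecast_var(Y, model_config("VAR"), 3)
  est <- t(r$model$coefficients[2:3, ])    # lag-1 block, equation by row
  expect_lt(max(abs(est - A)), 0.1)
  # constant system: forecasts equal the constants
  Yc <- cbind(rep(2, 40), rep(5, 40))
  rc <- fit_forecast_var(Yc, model_config("VAR"), 4)
  expect_equal(unname(rc$forecast), cbind(rep(2, 4), rep(5, 4)))
  # one constant column among varying ones: singular design, named
  Ym <- cbind(stats::rnorm(40), rep(1, 40))
  colnames(Ym) <- c("a", "b")
  expect_error(fit_forecast_var(Ym, model_config("VAR"), 2), "b")
  # k = 0: fitted model only
  r0 <- fit_forecast_var(Y, model_config("VAR"), 0)
  expect_equal(nrow(r0$forecast), 0)
  expect_false(is.null(r0$model$coefficients))
})

test_that("VAR estimation error shrinks with sample size", {
  A <- matrix(c(0.5, 0.0, 0.1, 0.4), 2)
  rmse_at <- function(n, seed) {
    set.seed(seed)
    Y <- matrix(0, n, 2)
    for (t in 2:n) Y[t, ] <- A %*% Y[t - 1, ] + stats::rnorm(2, 0, 0.1)
    r <- fit_forecast_var(Y, model_config("VAR", var_max_lag = 1), 1)
    sqrt(mean((t(r$model$coefficients[2:3, ]) - A)^2))
  }
  small <- mean(vapply(1:5, function(s) rmse_at(100, s), numeric(1)))
  large <- mean(vapply(1:5, function(s) rmse_at(1000, s), numeric(1)))
  expect_lt(large, small)
})
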