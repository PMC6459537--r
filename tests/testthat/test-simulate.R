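test_that("noiseless simulation equals the analytic ILR path", {
  prm <- scenario_params(a = c(0.3, 1.2), b = c(-0.01, 0.02), sigma = 0,
                         n = 25, seed = 3)
  s <- simulate_coda_series(prm)
  truth <- t(vapply(1:25, function(t) ilr_inverse(prm$a + prm$b * t),
                    numeric(3)))
  expect_equal(unname(s$parts), truth, tolerance = 1e-12)
  # b = 0, sigma = 0: constant at ilr_inverse(a)
  flat <- simulate_coda_series(scenario_params(a = c(0.3, 1.2),
                                               b = c(0, 0), sigma = 0,
                                               n = 10, seed = 3))
  expect_true(all(abs(sweep(flat$parts, 2, ilr_inverse(c(0.3, 1.2)))) <
                    1e-12))
})

test_that("declared trend signs show up in the mean path", {
  prm <- scenario_params(a = c(0.3, 1.2), b = c(-0.01, 0.02), phi = 0.5,
                         sigma = 0.05, n = 57, seed = 9)
  mean_path <- codaf:::scenario_mean_path(prm)
  expect_true(all(diff(mean_path$parts[, 1]) < 0))   # first share falls
})

test_that("simulation is reproducible and strictly positive", {
  prm <- scenario_presets("china-like")
  s1 <- simulate_coda_series(prm)
  s2 <- simulate_coda_series(prm)
  expect_identical(s1, s2)
  expect_true(all(s1$parts > 0))
  expect_true(all(abs(rowSums(s1$parts) - 1) < 1e-9))
  s3 <- simulate_coda_series(scenario_presets("china-like", seed = 99))
  expect_false(identical(s1$parts, s3$parts))
})

test_that("presets reproduce their qualitative trend shapes", {
  ch <- codaf:::scenario_mean_path(scenario_presets("china-like"))
  n <- length(ch$years)
  expect_true(all(diff(ch$parts[(n - 20):n, "old"]) > 0))
  expect_true(all(diff(ch$parts[, "young"]) < 0))
  ind <- codaf:::scenario_mean_path(scenario_presets("india-like"))
  expect_true(all(diff(ind$parts[, "middle"]) > 0))
  vn <- codaf:::scenario_mean_path(scenario_presets("vietnam-like"))
  expect_gt(vn$parts[n, "old"], vn$parts[1, "old"])
  expect_error(scenario_presets("xyz"), "china-like")
})

test_that("parameter recovery is exact without noise and bounded with noise", {
  prm <- scenario_params(a = c(0.3, 1.2), b = c(-0.01, 0.02), sigma = 0,
                         n = 30, seed = 5)
  est <- recover_parameters(simulate_coda_series(prm))
  expect_equal(est$a_hat, prm$a, tolerance = 1e-8)
  expect_equal(est$b_hat, prm$b, tolerance = 1e-8)
  expect_lt(est$sigma_hat, 1e-8)

  short <- simulate_coda_series(scenario_params(a = c(0, 0), b = c(0, 0),
                                                sigma = 0.01, n = 5,
                                                seed = 5))
  expect_error(recover_parameters(short), "at least 10")
})

test_that("slope recovery error shrinks as the noise vanishes", {
  base <- scenario_presets("china-like")
  err_at <- function(sig) {
    prm <- scenario_params(a = base$a, b = base$b, phi = 0.5, sigma = sig,
                           n = 57, seed = 17)
    est <- recover_parameters(simulate_coda_series(prm))
    mean(abs(est$b_hat - base$b))
  }
  expect_lt(err_at(0.01), err_at(0.2))
})
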