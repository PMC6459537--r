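test_that("Aitchison distance matches the clr oracle and frozen values", {
  x <- c(0.5, 0.25, 0.25)
  y <- c(0.25, 0.25, 0.5)
  expect_equal(aitchison_distance(x, y), sqrt(2) * log(2),
               tolerance = 1e-12)
  expect_equal(aitchison_distance(x, y), 0.980258, tolerance = 1e-6)
  expect_equal(aitchison_distance(x, x), 0)
  expect_error(aitchison_distance(x, c(0.5, 0.5)), "different numbers")
  set.seed(201)
  for (i in 1:50) {
    a <- rand_comp(4)
    b <- rand_comp(4)
    expect_equal(aitchison_distance(a, b), oracle_dist(a, b),
                 tolerance = 1e-12)
    expect_equal(aitchison_distance(a, b), aitchison_distance(b, a))
  }
})

test_that("ILR is an isometry: coordinate distance equals Aitchison distance", {
  set.seed(202)
  worst <- 0
  for (i in 1:1000) {
    D <- sample(2:6, 1)
    a <- rand_comp(D)
    b <- rand_comp(D)
    d_coord <- sqrt(sum((ilr_forward(a) - ilr_forward(b))^2))
    worst <- max(worst, abs(aitchison_distance(a, b) - d_coord))
  }
  expect_lt(worst, 1e-10)
})

test_that("metric axioms and perturbation invariance hold", {
  set.seed(203)
  for (i in 1:100) {
    D <- sample(2:5, 1)
    x <- rand_comp(D); y <- rand_comp(D); z <- rand_comp(D)
    dxy <- aitchison_distance(x, y)
    expect_gte(dxy, 0)
    expect_lte(dxy, aitchison_distance(x, z) + aitchison_distance(z, y) +
                 1e-12)
    p <- rand_comp(D)   # perturbation: closure of the elementwise product
    expect_equal(aitchison_distance(closure(p * x), closure(p * y)), dxy,
                 tolerance = 1e-10)
  }
})

test_that("Aitchison norm equals the distance from the uniform composition", {
  expect_equal(coda_norm(c(1, 1, 1) / 3), 0)
  expect_equal(coda_norm(c(0.5, 0.25, 0.25)), sqrt(2) * log(2) / sqrt(3),
               tolerance = 1e-12)
  set.seed(204)
  for (i in 1:25) {
    D <- sample(2:6, 1)
    x <- rand_comp(D)
    expect_equal(coda_norm(x), aitchison_distance(x, rep(1 / D, D)),
                 tolerance = 1e-12)
  }
})

test_that("CoDa errors: perfect forecast, frozen single point, mean of distances", {
  obs <- coda_series(2001:2003, rbind(c(0.2, 0.5, 0.3), c(0.25, 0.5, 0.25),
                                      c(0.3, 0.45, 0.25)))
  expect_equal(coda_errors(obs, obs), list(coda_rmse = 0, coda_mape = 0))

  one <- coda_series(2001, matrix(c(0.5, 0.25, 0.25), 1))
  hat <- coda_series(2001, matrix(c(0.25, 0.25, 0.5), 1))
  e <- coda_errors(one, hat)
  expect_equal(e$coda_rmse, 0.980258, tolerance = 1e-6)
  expect_equal(e$coda_mape, sqrt(3) * 100, tolerance = 1e-6)
  expect_equal(e$coda_mape, 173.20, tolerance = 1e-4)

  # CoDa-RMSE is the plain mean of distances, not a root mean square
  two_obs <- coda_series(2001:2002, rbind(c(0.5, 0.25, 0.25),
                                          c(0.2, 0.5, 0.3)))
  two_hat <- coda_series(2001:2002, rbind(c(0.25, 0.25, 0.5),
                                          c(0.2, 0.5, 0.3)))
  d1 <- aitchison_distance(c(0.5, 0.25, 0.25), c(0.25, 0.25, 0.5))
  expect_equal(coda_errors(two_obs, two_hat)$coda_rmse, d1 / 2,
               tolerance = 1e-12)
  expect_equal(coda_errors(two_obs, two_hat,
                           root_mean_square = TRUE)$coda_rmse,
               sqrt(d1^2 / 2), tolerance = 1e-12)

  # uniform observation makes the MAPE undefined, named by year
  unif <- coda_series(2001, matrix(c(1, 1, 1) / 3, 1))
  expect_error(coda_errors(unif, hat), "2001")
  # misaligned years
  expect_error(coda_errors(one, coda_series(2002,
                                            matrix(c(0.3, 0.3, 0.4), 1))),
               "different years")
})
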