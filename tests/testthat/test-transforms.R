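test_that("ILR forward matches direct evaluation of the definition", {
  expect_equal(ilr_forward(c(1, 1, 1) / 3), c(0, 0))
  expect_equal(ilr_forward(c(0.5, 0.25, 0.25)),
               oracle_ilr(c(0.5, 0.25, 0.25)), tolerance = 1e-12)
  expect_equal(ilr_forward(c(0.5, 0.25, 0.25)), c(0.490129, 0.282976),
               tolerance = 1e-6)
  expect_equal(ilr_forward(c(0.8, 0.2)), sqrt(1 / 2) * log(4),
               tolerance = 1e-12)
  set.seed(101)
  for (i in 1:25) {
    x <- rand_comp(sample(2:6, 1))
    expect_equal(ilr_forward(x), oracle_ilr(x), tolerance = 1e-12)
  }
})

test_that("ILR inverse is exact: neutral element, frozen example, round trip", {
  expect_equal(ilr_inverse(c(0, 0)), c(1, 1, 1) / 3, tolerance = 1e-12)
  expect_equal(ilr_inverse(c(0.490129, 0.282976)), c(0.5, 0.25, 0.25),
               tolerance = 1e-6)
  expect_equal(ilr_inverse(0.980258), c(0.8, 0.2), tolerance = 1e-6)
  expect_error(ilr_inverse(c(1, NaN)), "finite")
  expect_error(ilr_forward(c(1, 0), epsilon = NULL), "strictly positive")
})

test_that("clr expansion of ILR coordinates sums to zero", {
  set.seed(102)
  for (i in 1:50) {
    w <- stats::rnorm(sample(1:5, 1), sd = 3)
    expect_lt(abs(sum(codaf:::clr_from_ilr(w))), 1e-9)
  }
})

test_that("DRHT angles match hand-computed values and stay in [0, pi/2]", {
  expect_equal(drht_forward(c(0.25, 0.25, 0.5)), c(pi / 4, pi / 4),
               tolerance = 1e-10)
  expect_equal(drht_forward(c(1, 1, 1) / 3),
               c(acos(1 / sqrt(2)), acos(1 / sqrt(3))), tolerance = 1e-10)
  expect_equal(drht_forward(c(0, 0, 1)), c(0, 0))
  set.seed(103)
  for (i in 1:25) {
    th <- drht_forward(rand_comp(sample(2:6, 1)))
    expect_true(all(th >= 0 & th <= pi / 2))
  }
})

test_that("DRHT inverse reconstructs compositions and handles boundaries", {
  expect_equal(drht_inverse(c(pi / 4, pi / 4)), c(0.25, 0.25, 0.5),
               tolerance = 1e-10)
  expect_equal(drht_inverse(c(0, 0)), c(0, 0, 1))
  expect_equal(drht_inverse(c(pi / 2, pi / 2)), c(1, 0, 0))
  expect_error(drht_inverse(c(2, 0.5)), "clip")
})

test_that("round trips are exact to 1e-10 across dimensions", {
  set.seed(104)
  worst_ilr <- worst_drht <- 0
  for (i in 1:1000) {
    x <- rand_comp(sample(2:6, 1))
    worst_ilr <- max(worst_ilr, max(abs(ilr_inverse(ilr_forward(x)) - x)))
    worst_drht <- max(worst_drht,
                      max(abs(drht_inverse(drht_forward(x)) - x)))
  }
  expect_lt(worst_ilr, 1e-10)
  expect_lt(worst_drht, 1e-10)
})

test_that("DRHT inverse output sums to one by construction", {
  set.seed(105)
  for (i in 1:50) {
    th <- stats::runif(sample(1:5, 1), 0, pi / 2)
    expect_lt(abs(sum(drht_inverse(th)) - 1), 1e-12)
  }
})

test_that("LCC completion inserts the complement and flags invalid rows", {
  r <- lcc_complete(c(0.2, 0.7), 3)
  expect_equal(r$parts, c(0.2, 0.7, 0.1))
  expect_true(r$valid)
  r <- lcc_complete(c(0.6, 0.5), 3)
  expect_equal(r$parts, c(0.6, 0.5, -0.1))
  expect_false(r$valid)
  r <- lcc_complete(c(0.25, 0.5), 1)
  expect_equal(r$parts, c(0.25, 0.25, 0.5))
  expect_true(r$valid)
  expect_error(lcc_complete(c(0.2, 0.3), 5), "dropped_index")
})
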