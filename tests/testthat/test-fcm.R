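test_that("two separated points with two clusters reach the fixed point", {
  x <- matrix(c(0, 10), ncol = 1)
  fit <- fuzzy_cmeans(x, c = 2, m = 2, seed = 1, restarts = 3)
  cen <- unname(sort(fit$centers[, 1]))
  expect_equal(cen, c(0, 10), tolerance = 1e-4)
  expect_true(all(apply(fit$membership, 1, max) > 0.999))
})

test_that("an equidistant point gets symmetric membership at m = 2", {
  x <- rbind(c(-1, 0), c(1, 0), c(0, 0), c(-1, 0.01), c(1, 0.01))
  fit <- fuzzy_cmeans(x, c = 2, m = 2, seed = 2, restarts = 5)
  expect_equal(unname(fit$membership[3, ]), c(0.5, 0.5), tolerance = 1e-3)
})

test_that("memberships are row-stochastic for every gene", {
  set.seed(9)
  for (rep in 1:5) {
    x <- matrix(rnorm(40 * 4), 40, 4)
    fit <- fuzzy_cmeans(x, c = 5, m = 1.7, seed = rep)
    expect_true(all(abs(rowSums(fit$membership) - 1) < 1e-9))
    expect_true(all(fit$membership >= 0 & fit$membership <= 1))
    expect_true(all(is.finite(fit$centers)))
  }
})

test_that("the objective is non-increasing across iterations", {
  set.seed(1)
  x <- matrix(rnorm(60 * 3), 60, 3)
  fit <- fuzzy_cmeans(x, c = 4, m = 2, seed = 3, restarts = 1)
  expect_true(all(diff(fit$objective_trace) <= 1e-10))
  # final reported objective agrees with a direct re-evaluation
  expect_equal(unname(fit$objective),
               unname(bf_fcm_objective(x, fit$centers, fit$membership, 2)),
               tolerance = 1e-10)
})

test_that("the implementation matches a brute-force oracle from the same start", {
  set.seed(5)
  for (rep in 1:4) {
    n <- sample(4:6, 1)
    x <- matrix(rnorm(n * 2), n, 2)
    cc <- sample(2:3, 1)
    u0 <- matrix(runif(n * cc), n, cc)
    u0 <- u0 / rowSums(u0)
    fit <- fuzzy_cmeans(x, c = cc, m = 2, init = u0, tol = 1e-12,
                        max_iter = 50)
    oracle <- bf_fcm(x, cc, 2, u0, tol = 1e-12, max_iter = 50)
    expect_equal(unname(fit$centers), unname(oracle$centers),
                 tolerance = 1e-10)
    expect_equal(unname(fit$membership), unname(oracle$membership),
                 tolerance = 1e-10)
  }
})

test_that("a point coincident with a center takes full membership there", {
  x <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  fit <- fuzzy_cmeans(x, c = 2, m = 2, seed = 1)
  expect_true(all(apply(fit$membership, 1, max) == 1))
})

test_that("clustering is deterministic in the seed", {
  x <- matrix(rnorm(30 * 4), 30, 4)
  a <- fuzzy_cmeans(x, c = 3, m = 1.8, seed = 7)
  b <- fuzzy_cmeans(x, c = 3, m = 1.8, seed = 7)
  expect_identical(a$membership, b$membership)
})

test_that("converged centers agree with an independent library on clean data", {
  skip_if_not_installed("e1071")
  set.seed(13)
  x <- rbind(matrix(rnorm(60, 0, 0.2), 30, 2),
             matrix(rnorm(60, 4, 0.2), 30, 2))
  ours <- fuzzy_cmeans(x, c = 2, m = 2, seed = 1)
  theirs <- e1071::cmeans(x, centers = 2, m = 2)
  match_order <- order(ours$centers[, 1])
  lib_order <- order(theirs$centers[, 1])
  expect_equal(unname(ours$centers[match_order, ]),
               unname(theirs$centers[lib_order, ]), tolerance = 1e-3)
})

test_that("the empirical fuzzifier estimate behaves as published", {
  x <- matrix(rnorm(1000 * 5), 1000, 5)
  expect_equal(estimate_fuzzifier(x), 2.074179, tolerance = 1e-5)
  # always > 1, and decreasing in the number of conditions at fixed N
  ms <- vapply(3:12, function(D)
    estimate_fuzzifier(matrix(0, 500, D)), numeric(1))
  expect_true(all(ms > 1))
  expect_true(all(diff(ms) < 0))
})
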