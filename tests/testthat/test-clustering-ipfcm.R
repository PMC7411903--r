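test_that("pcm_scales evaluates the weighted mean squared distance", {
  # constant distances factor out
  u <- matrix(runif(8), 4)
  d2 <- matrix(3, 4, 2)
  expect_equal(pcm_scales(u, d2, p = 2, W = 1), c(3, 3))
  # hand evaluation: (1 + 0.25*4)/(1 + 0.25) = 1.6
  expect_equal(pcm_scales(matrix(c(1, 0.5), 2), matrix(c(1, 4), 2), p = 2),
               1.6)
  # linear in W
  expect_equal(pcm_scales(u, d2, p = 2, W = 2), 2 * pcm_scales(u, d2, p = 2))
  expect_error(pcm_scales(matrix(0, 2, 1), matrix(1, 2, 1)), "zero membership")
})

test_that("pcm_typicality follows the corrected possibilistic update", {
  expect_equal(drop(pcm_typicality(matrix(2, 1, 1), 2, p = 3)), 0.5)
  expect_equal(drop(pcm_typicality(matrix(0, 1, 1), 5, p = 2)), 1)
  expect_equal(drop(pcm_typicality(matrix(4, 1, 1), 1, p = 2)), 0.2)
  expect_error(pcm_typicality(matrix(1, 1, 1), 1, p = 1), "p must be > 1")
  expect_error(pcm_typicality(matrix(1, 1, 1), -1, p = 2), "positive")
})

test_that("pcm_typicality matches 1-D grid minimization on random draws", {
  set.seed(7)
  for (rep in 1:40) {
    d2 <- rexp(1); lambda <- rexp(1) + 0.05; p <- runif(1, 1.3, 3.5)
    expect_lt(abs(drop(pcm_typicality(matrix(d2, 1, 1), lambda, p)) -
                    grid_typicality(d2, lambda, p)), 1e-3)
  }
})

test_that("sugeno_hesitation satisfies the intuitionistic identities", {
  u <- seq(0, 1, by = 0.05)
  h0 <- sugeno_hesitation(u, 0)
  expect_equal(h0$nu, 1 - u)
  expect_equal(h0$pi, rep(0, length(u)))
  h <- sugeno_hesitation(0.5, 2)
  expect_equal(h$nu, 0.25)
  expect_equal(h$pi, 0.25)
  expect_equal(sugeno_hesitation(0, 5)$nu, 1)
  expect_equal(sugeno_hesitation(1, 5)$nu, 0)
  expect_equal(sugeno_hesitation(1, 5)$pi, 0)
  expect_error(sugeno_hesitation(1.2, 1), "\\[0, 1\\]")
  expect_error(sugeno_hesitation(0.5, -1), ">= 0")
})

test_that("star_membership adds the hesitation degree", {
  expect_equal(star_membership(0, 0), 0)
  expect_equal(star_membership(1, 0), 1)
  h <- sugeno_hesitation(0.5, 2)
  expect_equal(star_membership(0.5, h$pi), 0.75)
  u <- runif(50)
  h <- sugeno_hesitation(u, 0)
  expect_identical(star_membership(u, h$pi), u)
})

test_that("ipfcm_objective evaluates the hybrid cost", {
  expect_equal(ipfcm_objective(matrix(1, 2, 1), matrix(0, 2, 1), 1, 2), 0)
  expect_equal(ipfcm_objective(matrix(0.5, 1, 1), matrix(1, 1, 1), 1, 2), 0.5)
})

test_that("fit_ifcm reduces to fit_fcm at sugeno_lambda = 0", {
  x <- two_blob_1d(21, n_per = 25)
  a <- fit_fcm(x, 2, seed = 4)
  b <- fit_ifcm(x, 2, sugeno_lambda = 0, seed = 4)
  expect_identical(a$memberships, b$memberships)
  expect_identical(a$centers, b$centers)
  expect_identical(a$objective_trace, b$objective_trace)
  expect_identical(a$iterations_run, b$iterations_run)
})

test_that("fit_ifcm stays near the FCM centers and does not renormalize", {
  x <- two_blob_1d(22, n_per = 30)
  f <- fit_fcm(x, 2, seed = 6)
  g <- fit_ifcm(x, 2, sugeno_lambda = 2, seed = 6)
  expect_lt(max(abs(sort(drop(g$centers)) - sort(drop(f$centers)))), 2e-2)
  expect_true(any(rowSums(g$memberships) > 1))  # star rows exceed one
})

test_that("fit_pfcm keeps blob centers and flags outliers by low typicality", {
  x <- c(0, 0.1, 0.2, 0.8, 0.9, 1.0)
  f <- fit_fcm(x, 2, seed = 2)
  p <- fit_pfcm(x, 2, seed = 2)
  expect_lt(max(abs(sort(drop(p$centers)) - sort(drop(f$centers)))), 1e-2)
  # outlier at 10x the data range scores low typicality in every cluster
  d2 <- squared_distances(10, p$centers)
  expect_true(all(pcm_typicality(d2, p$scales, 2) < 0.1))
  p2 <- fit_pfcm(x, 2, seed = 2)
  expect_identical(p$memberships, p2$memberships)
})

test_that("fit_ipfcm reduces to fit_pfcm at sugeno_lambda = 0", {
  x <- two_blob_1d(23, n_per = 20)
  a <- fit_pfcm(x, 2, seed = 8)
  b <- fit_ipfcm(x, 2, sugeno_lambda = 0, seed = 8)
  expect_identical(a$memberships, b$memberships)
  expect_identical(a$centers, b$centers)
  expect_identical(a$scales, b$scales)
  expect_identical(a$objective_trace, b$objective_trace)
})

test_that("fit_ipfcm honors its iteration contract", {
  x <- two_blob_1d(24, n_per = 15)
  f <- fit_ipfcm(x, 2, seed = 1, max_iter = 3)
  expect_lte(f$iterations_run, 3)
  g <- fit_ipfcm(x, 2, seed = 1, max_iter = 100)
  expect_true(g$converged)
  expect_lte(g$iterations_run, 100)
})
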