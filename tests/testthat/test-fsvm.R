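test_that("gaussian_kernel has unit diagonal, symmetry and scale", {
  expect_equal(gaussian_kernel(c(1, 2), c(1, 2), 1), 1)
  sigma <- 0.7
  y1 <- c(0, 0); y2 <- c(sigma * sqrt(2), 0)  # ||d||^2 = 2 sigma^2
  expect_equal(gaussian_kernel(y1, y2, sigma), exp(-1))
  set.seed(2)
  for (rep in 1:5) {
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(gaussian_kernel(a, b, 2), gaussian_kernel(b, a, 2))
  }
  expect_error(gaussian_kernel(1, 1, 0), "positive")
  expect_error(gaussian_kernel(c(1, 2), 1, 1), "dimension")
})

test_that("class_center_memberships decay linearly from the class mean", {
  X <- rbind(c(0, 0), c(2, 0), c(1, 1), c(5, 5), c(7, 5), c(6, 6))
  z <- c(-1, -1, -1, 1, 1, 1)
  s <- class_center_memberships(X, z)
  expect_true(all(s > 0 & s <= 1))
  # symmetric pair: equal weights
  X2 <- rbind(c(-1, 0), c(1, 0), c(4, 0), c(6, 0))
  s2 <- class_center_memberships(X2, c(-1, -1, 1, 1))
  expect_equal(s2[1], s2[2])
  expect_equal(s2[3], s2[4])
  # the farthest point's weight is ~delta/(r+delta)
  expect_lt(s2[1], 1e-4)
  # a point at its class mean gets weight 1 (single-point class)
  s3 <- class_center_memberships(rbind(c(0, 0), c(1, 1)), c(-1, 1))
  expect_equal(s3, c(1, 1))
})

test_that("two symmetric points give equal multipliers and a central boundary", {
  X <- matrix(c(-1, 1), ncol = 1)
  z <- c(-1, 1)
  m <- solve_fsvm_dual(X, z, c(1, 1), C = 100, sigma = 10)
  expect_equal(m$beta[1], m$beta[2], tolerance = 1e-8)
  expect_gt(m$beta[1], 0)
  expect_equal(decision_value(m, 0), 0, tolerance = 1e-9)
  expect_equal(sum(m$beta * z), 0, tolerance = 1e-8)
  # at a margin support vector the decision equals the label
  expect_equal(decision_value(m, 1), 1, tolerance = 1e-6)
})

test_that("duplicating the dataset leaves the decision function unchanged", {
  set.seed(6)
  X <- rbind(matrix(rnorm(12, -1), ncol = 2), matrix(rnorm(12, 1), ncol = 2))
  z <- rep(c(-1, 1), each = 6)
  m1 <- solve_fsvm_dual(X, z, rep(1, 12), C = 10, sigma = 1)
  m2 <- solve_fsvm_dual(rbind(X, X), c(z, z), rep(1, 24), C = 10, sigma = 1)
  probe <- matrix(rnorm(20), ncol = 2)
  expect_equal(decision_value(m1, probe), decision_value(m2, probe),
               tolerance = 1e-6)
})

test_that("degenerate label sets are rejected", {
  X <- matrix(rnorm(10), ncol = 2)
  expect_error(solve_fsvm_dual(X, rep(1, 5), rep(1, 5)), "both classes")
  expect_error(solve_fsvm_dual(X, c(1, 1, 1, 1, 2), rep(1, 5)), "\\{-1, \\+1\\}")
})

test_that("the decision function is invariant to sample ordering", {
  set.seed(10)
  X <- rbind(matrix(rnorm(14, -1.2), ncol = 2),
             matrix(rnorm(14, 1.2), ncol = 2))
  z <- rep(c(-1, 1), each = 7)
  s <- class_center_memberships(X, z)
  ord <- sample(nrow(X))
  m1 <- solve_fsvm_dual(X, z, s, C = 5, sigma = 1)
  m2 <- solve_fsvm_dual(X[ord, ], z[ord], s[ord], C = 5, sigma = 1)
  probe <- matrix(rnorm(10), ncol = 2)
  expect_equal(decision_value(m1, probe), decision_value(m2, probe),
               tolerance = 1e-6)
})

test_that("shrinking a fuzzy weight caps its multiplier", {
  set.seed(20)
  X <- rbind(matrix(rnorm(10, -1), ncol = 2), matrix(rnorm(10, 1), ncol = 2))
  z <- rep(c(-1, 1), each = 5)
  s <- rep(1, 10)
  m1 <- solve_fsvm_dual(X, z, s, C = 2, sigma = 1)
  target <- which.max(m1$beta)
  s2 <- s; s2[target] <- 0.2
  m2 <- solve_fsvm_dual(X, z, s2, C = 2, sigma = 1)
  expect_lte(m2$beta[target], 0.2 * 2 + 1e-10)
  expect_true(all(m2$beta <= s2 * 2 + 1e-10))
})

test_that("fit_predict separates blobs and weighting mutes outliers", {
  set.seed(5)
  n <- 15
  X <- rbind(matrix(rnorm(2 * n, -1.5, 0.5), ncol = 2),
             matrix(rnorm(2 * n, 1.5, 0.5), ncol = 2))
  z <- rep(c(-1, 1), each = n)
  fit <- fit_predict(X, z, X, C = 100, sigma = 1)
  expect_equal(fit$predictions, z)  # separable: training accuracy 1
  # far mislabeled outlier moves the boundary less with weighting on
  Xo <- rbind(X, c(-4, -4)); zo <- c(z, 1)
  probe <- as.matrix(expand.grid(seq(-3, 3, 0.5), seq(-3, 3, 0.5)))
  shift <- function(w) {
    f0 <- fit_predict(X, z, probe, weighting = w)
    f1 <- fit_predict(Xo, zo, probe, weighting = w)
    max(abs(f1$decision_values - f0$decision_values))
  }
  expect_lt(shift(TRUE), shift(FALSE))
})

test_that("fuzzy-SVM models survive a JSON round trip", {
  set.seed(30)
  X <- rbind(matrix(rnorm(8, -1), ncol = 2), matrix(rnorm(8, 1), ncol = 2))
  z <- rep(c(-1, 1), each = 4)
  m <- solve_fsvm_dual(X, z, rep(1, 8), C = 3, sigma = 1.5)
  path <- file.path(tempdir(), "model.json")
  fsvm_to_json(m, path)
  back <- fsvm_from_json(path)
  probe <- matrix(rnorm(6), ncol = 2)
  expect_equal(decision_value(back, probe), decision_value(m, probe),
               tolerance = 1e-12)
})
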