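#' Gaussian (RBF) kernel
#'
#' J(y1, y2) = exp(-||y1 - y2||^2 / (2 sigma^2)).
#'
#' @param y1,y2 numeric vectors of equal length.
#' @param sigma kernel width, > 0.
#' @export
gaussian_kernel <- function(y1, y2, sigma = 1) {
  if (sigma <= 0) stop("sigma must be positive")
  if (length(y1) != length(y2)) stop("dimension mismatch")
  exp(-sum((y1 - y2)^2) / (2 * sigma^2))
}

# Dense Gaussian kernel matrix between the rows of A and B.
kernel_matrix <- function(A, B, sigma) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Fuzzy weights from distance to the class center
#'
#' For each class, with center the class mean and radius r the maximum
#' in-class distance to it, s_m = 1 - d_m / (r + delta). Points at their
#' class mean get weight 1; the farthest point gets delta/(r + delta) > 0.
#' A single-point class gets weight 1.
#'
#' @param inputs n x d feature matrix.
#' @param labels vector in {-1, +1}.
#' @param delta small positive offset keeping weights positive.
#' @return weights s in (0, 1].
#' @export
class_center_memberships <- function(inputs, labels, delta = 1e-6) {
  X <- as.matrix(inputs)
  s <- numeric(nrow(X))
  for (z in unique(labels)) {
    idx <- which(labels == z)
    ctr <- colMeans(X[idx, , drop = FALSE])
    d <- sqrt(rowSums(sweep(X[idx, , drop = FALSE], 2L, ctr)^2))
    r <- max(d)
    s[idx] <- if (r == 0) 1 else 1 - d / (r + delta)
  }
  s
}

#' Solve the fuzzy-SVM dual by SMO
#'
#' Maximizes sum beta - 1/2 sum_mn beta_m beta_n z_m z_n J(y_m, y_n) subject
#' to sum beta z = 0 and 0 <= beta_m <= s_m C: the per-sample fuzzy weight
#' scales the box constraint, shrinking the influence an outlier can exert.
#' Sequential minimal optimization with maximal-violating-pair selection;
#' deterministic given the input order. The bias t is averaged over margin
#' support vectors (0 < beta < sC), falling back to the KKT midpoint when
#' none exist.
#'
#' @param inputs n x d feature matrix.
#' @param labels vector in {-1, +1}, both classes present.
#' @param fuzzy_weights per-sample weights in (0, 1].
#' @param C penalty parameter.
#' @param sigma Gaussian kernel width.
#' @param tol KKT violation tolerance (default 1e-8).
#' @param max_pairs cap on pairwise updates (default 1e5).
#' @return an `fsvm_model`: beta, bias t, support vectors and metadata.
#' @export
solve_fsvm_dual <- function(inputs, labels, fuzzy_weights = NULL, C = 10,
                            sigma = 1, tol = 1e-8, max_pairs = 1e5) {
  X <- as.matrix(inputs)
  z <- as.numeric(labels)
  n <- nrow(X)
  if (!all(z %in% c(-1, 1))) stop("labels must be in {-1, +1}")
  if (length(unique(z)) < 2L) stop("both classes must be present")
  if (is.null(fuzzy_weights)) fuzzy_weights <- rep(1, n)
  if (any(fuzzy_weights <= 0)) stop("fuzzy weights must be positive")
  cap <- fuzzy_weights * C
  K <- kernel_matrix(X, X, sigma)
  Q <- K * tcrossprod(z)
  beta <- numeric(n)
  grad <- rep(-1, n)  # gradient of 1/2 b'Qb - sum b
  pairs <- 0L
  repeat {
    # maximal violating pair (LIBSVM working-set selection)
    up <- (z > 0 & beta < cap - 1e-12) | (z < 0 & beta > 1e-12)
    lo <- (z > 0 & beta > 1e-12) | (z < 0 & beta < cap - 1e-12)
    if (!any(up) || !any(lo)) break
    gmax_i <- which(up)[which.max(-z[up] * grad[up])]
    gmin_j <- which(lo)[which.min(-z[lo] * grad[lo])]
    gap <- (-z[gmax_i] * grad[gmax_i]) - (-z[gmin_j] * grad[gmin_j])
    if (gap < tol) break
    if (pairs >= max_pairs) {
      stop(sprintf("SMO failed to converge in %d pair updates (gap %.3g)",
                   max_pairs, gap))
    }
    i <- gmax_i; j <- gmin_j
    # analytic 2-variable solve along the equality constraint
    eta <- Q[i, i] + Q[j, j] - 2 * z[i] * z[j] * Q[i, j]
    if (eta <= 0) eta <- 1e-12
    delta <- (-z[i] * grad[i] + z[j] * grad[j]) / eta
    bi_old <- beta[i]; bj_old <- beta[j]
    # clip delta so beta_i + z_i*delta and beta_j - z_j*delta stay in the box
    if (z[i] > 0) { lo_i <- -bi_old; hi_i <- cap[i] - bi_old }
    else          { lo_i <- bi_old - cap[i]; hi_i <- bi_old }
    if (z[j] > 0) { lo_j <- bj_old - cap[j]; hi_j <- bj_old }
    else          { lo_j <- -bj_old; hi_j <- cap[j] - bj_old }
    delta <- min(max(delta, max(lo_i, lo_j)), min(hi_i, hi_j))
    beta[i] <- bi_old + z[i] * delta
    beta[j] <- bj_old - z[j] * delta
    grad <- grad + (beta[i] - bi_old) * Q[, i] + (beta[j] - bj_old) * Q[, j]
    pairs <- pairs + 1L
  }
  # bias from margin support vectors: z_m - sum beta z K(., m)
  f <- as.vector(K %*% (beta * z))
  margin <- beta > 1e-8 & beta < cap - 1e-8
  t_bias <- if (any(margin)) {
    mean(z[margin] - f[margin])
  } else {
    # midpoint of the KKT feasibility interval for the bias
    up <- (z > 0 & beta < cap - 1e-12) | (z < 0 & beta > 1e-12)
    lo <- (z > 0 & beta > 1e-12) | (z < 0 & beta < cap - 1e-12)
    (min((z - f)[up]) + max((z - f)[lo])) / 2
  }
  structure(list(
    beta = beta, bias = t_bias, labels = z, support = X,
    fuzzy_weights = fuzzy_weights, C = C, sigma = sigma,
    pair_updates = pairs
  ), class = "fsvm_model")
}

#' KKT residual of a fitted dual solution
#'
#' Returns the maximal violating-pair gap, zero for an exact solution.
#'
#' @param model an `fsvm_model`.
#' @export
fsvm_kkt_residual <- function(model) {
  z <- model$labels
  beta <- model$beta
  cap <- model$fuzzy_weights * model$C
  Q <- kernel_matrix(model$support, model$support, model$sigma) *
    tcrossprod(z)
  grad <- as.vector(Q %*% beta) - 1
  up <- (z > 0 & beta < cap - 1e-12) | (z < 0 & beta > 1e-12)
  lo <- (z > 0 & beta > 1e-12) | (z < 0 & beta < cap - 1e-12)
  if (!any(up) || !any(lo)) return(0)
  max(-z[up] * grad[up]) - min(-z[lo] * grad[lo])
}

#' Decision value of a fuzzy-SVM model
#'
#' f(y) = sum_m beta_m z_m J(y_m, y) + t.
#'
#' @param model an `fsvm_model`.
#' @param y a single feature vector or a matrix of rows.
#' @export
decision_value <- function(model, y) {
  Y <- if (is.matrix(y)) y else matrix(y, nrow = 1L)
  if (ncol(Y) != ncol(model$support)) stop("dimension mismatch")
  Kt <- kernel_matrix(Y, model$support, model$sigma)
  as.vector(Kt %*% (model$beta * model$labels)) + model$bias
}

#' Predicted labels (ties at exactly zero go to +1)
#'
#' @inheritParams decision_value
#' @export
predict_labels <- function(model, y) {
  ifelse(decision_value(model, y) >= 0, 1, -1)
}

#' Train on one set, predict on another
#'
#' Standardizes features with training statistics, computes class-center
#' fuzzy weights (or all ones with `weighting = FALSE`, the plain-SVM
#' baseline), solves the dual and predicts signs on the test rows.
#'
#' @param train_x,train_z training features and labels in {-1, +1}
#'   (malignant = +1 by convention).
#' @param test_x test feature matrix.
#' @param C penalty (default 10).
#' @param sigma kernel width on standardized features (default 1).
#' @param weighting use fuzzy weighting (default TRUE).
#' @return list: predictions, decision values, model, standardization.
#' @export
fit_predict <- function(train_x, train_z, test_x, C = 10, sigma = 1,
                        weighting = TRUE) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  mu <- colMeans(train_x)
  sd_ <- apply(train_x, 2L, stats::sd)
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  scale_mat <- function(M) sweep(sweep(M, 2L, mu), 2L, sd_, "/")
  Xtr <- scale_mat(train_x)
  Xte <- scale_mat(test_x)
  s <- if (weighting) class_center_memberships(Xtr, train_z) else
    rep(1, nrow(Xtr))
  model <- solve_fsvm_dual(Xtr, train_z, s, C = C, sigma = sigma)
  dec <- decision_value(model, Xte)
  list(predictions = ifelse(dec >= 0, 1, -1), decision_values = dec,
       model = model, standardization = list(center = mu, scale = sd_))
}

#' Serialize a fuzzy-SVM model to JSON
#'
#' @param model an `fsvm_model`.
#' @param path output file.
#' @param standardization optional list(center, scale) recorded alongside.
#' @export
fsvm_to_json <- function(model, path, standardization = NULL) {
  obj <- list(beta = model$beta, bias = model$bias, labels = model$labels,
              support = model$support, fuzzy_weights = model$fuzzy_weights,
              C = model$C, sigma = model$sigma,
              standardization = standardization)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname fsvm_to_json
#' @export
fsvm_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(beta = obj$beta, bias = obj$bias, labels = obj$labels,
                 support = as.matrix(obj$support),
                 fuzzy_weights = obj$fuzzy_weights, C = obj$C,
                 sigma = obj$sigma), class = "fsvm_model")
}
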