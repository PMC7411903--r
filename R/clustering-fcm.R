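# Coerce clustering input to an N x d numeric matrix. Image matrices are
# flattened to one intensity column; vectors become a single column.
as_data_matrix <- function(data) {
  if (is.matrix(data) && !is.null(attr(data, "gray_image"))) {
    data <- matrix(as.numeric(data), ncol = 1L)
  } else if (is.matrix(data)) {
    storage.mode(data) <- "double"
  } else {
    data <- matrix(as.numeric(data), ncol = 1L)
  }
  if (nrow(data) < 1L) stop("data must contain at least one point")
  if (!all(is.finite(data))) stop("data must be finite")
  data
}

#' Squared Euclidean distances between points and cluster centers
#'
#' @param data numeric vector or N x d matrix of points.
#' @param centers numeric vector or k x d matrix of cluster centers.
#' @return N x k matrix with entry (l, m) = ||x_l - v_m||^2.
#' @export
squared_distances <- function(data, centers) {
  data <- as_data_matrix(data)
  centers <- as_data_matrix(centers)
  if (ncol(data) != ncol(centers)) {
    stop(sprintf("dimension mismatch: data has %d columns, centers have %d",
                 ncol(data), ncol(centers)))
  }
  # ||x||^2 + ||v||^2 - 2 x.v, clamped at 0 against roundoff
  d2 <- outer(rowSums(data^2), rowSums(centers^2), "+") -
    2 * tcrossprod(data, centers)
  d2[d2 < 0] <- 0
  d2
}

#' Fuzzy c-means membership update
#'
#' Computes the probabilistic membership matrix from squared distances:
#' u_lm = 1 / sum_q (d_lm^2 / d_lq^2)^(1/(p-1)). Rows sum to one. A point
#' coincident with one or more centers gets its membership split equally
#' over the zero-distance clusters.
#'
#' @param sq_dists N x k matrix of squared distances.
#' @param p fuzzifier, > 1.
#' @return N x k membership matrix.
#' @export
fcm_memberships <- function(sq_dists, p = 2) {
  sq_dists <- as.matrix(sq_dists)
  if (p <= 1) stop("fuzzifier p must be > 1")
  expo <- 1 / (p - 1)
  # inverse-distance weights; rows renormalised to sum 1
  w <- sq_dists^(-expo)
  u <- w / rowSums(w)
  zero_rows <- which(!apply(is.finite(u), 1L, all))
  for (l in zero_rows) {
    z <- sq_dists[l, ] == 0
    u[l, ] <- 0
    u[l, z] <- 1 / sum(z)
  }
  u
}

#' Membership-weighted cluster centers
#'
#' v_m = sum_l u_lm^p x_l / sum_l u_lm^p.
#'
#' @param memberships N x k matrix of (star) memberships or typicalities.
#' @param data points as accepted by [squared_distances()].
#' @param p fuzzifier, > 1 (crisp 0/1 memberships are unchanged by the power).
#' @return k x d matrix of centers.
#' @export
weighted_centers <- function(memberships, data, p = 2) {
  data <- as_data_matrix(data)
  u <- as.matrix(memberships)
  if (nrow(u) != nrow(data)) stop("memberships and data disagree in length")
  up <- u^p
  denom <- colSums(up)
  if (any(denom <= 0)) {
    stop(sprintf("cluster %d has zero total membership weight",
                 which(denom <= 0)[1L]))
  }
  sweep(crossprod(up, data), 1L, denom, "/")
}

#' Fuzzy c-means objective
#'
#' sum_m sum_l u_lm^p d_lm^2.
#'
#' @inheritParams fcm_memberships
#' @param memberships N x k membership matrix.
#' @export
fcm_objective <- function(memberships, sq_dists, p = 2) {
  u <- as.matrix(memberships)
  d2 <- as.matrix(sq_dists)
  if (!all(dim(u) == dim(d2))) stop("memberships and sq_dists shapes disagree")
  sum(u^p * d2)
}

# Seeded draw of k distinct data points as initial centers; restores the
# caller's RNG state.
init_centers <- function(data, k, seed) {
  if (is.null(seed)) stop("seed is required for center initialization")
  n <- nrow(data)
  idx <- with_seed(seed, sample.int(n, k))
  data[idx, , drop = FALSE]
}

# Evaluate RNG-dependent code under a fixed seed, restoring global RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Shared FCM/IFCM alternation. sugeno_lambda = 0 reduces exactly to plain FCM
# because the Sugeno negation then yields zero hesitation bitwise.
fcm_engine <- function(data, k, p, sugeno_lambda, tol, max_iter, seed) {
  data <- as_data_matrix(data)
  n <- nrow(data)
  if (k > n) stop("k must not exceed the number of points")
  if (p <= 1) stop("fuzzifier p must be > 1")
  degenerate <- all(apply(data, 2L, function(col) diff(range(col)) == 0))
  if (degenerate && k > 1L) {
    warning("all points identical; returning a single-center partition")
    k <- 1L
  }
  centers <- init_centers(data, k, seed)
  u_prev <- NULL
  objective_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    d2 <- squared_distances(data, centers)
    u <- fcm_memberships(d2, p)
    if (sugeno_lambda > 0) {
      hes <- sugeno_hesitation(u, sugeno_lambda)
      ustar <- star_membership(u, hes$pi)
    } else {
      ustar <- u
    }
    objective_trace <- c(objective_trace, fcm_objective(ustar, d2, p))
    centers <- weighted_centers(ustar, data, p)
    if (!is.null(u_prev) && max(abs(ustar - u_prev)) < tol) {
      converged <- TRUE
      u_prev <- ustar
      break
    }
    u_prev <- ustar
  }
  structure(list(
    memberships = u_prev,
    fcm_memberships = u,
    centers = centers,
    fuzzifier = p,
    sugeno_lambda = sugeno_lambda,
    iterations_run = iter,
    converged = converged,
    objective_trace = objective_trace,
    seed = seed,
    k = k
  ), class = "fuzzy_partition")
}

#' Fit fuzzy c-means
#'
#' Alternates the membership and center updates from a seeded random center
#' initialization (k distinct data points) until the largest absolute
#' membership change drops below `tol` or `max_iter` is reached.
#'
#' @param data numeric vector, matrix of points, or a gray image matrix
#'   (flattened to per-pixel intensities).
#' @param k number of clusters (>= 1, <= N).
#' @param p fuzzifier, > 1.
#' @param tol convergence tolerance on max |delta u|.
#' @param max_iter iteration cap.
#' @param seed required integer seed for center initialization.
#' @return A `fuzzy_partition`: memberships, centers, fuzzifier,
#'   iterations_run, converged flag and the objective trace.
#' @examples
#' fit <- fit_fcm(c(0, 0.1, 0.2, 0.8, 0.9, 1.0), k = 2, seed = 1)
#' sort(drop(fit$centers))
#' @export
fit_fcm <- function(data, k, p = 2, tol = 1e-5, max_iter = 100, seed) {
  fcm_engine(data, k, p, sugeno_lambda = 0, tol, max_iter, seed)
}

#' Fit intuitionistic fuzzy c-means
#'
#' Like [fit_fcm()] but each iteration lifts the probabilistic memberships by
#' their Sugeno hesitation degree (u* = u + pi) before the center update;
#' convergence is judged on the star memberships. `sugeno_lambda = 0`
#' reproduces [fit_fcm()] exactly.
#'
#' @inheritParams fit_fcm
#' @param sugeno_lambda Sugeno negation parameter, >= 0.
#' @export
fit_ifcm <- function(data, k, p = 2, sugeno_lambda = 2, tol = 1e-5,
                     max_iter = 100, seed) {
  if (sugeno_lambda < 0) stop("sugeno_lambda must be >= 0")
  fcm_engine(data, k, p, sugeno_lambda, tol, max_iter, seed)
}

#' Hard labels from a fuzzy partition
#'
#' Per-point argmax over cluster memberships; ties go to the lowest cluster
#' index. Labels are 0-based (cluster 0 .. k-1).
#'
#' @param partition a `fuzzy_partition` or a membership matrix.
#' @return integer vector of labels in 0..k-1.
#' @export
labels_from_partition <- function(partition) {
  u <- if (inherits(partition, "fuzzy_partition")) partition$memberships
       else as.matrix(partition)
  max.col(u, ties.method = "first") - 1L
}
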