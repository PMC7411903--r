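#' Possibilistic scale parameters
#'
#' lambda_m = W * sum_l u_lm^p d_lm^2 / sum_l u_lm^p, estimated from a
#' (converged) fuzzy partition. These scales calibrate the typicality
#' bandwidth of each cluster.
#'
#' @param memberships N x k membership matrix (from a converged FCM run).
#' @param sq_dists N x k matrix of squared distances to the same centers.
#' @param p fuzzifier, > 1.
#' @param W positive weight multiplying every scale (default 1).
#' @return numeric vector of k positive scales.
#' @export
pcm_scales <- function(memberships, sq_dists, p = 2, W = 1) {
  u <- as.matrix(memberships)
  d2 <- as.matrix(sq_dists)
  if (!all(dim(u) == dim(d2))) stop("memberships and sq_dists shapes disagree")
  up <- u^p
  denom <- colSums(up)
  if (any(denom <= 0)) stop("zero membership mass in a cluster denominator")
  W * colSums(up * d2) / denom
}

#' Possibilistic typicality update
#'
#' u_lm = 1 / (1 + (d_lm^2 / lambda_m)^(1/(p-1))). Typicalities are
#' independent across clusters: a far outlier scores low everywhere, which is
#' what makes the possibilistic family robust to impulse noise.
#'
#' @inheritParams pcm_scales
#' @param scales k positive scale parameters lambda_m.
#' @return N x k typicality matrix with values in (0, 1].
#' @export
pcm_typicality <- function(sq_dists, scales, p = 2) {
  d2 <- as.matrix(sq_dists)
  if (p <= 1) stop("fuzzifier p must be > 1")
  if (any(scales <= 0)) stop("scales must be positive")
  1 / (1 + sweep(d2, 2L, scales, "/")^(1 / (p - 1)))
}

#' Sugeno nonmembership and hesitation degree
#'
#' nu = (1 - u) / (1 + lambda_s * u), pi = 1 - u - nu. The Sugeno negation
#' guarantees pi >= 0 for lambda_s >= 0 and the identity u + nu + pi = 1 holds
#' exactly by construction.
#'
#' @param u membership value(s) in `[0, 1]` (vector or matrix).
#' @param sugeno_lambda Sugeno parameter lambda_s >= 0 (scalar or elementwise
#'   vector conformable with `u`).
#' @return list with components `nu` and `pi`, same shape as `u`.
#' @export
sugeno_hesitation <- function(u, sugeno_lambda) {
  if (any(u < 0 | u > 1)) stop("memberships must lie in [0, 1]")
  if (any(sugeno_lambda < 0)) stop("sugeno_lambda must be >= 0")
  nu <- (1 - u) / (1 + sugeno_lambda * u)
  pi <- 1 - u - nu
  list(nu = nu, pi = pi)
}

#' Intuitionistic (star) membership
#'
#' u* = u + pi; lies in `[u, 1]` and is monotone in u for fixed lambda_s.
#'
#' @param u membership value(s).
#' @param pi hesitation degree(s) from [sugeno_hesitation()].
#' @export
star_membership <- function(u, pi) {
  u + pi
}

#' Hybrid possibilistic objective
#'
#' sum_m sum_l u*_lm^p d_lm^2 + sum_m lambda_m sum_l (1 - u*_lm)^p. The
#' exponent p on the penalty makes the typicality update its exact pointwise
#' minimizer.
#'
#' @param star_memberships N x k matrix of star memberships (typicalities for
#'   the plain possibilistic case).
#' @inheritParams pcm_typicality
#' @export
ipfcm_objective <- function(star_memberships, sq_dists, scales, p = 2) {
  u <- as.matrix(star_memberships)
  d2 <- as.matrix(sq_dists)
  if (!all(dim(u) == dim(d2))) stop("shapes disagree")
  sum(u^p * d2) + sum(scales * colSums((1 - u)^p))
}

# Shared possibilistic loop. sugeno_lambda = 0 is the plain possibilistic
# fuzzy c-means; > 0 lifts each typicality by its hesitation degree before
# the center update. The scales lambda_m are estimated once from the
# converged FCM phase (star-lifted numerator, plain-membership denominator)
# and held fixed, so the possibilistic phase descends a fixed objective.
possibilistic_engine <- function(data, k, p, W, sugeno_lambda, tol, max_iter,
                                 seed) {
  data <- as_data_matrix(data)
  fcm <- fcm_engine(data, k, p, sugeno_lambda = 0, tol, max_iter, seed)
  k <- fcm$k
  centers <- fcm$centers
  d2 <- squared_distances(data, centers)
  u_fcm <- fcm$memberships
  scales <- pcm_scales(u_fcm, d2, p, W)
  u_prev <- NULL
  typ <- NULL
  hes <- list(nu = NULL, pi = NULL)
  objective_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    d2 <- squared_distances(data, centers)
    typ <- pcm_typicality(d2, scales, p)
    if (sugeno_lambda > 0) {
      hes <- sugeno_hesitation(typ, sugeno_lambda)
      ustar <- star_membership(typ, hes$pi)
    } else {
      ustar <- typ
    }
    objective_trace <- c(objective_trace, ipfcm_objective(ustar, d2, scales, p))
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
    typicalities = typ,
    nonmemberships = hes$nu,
    hesitations = hes$pi,
    centers = centers,
    scales = scales,
    weight = W,
    fuzzifier = p,
    sugeno_lambda = sugeno_lambda,
    iterations_run = iter,
    converged = converged,
    objective_trace = objective_trace,
    fcm_init = fcm,
    seed = seed,
    k = k
  ), class = c("possibilistic_partition", "fuzzy_partition"))
}

#' Fit possibilistic fuzzy c-means
#'
#' Runs [fit_fcm()] to convergence, estimates the cluster scales lambda_m from
#' that solution, then alternates the typicality and center updates with the
#' scales held fixed.
#'
#' @inheritParams fit_fcm
#' @param W positive scale weight (default 1).
#' @export
fit_pfcm <- function(data, k, p = 2, W = 1, tol = 1e-5, max_iter = 100, seed) {
  possibilistic_engine(data, k, p, W, sugeno_lambda = 0, tol, max_iter, seed)
}

#' Fit intuitionistic possibilistic fuzzy c-means
#'
#' The hybrid algorithm: FCM initialization, possibilistic scale estimation
#' (star-lifted numerator), then a loop of typicality update, Sugeno
#' hesitation, star lift u* = u + pi, and star-weighted center update, until
#' the star memberships stabilise. `sugeno_lambda = 0` reproduces
#' [fit_pfcm()] exactly.
#'
#' @inheritParams fit_pfcm
#' @param sugeno_lambda Sugeno negation parameter, >= 0 (default 2).
#' @examples
#' x <- c(rnorm(50, 0.1, 0.03), rnorm(50, 0.9, 0.03))
#' fit <- fit_ipfcm(x, k = 2, seed = 42)
#' sort(drop(fit$centers))
#' @export
fit_ipfcm <- function(data, k, p = 2, W = 1, sugeno_lambda = 2, tol = 1e-5,
                      max_iter = 100, seed) {
  if (sugeno_lambda < 0) stop("sugeno_lambda must be >= 0")
  possibilistic_engine(data, k, p, W, sugeno_lambda, tol, max_iter, seed)
}
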