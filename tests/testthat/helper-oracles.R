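# Independent oracles. These deliberately re-derive results by brute force
# (grid search, exhaustive enumeration, long randomized ascent) and share no
# code path with the package implementations they check.

# Minimize u1^p d1 + (1-u1)^p d2 over the 2-simplex by grid search.
grid_fcm_membership_k2 <- function(d2, p, step = 1e-4) {
  u1 <- seq(0, 1, by = step)
  obj <- u1^p * d2[1] + (1 - u1)^p * d2[2]
  u <- u1[which.min(obj)]
  c(u, 1 - u)
}

# Minimize u^p d2 + lambda (1-u)^p over u in [0, 1] by grid search.
grid_typicality <- function(d2, lambda, p, step = 1e-4) {
  u <- seq(0, 1, by = step)
  u[which.min(u^p * d2 + lambda * (1 - u)^p)]
}

# All permutations of 1..n, coded independently (Heap-style recursion).
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Exhaustive best-permutation agreement between two label vectors.
perm_accuracy_oracle <- function(labels, truth) {
  la <- as.integer(factor(labels))
  tr <- as.integer(factor(truth))
  k <- max(la, tr)
  best <- 0
  for (p in all_perms(k)) {
    best <- max(best, mean(unlist(p)[la] == tr))
  }
  best
}

# Otsu by direct per-cut evaluation of the between-class variance on the
# same equal-width histogram binning.
otsu_oracle <- function(x, levels = 256) {
  rng <- range(x)
  bin <- pmin(floor((x - rng[1]) / diff(rng) * levels) + 1L, levels)
  mids <- rng[1] + (seq_len(levels) - 0.5) / levels * diff(rng)
  best_v <- -Inf
  best_cut <- NA
  for (cut in 1:(levels - 1L)) {
    lo <- bin <= cut
    if (!any(lo) || all(lo)) next
    w0 <- mean(lo)
    mu0 <- mean(mids[bin[lo]])
    mu1 <- mean(mids[bin[!lo]])
    v <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (v > best_v + 1e-15) {
      best_v <- v
      best_cut <- cut
    }
  }
  rng[1] + best_cut / levels * diff(rng)
}

# AUC as the pairwise concordance probability (ties count 1/2).
concordance_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == -1]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Independently coded confusion-matrix formulas.
metrics_oracle <- function(tp, fp, fn, tn) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  mccd <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    accuracy = div(tp + tn, tp + fp + fn + tn),
    ppv = div(tp, tp + fp),
    npv = div(tn, tn + fn),
    mcc = if (mccd == 0) 0 else (tp * tn - fp * fn) / mccd
  )
}

# Long-run randomized pairwise exact coordinate ascent on the fuzzy-SVM
# dual with incremental gradient updates; independent of the package's
# maximal-violating-pair solver.
pair_ascent_oracle <- function(X, z, cap, sigma = 1, iters = 2e5, seed = 1) {
  n <- length(z)
  d2 <- as.matrix(stats::dist(X))^2
  K <- exp(-d2 / (2 * sigma^2))
  Q <- K * tcrossprod(z)
  beta <- numeric(n)
  grad <- rep(-1, n)
  set.seed(seed)
  pairs <- matrix(sample.int(n, 2 * iters, replace = TRUE), ncol = 2)
  for (it in seq_len(iters)) {
    i <- pairs[it, 1]; j <- pairs[it, 2]
    if (i == j) next
    eta <- Q[i, i] + Q[j, j] - 2 * z[i] * z[j] * Q[i, j]
    if (eta <= 0) eta <- 1e-12
    delta <- (-z[i] * grad[i] + z[j] * grad[j]) / eta
    lo_i <- if (z[i] > 0) -beta[i] else beta[i] - cap[i]
    hi_i <- if (z[i] > 0) cap[i] - beta[i] else beta[i]
    lo_j <- if (z[j] > 0) beta[j] - cap[j] else -beta[j]
    hi_j <- if (z[j] > 0) beta[j] else cap[j] - beta[j]
    delta <- min(max(delta, max(lo_i, lo_j)), min(hi_i, hi_j))
    if (delta == 0) next
    di <- z[i] * delta; dj <- -z[j] * delta
    beta[i] <- beta[i] + di
    beta[j] <- beta[j] + dj
    grad <- grad + di * Q[, i] + dj * Q[, j]
  }
  beta
}

fsvm_dual_objective <- function(beta, X, z, sigma = 1) {
  K <- exp(-as.matrix(stats::dist(X))^2 / (2 * sigma^2))
  sum(beta) - 0.5 * drop(t(beta) %*% (K * tcrossprod(z)) %*% beta)
}

# FCM fixed point by long multi-start alternation at machine tolerance,
# with the updates re-derived inline.
fcm_alternation_oracle <- function(x, k, p = 2, starts = 8) {
  best <- NULL
  best_obj <- Inf
  n <- length(x)
  for (s in seq_len(starts)) {
    set.seed(1000 + s)
    v <- sort(sample(x, k))
    for (it in 1:5000) {
      d2 <- outer(x, v, function(a, b) (a - b)^2)
      w <- d2^(-1 / (p - 1))
      u <- w / rowSums(w)
      for (l in which(!is.finite(rowSums(u)))) {
        zz <- d2[l, ] == 0
        u[l, ] <- 0; u[l, zz] <- 1 / sum(zz)
      }
      v_new <- colSums(u^p * x) / colSums(u^p)
      if (max(abs(v_new - v)) < 1e-13) { v <- v_new; break }
      v <- v_new
    }
    obj <- sum(u^p * outer(x, v, function(a, b) (a - b)^2))
    if (obj < best_obj) { best_obj <- obj; best <- v }
  }
  sort(best)
}
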