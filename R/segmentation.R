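#' Otsu threshold
#'
#' Exhaustive scan of histogram cut points maximizing the between-class
#' variance omega0 * omega1 * (mu0 - mu1)^2. Ties go to the lowest threshold.
#'
#' @param image numeric matrix or vector of intensities.
#' @param levels number of histogram bins spanning the intensity range.
#' @return the threshold intensity (upper edge of the lower class).
#' @export
otsu_threshold <- function(image, levels = 256) {
  x <- as.numeric(image)
  if (length(x) == 0L) stop("empty image")
  rng <- range(x)
  if (diff(rng) == 0) stop("degenerate histogram: constant image")
  # bin pixels into `levels` equal-width bins over the observed range
  bin <- pmin(floor((x - rng[1]) / diff(rng) * levels) + 1L, levels)
  h <- tabulate(bin, nbins = levels) / length(x)
  mids <- rng[1] + (seq_len(levels) - 0.5) / levels * diff(rng)
  w0 <- cumsum(h)
  m0 <- cumsum(h * mids)
  mT <- m0[levels]
  # candidate cuts after bins 1..levels-1
  w0c <- w0[-levels]
  m0c <- m0[-levels]
  valid <- w0c > 0 & w0c < 1
  bcv <- rep(-Inf, levels - 1L)
  bcv[valid] <- (mT * w0c[valid] - m0c[valid])^2 /
    (w0c[valid] * (1 - w0c[valid]))
  best <- which.max(bcv)  # which.max takes the first (lowest) maximiser
  rng[1] + best / levels * diff(rng)
}

#' Segment an image by Otsu thresholding
#'
#' @param image gray image matrix.
#' @param levels histogram bins for [otsu_threshold()].
#' @return integer label matrix (0 = below threshold, 1 = above).
#' @export
otsu_segment <- function(image, levels = 256) {
  thr <- otsu_threshold(image, levels)
  lab <- matrix(as.integer(image > thr), nrow = nrow(image))
  lab
}

# All permutations of 1..n (n <= 8 guarded by the caller).
permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow = nrow(sub))
  }
  out
}

#' Segmentation accuracy up to label permutation
#'
#' Fraction of pixels agreeing between two label maps, maximized over all
#' relabelings of the predicted map. Equals 1 iff some permutation makes the
#' maps identical. Both maps may use at most 8 distinct labels.
#'
#' @param labels predicted label map (matrix or vector).
#' @param truth ground-truth label map of identical shape.
#' @return agreement fraction in `[0, 1]`.
#' @export
segmentation_accuracy <- function(labels, truth) {
  if (length(labels) != length(truth) ||
      (is.matrix(labels) && is.matrix(truth) &&
       !all(dim(labels) == dim(truth)))) {
    stop("labels and truth must have the same shape")
  }
  la <- as.integer(factor(as.vector(labels)))
  tr <- as.integer(factor(as.vector(truth)))
  k <- max(max(la), max(tr))
  if (k > 8L) stop("more than 8 labels: permutation search refused")
  tab <- matrix(0, nrow = k, ncol = k)
  counts <- table(factor(la, levels = seq_len(k)),
                  factor(tr, levels = seq_len(k)))
  tab[seq_len(k), seq_len(k)] <- as.numeric(counts)
  perms <- permutations(k)
  best <- 0
  for (i in seq_len(nrow(perms))) {
    agree <- sum(tab[cbind(perms[i, ], seq_len(k))])
    if (agree > best) best <- agree
  }
  best / length(la)
}

#' Cluster an image with a chosen segmentation method
#'
#' Flattens the image to per-pixel intensities, runs the chosen clustering
#' algorithm, and returns the label map plus the index of the lesion (ROI)
#' cluster, taken as the cluster with the highest center intensity.
#'
#' @param image gray image matrix with values in `[0, 1]`.
#' @param method one of "otsu", "fcm", "ifcm", "pfcm", "ipfcm".
#' @param k number of clusters (ignored by "otsu").
#' @param seed seed for center initialization.
#' @param truth optional ground-truth label map; when given, the agreement
#'   fraction is attached.
#' @param ... further arguments passed to the fitting routine.
#' @return a `segmentation_result`: label_map, roi_mask, roi_cluster,
#'   accuracy (or NA), method and fit object (NULL for Otsu).
#' @export
segment_image <- function(image, method = c("ipfcm", "fcm", "ifcm", "pfcm",
                                            "otsu"),
                          k = 3, seed = 1, truth = NULL, ...) {
  method <- match.arg(method)
  if (method == "otsu") {
    label_map <- otsu_segment(image)
    roi_cluster <- 1L
    fit <- NULL
  } else {
    fit <- switch(method,
      fcm = fit_fcm(image, k = k, seed = seed, ...),
      ifcm = fit_ifcm(image, k = k, seed = seed, ...),
      pfcm = fit_pfcm(image, k = k, seed = seed, ...),
      ipfcm = fit_ipfcm(image, k = k, seed = seed, ...)
    )
    labels <- labels_from_partition(fit)
    label_map <- matrix(labels, nrow = nrow(image))
    roi_cluster <- which.max(rowMeans(fit$centers)) - 1L
  }
  accuracy <- if (!is.null(truth)) segmentation_accuracy(label_map, truth)
              else NA_real_
  structure(list(
    label_map = label_map,
    roi_cluster = roi_cluster,
    roi_mask = label_map == roi_cluster,
    accuracy = accuracy,
    method = method,
    fit = fit
  ), class = "segmentation_result")
}
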