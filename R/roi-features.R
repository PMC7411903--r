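# 8-connected component labeling by BFS over a logical mask.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  current <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- start
    lab[start] <- current
    while (length(queue) > 0L) {
      v <- queue
      queue <- integer(0)
      r <- (v - 1L) %% nr + 1L
      c <- (v - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; cc <- c + dc
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        if (!any(ok)) next
        w <- (cc[ok] - 1L) * nr + rr[ok]
        w <- w[mask[w] & lab[w] == 0L]
        if (length(w) > 0L) {
          lab[w] <- current
          queue <- c(queue, unique(w))
        }
      }
    }
  }
  lab
}

#' Region-of-interest mask from a label map
#'
#' Selects the pixels of the given cluster, keeps the largest 8-connected
#' component, and computes its centroid.
#'
#' @param label_map integer label matrix.
#' @param roi_cluster label value of the lesion cluster.
#' @param min_pixels minimum admissible component size (default 9).
#' @return a `roi_mask`: logical mask, centroid (row, col), area.
#' @export
roi_mask_from_labels <- function(label_map, roi_cluster, min_pixels = 9) {
  mask <- label_map == roi_cluster
  if (!any(mask)) stop("cluster ", roi_cluster, " absent from label map")
  comp <- label_components(mask)
  sizes <- tabulate(comp[comp > 0L])
  keep <- which.max(sizes)
  mask <- comp == keep
  if (sum(mask) < min_pixels) {
    stop("largest component has ", sum(mask), " pixels (< ", min_pixels, ")")
  }
  roi_mask(mask)
}

#' Construct a ROI mask object
#'
#' @param mask logical matrix (single connected lesion region).
#' @export
roi_mask <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 1L) stop("empty mask")
  structure(list(
    mask = mask,
    centroid = c(row = mean(idx[, 1]), col = mean(idx[, 2])),
    area = nrow(idx)
  ), class = "roi_mask")
}

# 3x3 box average of the binary mask: regularises the digitisation
# staircase so the 0.5 level set tracks the true boundary within ~0.2 px
# (a raw bilinear field wobbles by ~0.5 px near pixel corners).
smooth_occupancy <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask))
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  out <- matrix(0, nr, nc)
  for (i in 0:2) for (j in 0:2) out <- out + p[(1:nr) + i, (1:nc) + j]
  out / 9
}

# Continuous occupancy field: bilinear interpolation of the binary mask.
# Values >= 0.5 count as inside; the 0.5 level set is the sub-pixel boundary.
mask_field <- function(mask, r, c) {
  nr <- nrow(mask); nc <- ncol(mask)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  m00 <- mask[cbind(r0, c0)]; m10 <- mask[cbind(r0 + 1L, c0)]
  m01 <- mask[cbind(r0, c0 + 1L)]; m11 <- mask[cbind(r0 + 1L, c0 + 1L)]
  (1 - fr) * (1 - fc) * m00 + fr * (1 - fc) * m10 +
    (1 - fr) * fc * m01 + fr * fc * m11
}

inside_mask <- function(mask, r, c) {
  out <- r < 1 | r > nrow(mask) | c < 1 | c > ncol(mask)
  val <- mask_field(mask, r, c)
  val >= 0.5 & !out
}

#' Radial profile of a ROI
#'
#' Samples 32 equally spaced rays from the centroid; along each ray the
#' boundary crossing distance rl is found by marching outward in steps of a
#' quarter pixel over a smoothed continuous occupancy field and refining the
#' last-inside/first-outside pair by linear interpolation of the field to
#' its 0.5 level. The normalized radial length is
#' nrl = rl / max(rl). If the centroid itself falls outside the mask
#' (non-star-shaped region) the farthest crossing along each ray is used and
#' `centroid_inside` is flagged FALSE.
#'
#' @param roi a `roi_mask`.
#' @param n_rays number of rays (default 32).
#' @param step marching step in pixels.
#' @return a `radial_profile`: angles, rl, nrl, centroid, centroid_inside.
#' @export
radial_profile <- function(roi, n_rays = 32, step = 0.25) {
  stopifnot(inherits(roi, "roi_mask"))
  mask <- roi$mask
  ctr <- roi$centroid
  angles <- 2 * base::pi * (seq_len(n_rays) - 1L) / n_rays
  max_t <- sqrt(nrow(mask)^2 + ncol(mask)^2)
  ts <- seq(0, max_t, by = step)
  occ <- smooth_occupancy(mask)
  centroid_inside <- inside_mask(mask, ctr[1], ctr[2])
  rl <- numeric(n_rays)
  for (j in seq_len(n_rays)) {
    dr <- sin(angles[j]); dc <- cos(angles[j])
    rr <- ctr[1] + ts * dr; cc <- ctr[2] + ts * dc
    off <- rr < 1 | rr > nrow(mask) | cc < 1 | cc > ncol(mask)
    val <- mask_field(occ, rr, cc)
    ins <- val >= 0.5 & !off
    trans <- which(ins[-length(ins)] & !ins[-1L])  # inside -> outside
    if (length(trans) == 0L) {
      last_in <- which(ins)
      rl[j] <- if (length(last_in) > 0L) ts[max(last_in)] else 0
      next
    }
    cross <- if (centroid_inside) trans[1L] else trans[length(trans)]
    # linear interpolation of the occupancy field to the 0.5 crossing
    v1 <- val[cross]; v2 <- val[cross + 1L]
    frac <- if (v1 > v2) (v1 - 0.5) / (v1 - v2) else 0.5
    rl[j] <- ts[cross] + frac * step
  }
  if (max(rl) <= 0) stop("degenerate radial profile")
  structure(list(
    angles = angles,
    rl = rl,
    nrl = rl / max(rl),
    centroid = ctr,
    centroid_inside = centroid_inside
  ), class = "radial_profile")
}

# Boundary pixels: mask pixels with at least one background 8-neighbor
# (image border counts as background).
boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(FALSE, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- mask
  all_nb <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    all_nb <- all_nb & padded[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  mask & !all_nb
}

# Chain-code perimeter by Moore-neighbor boundary tracing: sum of step
# lengths (1 for axial moves, sqrt(2) for diagonal moves) around the outer
# contour. For a digitized circle this tracks the true circumference within
# a few percent, so the circularity of a disk stays near zero -- a
# pixel-count perimeter would bias it to ~0.36 regardless of radius.
chain_perimeter <- function(mask) {
  if (sum(mask) == 1L) return(1)
  nr <- nrow(mask); nc <- ncol(mask)
  at <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  # clockwise Moore neighborhood starting east
  dr8 <- c(0, 1, 1, 1, 0, -1, -1, -1)
  dc8 <- c(1, 1, 0, -1, -1, -1, 0, 1)
  start <- which(mask)[1L]
  sr <- (start - 1L) %% nr + 1L; sc <- (start - 1L) %/% nr + 1L
  # first TRUE in column-major order: west and northwest neighbors are
  # outside, so treat the arrival as an eastward move
  next_move <- function(r, c, dir) {
    for (k in 0:7) {
      d <- (dir + 5L + k) %% 8L  # sweep clockwise from just past backtrack
      rr <- r + dr8[d + 1L]; cc <- c + dc8[d + 1L]
      if (at(rr, cc)) return(c(rr, cc, d))
    }
    NULL
  }
  first <- next_move(sr, sc, 0L)
  if (is.null(first)) return(4)  # isolated pixel
  r <- first[1]; c <- first[2]; dir <- first[3]
  step_len <- function(d) if (dr8[d + 1L] != 0 && dc8[d + 1L] != 0) sqrt(2) else 1
  total <- step_len(dir)
  steps <- 0L
  max_steps <- 8L * sum(mask) + 8L
  while (steps < max_steps) {
    mv <- next_move(r, c, dir)
    # Jacob's stopping criterion: stop on re-entering the start pixel with
    # the same successor as the initial move
    if (r == sr && c == sc && all(mv[1:2] == first[1:2])) break
    total <- total + step_len(mv[3])
    r <- mv[1]; c <- mv[2]; dir <- mv[3]
    steps <- steps + 1L
  }
  total
}

#' Shape descriptors of a segmented ROI
#'
#' Area (pixel count), perimeter (count of boundary pixels with a background
#' 8-neighbor), circularity Cr = 1 - 4*pi*Ar/Pr^2 (zero for a circle),
#' shape factor Sr = Pr^2/Ar (burr/spiculation indicator, 4*pi for a circle),
#' mean/sd of the 32 normalized radial lengths, their 10-bin base-2 entropy
#' Er, the normalized central position shift ncps (centroid to darkest ROI
#' pixel, scaled by the equivalent radius sqrt(Ar/pi)), and the mean
#' boundary-to-interior gray-level gradient over the 32 rays.
#'
#' @param roi a `roi_mask`.
#' @param profile a `radial_profile` for the same mask.
#' @param image gray image the mask was segmented from.
#' @param gradient_depth pixels inward along each ray for the gradient
#'   (default 10, clamped to the centroid on short rays).
#' @return a `shape_features` list with 9 numeric entries.
#' @export
shape_features <- function(roi, profile, image, gradient_depth = 10) {
  stopifnot(inherits(roi, "roi_mask"), inherits(profile, "radial_profile"))
  mask <- roi$mask
  Ar <- roi$area
  Pr <- chain_perimeter(mask)
  Cr <- 1 - 4 * base::pi * Ar / Pr^2
  Sr <- Pr^2 / Ar
  nrl <- profile$nrl
  nrl_mean <- mean(nrl)
  nrl_sigma <- sqrt(mean((nrl - nrl_mean)^2))
  bins <- pmin(floor(nrl * 10) + 1L, 10L)
  pk <- tabulate(bins, 10L) / length(nrl)
  pk <- pk[pk > 0]
  Er <- -sum(pk * log2(pk))
  # darkest pixel inside the ROI (first in column-major order on ties)
  inside <- which(mask)
  dark <- inside[which.min(image[inside])]
  dr <- (dark - 1L) %% nrow(mask) + 1L
  dc <- (dark - 1L) %/% nrow(mask) + 1L
  shift <- sqrt((dr - roi$centroid[1])^2 + (dc - roi$centroid[2])^2)
  ncps <- unname(shift / sqrt(Ar / base::pi))
  # gradient: boundary intensity minus intensity `gradient_depth` px inward
  ctr <- roi$centroid
  gr_rays <- vapply(seq_along(profile$angles), function(j) {
    a <- profile$angles[j]
    rl <- profile$rl[j]
    pb <- clamp_pixel(ctr + (rl - 0.5) * c(sin(a), cos(a)), dim(mask))
    ri <- max(rl - gradient_depth, 0)
    pi_ <- clamp_pixel(ctr + ri * c(sin(a), cos(a)), dim(mask))
    image[pb[1], pb[2]] - image[pi_[1], pi_[2]]
  }, numeric(1))
  structure(list(
    area = Ar, perimeter = Pr, circularity = Cr, shape_factor = Sr,
    nrl_mean = nrl_mean, nrl_sigma = nrl_sigma, nrl_entropy = Er,
    ncps = ncps, gradient = mean(gr_rays)
  ), class = "shape_features")
}

clamp_pixel <- function(p, dims) {
  c(min(max(floor(p[1] + 0.5), 1), dims[1]),
    min(max(floor(p[2] + 0.5), 1), dims[2]))
}

#' Gray-level histogram of a masked region
#'
#' @param image gray image in `[0, 1]`.
#' @param mask logical matrix or `roi_mask`.
#' @param levels number of gray levels L (default 256).
#' @return normalized histogram vector of length L (sums to 1), with the
#'   level values `(0:(L-1))/(L-1)` as attribute `"levels"`.
#' @export
gray_histogram <- function(image, mask, levels = 256) {
  if (inherits(mask, "roi_mask")) mask <- mask$mask
  vals <- image[mask]
  if (length(vals) == 0L) stop("empty mask")
  bin <- floor(vals * (levels - 1) + 0.5) + 1L
  h <- tabulate(bin, levels) / length(vals)
  attr(h, "levels") <- (0:(levels - 1)) / (levels - 1)
  h
}

#' Histogram texture moments
#'
#' The seven gray-level-histogram descriptors: mean, standard deviation,
#' smoothness 1 - 1/(1 + sigma^2), skewness (raw third central moment),
#' uniformity sum h^2, entropy -sum h log2 h, kurtosis (raw fourth central
#' moment). Moments are computed on level values rescaled to `[0, 1]` so the
#' descriptors are comparable across bit depths; skewness and kurtosis are
#' not standardized.
#'
#' @param h normalized histogram (sums to 1).
#' @param levels level values; defaults to the `"levels"` attribute of `h`
#'   or an equally spaced grid on `[0, 1]`.
#' @return a `texture_features` list with 7 numeric entries.
#' @export
texture_features <- function(h, levels = NULL) {
  if (abs(sum(h) - 1) > 1e-8) stop("histogram must be normalized to sum 1")
  if (is.null(levels)) levels <- attr(h, "levels")
  if (is.null(levels)) levels <- (seq_along(h) - 1) / (length(h) - 1)
  if (length(levels) != length(h)) stop("levels and histogram lengths differ")
  m <- sum(levels * h)
  v <- sum((levels - m)^2 * h)
  hpos <- h[h > 0]
  structure(list(
    mean = m,
    sigma = sqrt(v),
    smoothness = 1 - 1 / (1 + v),
    skewness = sum((levels - m)^3 * h),
    uniformity = sum(h^2),
    entropy = -sum(hpos * log2(hpos)),
    kurtosis = sum((levels - m)^4 * h)
  ), class = "texture_features")
}

feature_names <- c("area", "perimeter", "circularity", "shape_factor",
                   "nrl_mean", "nrl_sigma", "nrl_entropy", "ncps", "gradient",
                   "tex_mean", "tex_sigma", "tex_smoothness", "tex_skewness",
                   "tex_uniformity", "tex_entropy", "tex_kurtosis")

#' Extract all 16 features from one ROI
#'
#' @param image gray image.
#' @param roi a `roi_mask`.
#' @param levels histogram levels for the texture block.
#' @return named numeric vector of 16 features.
#' @export
extract_features <- function(image, roi, levels = 256) {
  prof <- radial_profile(roi)
  sf <- shape_features(roi, prof, image)
  tf <- texture_features(gray_histogram(image, roi, levels))
  out <- c(unlist(sf, use.names = FALSE), unlist(tf, use.names = FALSE))
  names(out) <- feature_names
  out
}

#' Feature table over a list of images and masks
#'
#' One row per ROI with the 16 shape+texture columns, preceded by an `id`
#' column (and `class` when labels are given). ROIs whose extraction fails
#' are skipped with a warning naming the id.
#'
#' @param images list of gray images.
#' @param masks list of `roi_mask` objects (or logical matrices).
#' @param ids identifiers (default sequence numbers).
#' @param classes optional class labels per ROI.
#' @return data.frame with fixed, documented column order.
#' @export
feature_table <- function(images, masks, ids = seq_along(images),
                          classes = NULL) {
  stopifnot(length(images) == length(masks))
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    mk <- masks[[i]]
    if (!inherits(mk, "roi_mask")) mk <- roi_mask(mk)
    feat <- tryCatch(extract_features(images[[i]], mk), error = function(e) {
      warning("ROI ", ids[i], " skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(feat)) {
      row <- data.frame(id = ids[i], t(feat))
      if (!is.null(classes)) row$class <- classes[i]
      rows[[i]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Write / read a feature table as CSV
#'
#' Values are written with 17 significant digits so a round trip is exact to
#' formatting precision.
#'
#' @param tab data.frame from [feature_table()].
#' @param path CSV path.
#' @export
write_feature_csv <- function(tab, path) {
  out <- tab
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
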