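#' Normalize raw intensities to `[0, 1]`
#'
#' With a bit depth (or explicit maximum) the image is divided by the full
#' level range; with neither, the image is min-max scaled and a constant
#' image maps to 0.
#'
#' @param raw numeric matrix of raw intensities.
#' @param bit_depth 8 or 16, or NULL.
#' @param max_value explicit maximum level overriding `bit_depth`.
#' @return gray image matrix in `[0, 1]` (attribute `gray_image` set).
#' @export
normalize_intensity <- function(raw, bit_depth = 8, max_value = NULL) {
  if (length(raw) == 0L) stop("empty image")
  raw <- as.matrix(raw)
  if (!is.null(max_value)) {
    out <- raw / max_value
  } else if (!is.null(bit_depth)) {
    if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16")
    out <- raw / (2^bit_depth - 1)
  } else {
    rng <- range(raw)
    out <- if (diff(rng) == 0) raw * 0 else (raw - rng[1]) / diff(rng)
  }
  out <- pmin(pmax(out, 0), 1)
  gray_image(out)
}

#' Mark a matrix as a gray image
#'
#' @param m numeric matrix with values in `[0, 1]`.
#' @param provenance optional source note.
#' @export
gray_image <- function(m, provenance = NULL) {
  m <- as.matrix(m)
  if (any(!is.finite(m)) || any(m < 0 | m > 1)) {
    stop("gray image values must be finite and in [0, 1]")
  }
  attr(m, "gray_image") <- TRUE
  if (!is.null(provenance)) attr(m, "provenance") <- provenance
  m
}

# Reflect-pad a matrix by `r` pixels on every side.
reflect_pad <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  if (r >= nr || r >= nc) stop("padding exceeds image size")
  ri <- c(rev(seq_len(r) + 1L), seq_len(nr), nr - seq_len(r))
  ci <- c(rev(seq_len(r) + 1L), seq_len(nc), nc - seq_len(r))
  m[ri, ci]
}

#' Gaussian kernel matrix
#'
#' @param size odd kernel side length.
#' @param sigma standard deviation in pixels.
#' @return size x size kernel summing to 1.
#' @export
gaussian_kernel_2d <- function(size = 5, sigma = 2) {
  if (size %% 2 == 0) stop("kernel size must be odd")
  r <- (size - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  kern <- outer(g, g)
  kern / sum(kern)
}

#' Gaussian smoothing
#'
#' Convolution with a normalized size x size Gaussian kernel; borders are
#' handled by reflection, so a constant image is unchanged.
#'
#' @param image gray image matrix.
#' @param size odd kernel size (default 5).
#' @param sigma kernel standard deviation (default 2).
#' @export
gaussian_smooth <- function(image, size = 5, sigma = 2) {
  kern <- gaussian_kernel_2d(size, sigma)
  r <- (size - 1) / 2
  pad <- reflect_pad(image, r)
  out <- matrix(0, nrow(image), ncol(image))
  for (i in seq_len(size)) {
    for (j in seq_len(size)) {
      out <- out + kern[i, j] *
        pad[i:(i + nrow(image) - 1L), j:(j + ncol(image) - 1L)]
    }
  }
  if (!is.null(attr(image, "gray_image"))) out <- gray_image(pmin(pmax(out, 0), 1))
  out
}

#' Median filter
#'
#' Each pixel is replaced by the median of its size x size neighborhood
#' (reflected borders).
#'
#' @inheritParams gaussian_smooth
#' @param size odd window size (default 3).
#' @export
median_filter <- function(image, size = 3) {
  if (size %% 2 == 0) stop("window size must be odd")
  r <- (size - 1) / 2
  pad <- reflect_pad(image, r)
  n <- nrow(image); m <- ncol(image)
  stack <- matrix(0, n * m, size * size)
  col <- 0L
  for (i in seq_len(size)) {
    for (j in seq_len(size)) {
      col <- col + 1L
      stack[, col] <- pad[i:(i + n - 1L), j:(j + m - 1L)]
    }
  }
  med <- apply(stack, 1L, stats::median)
  out <- matrix(med, n, m)
  if (!is.null(attr(image, "gray_image"))) out <- gray_image(out)
  out
}

#' Noise specification
#'
#' @param kind "salt_pepper" or "gaussian".
#' @param level corruption level in percent, in (0, 100).
#' @param seed integer seed, recorded with the spec.
#' @export
noise_spec <- function(kind = c("salt_pepper", "gaussian"), level, seed) {
  kind <- match.arg(kind)
  if (level <= 0 || level >= 100) stop("noise level must be in (0, 100)")
  structure(list(kind = kind, level = level, seed = seed),
            class = "noise_spec")
}

#' Corrupt an image with noise
#'
#' Salt-and-pepper mode picks exactly `round(level/100 * N)` pixels without
#' replacement (seeded) and sets each to 0 or 1 with equal probability.
#' Gaussian mode adds zero-mean noise with sd = level/100 of the intensity
#' range, clipped to `[0, 1]`.
#'
#' @param image gray image matrix in `[0, 1]`.
#' @param spec a [noise_spec()].
#' @export
add_noise <- function(image, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  n <- length(image)
  out <- image
  if (spec$kind == "salt_pepper") {
    n_corrupt <- round(spec$level / 100 * n)
    draws <- with_seed(spec$seed, {
      idx <- sample.int(n, n_corrupt)
      vals <- sample(c(0, 1), n_corrupt, replace = TRUE)
      list(idx = idx, vals = vals)
    })
    out[draws$idx] <- draws$vals
  } else {
    noise <- with_seed(spec$seed, stats::rnorm(n, 0, spec$level / 100))
    out <- out + matrix(noise, nrow(image), ncol(image))
    out <- pmin(pmax(out, 0), 1)
  }
  gray_image(out)
}
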