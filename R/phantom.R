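# Phantom mammograms: a bright lesion on textured tissue over a dark
# background, with ground truth. Benign lesions are near-elliptical with a
# smooth boundary; malignant lesions carry seeded radial spicules (harmonic
# boundary modulation), so the class signal lives in the boundary shape and
# a slightly heavier lesion texture -- the same rationale the shape features
# (circularity, shape factor, radial-length spread) are built on.

#' Generate one phantom mammogram
#'
#' Deterministic given `seed`. Ground truth has three classes (0 background,
#' 1 tissue, 2 lesion) so k = 3 clustering has a meaningful target; the
#' binary lesion mask is the lesion class.
#'
#' @param size image side in pixels (>= 64, default 128).
#' @param class "benign" or "malignant".
#' @param contrast lesion-over-tissue intensity lift (default 0.35).
#' @param texture_sd standard deviation of the smooth background texture
#'   (default 0.05).
#' @param spicule_count number of spicule harmonics for malignant lesions
#'   (default drawn in 6..12).
#' @param seed integer seed (required).
#' @return a `phantom`: image, truth_mask, truth_labels, class, seed, noise.
#' @export
make_phantom <- function(size = 128, class = c("benign", "malignant"),
                         contrast = 0.35, texture_sd = 0.05,
                         spicule_count = NULL, seed) {
  class <- match.arg(class)
  if (size < 64) stop("size must be >= 64")
  p <- with_seed(seed, {
    ctr <- size / 2 + stats::runif(2, -size / 16, size / 16)
    r0 <- stats::runif(1, 0.09, 0.15) * size
    elong <- stats::runif(1, 1, 1.15)
    rot <- stats::runif(1, 0, base::pi)
    if (class == "malignant") {
      n_sp <- if (is.null(spicule_count)) sample(6:12, 1) else spicule_count
      harmonics <- 2:(n_sp + 1)
      amps <- stats::runif(length(harmonics), 0.05, 0.22 / sqrt(length(harmonics)) + 0.08)
      phases <- stats::runif(length(harmonics), 0, 2 * base::pi)
      elong <- stats::runif(1, 1.1, 1.5)
    } else {
      harmonics <- 2:3
      amps <- stats::runif(2, 0, 0.02)
      phases <- stats::runif(2, 0, 2 * base::pi)
    }
    noise_field <- matrix(stats::rnorm(size * size), size, size)
    extra_noise <- matrix(stats::rnorm(size * size), size, size)
    list(ctr = ctr, r0 = r0, elong = elong, rot = rot, harmonics = harmonics,
         amps = amps, phases = phases, noise_field = noise_field,
         extra_noise = extra_noise)
  })
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  dy <- rows - p$ctr[1]
  dx <- cols - p$ctr[2]
  # elliptical coordinates: stretch one principal axis by elong
  ca <- cos(p$rot); sa <- sin(p$rot)
  u <- (ca * dx + sa * dy) / p$elong
  v <- -sa * dx + ca * dy
  rad <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)
  mod <- rep(1, length(theta))
  for (h in seq_along(p$harmonics)) {
    mod <- mod + p$amps[h] * cos(p$harmonics[h] * theta + p$phases[h])
  }
  mod <- pmax(mod, 0.35)
  lesion <- matrix(rad <= p$r0 * mod, size, size)
  tissue_r <- 0.42 * size
  tissue <- matrix((dx^2 + dy^2) <= tissue_r^2, size, size)
  truth_labels <- matrix(0L, size, size)
  truth_labels[tissue] <- 1L
  truth_labels[lesion] <- 2L
  base_levels <- c(0.12, 0.38, 0.38 + contrast)
  img <- matrix(base_levels[truth_labels + 1L], size, size)
  # smooth correlated texture, rescaled to the requested sd
  tex <- gaussian_smooth(p$noise_field, size = 5, sigma = 1.2)
  tex <- tex / stats::sd(tex) * texture_sd
  img <- img + tex
  if (class == "malignant") {
    img[lesion] <- img[lesion] + p$extra_noise[lesion] * texture_sd * 0.5
  }
  img <- gray_image(pmin(pmax(img, 0), 1))
  structure(list(
    image = img,
    truth_mask = lesion,
    truth_labels = truth_labels,
    class = class,
    seed = seed,
    noise = NULL
  ), class = "phantom")
}

#' Generate a labeled phantom dataset
#'
#' Per-phantom seeds are drawn (reproducibly) from the master seed, so the
#' whole suite regenerates identically from one integer.
#'
#' @param n_benign,n_malignant phantoms per class (>= 1 each). The study
#'   population the generator emulates has 63 benign and 51 malignant cases.
#' @param seed master seed.
#' @param ... passed to [make_phantom()].
#' @return list of `phantom` objects, benign first.
#' @export
make_labeled_dataset <- function(n_benign, n_malignant, seed, ...) {
  n <- n_benign + n_malignant
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  classes <- rep(c("benign", "malignant"), c(n_benign, n_malignant))
  lapply(seq_len(n), function(i) {
    make_phantom(class = classes[i], seed = seeds[i], ...)
  })
}

#' Corrupt phantoms at several noise levels
#'
#' @param phantoms list of `phantom` objects.
#' @param levels noise percentages (default c(5, 7, 9)).
#' @param seed master seed for the corruption draws.
#' @param kind noise kind for [noise_spec()].
#' @return nested list: `[[level]][[phantom]]`, each a phantom whose image is
#'   corrupted and whose `noise` field records the spec; truth unchanged.
#' @export
noise_sweep_suite <- function(phantoms, levels = c(5, 7, 9), seed,
                              kind = "salt_pepper") {
  seeds <- with_seed(seed,
    matrix(sample.int(.Machine$integer.max - 1L,
                      length(levels) * length(phantoms)),
           nrow = length(levels)))
  out <- lapply(seq_along(levels), function(li) {
    lapply(seq_along(phantoms), function(pi_) {
      ph <- phantoms[[pi_]]
      spec <- noise_spec(kind, levels[li], seeds[li, pi_])
      ph$image <- add_noise(ph$image, spec)
      ph$noise <- spec
      ph
    })
  })
  names(out) <- paste0("level_", levels)
  out
}
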