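test_that("roi_mask_from_labels keeps the largest 8-connected component", {
  lab <- matrix(0L, 30, 30)
  lab[5:14, 5:14] <- 1L        # 100 px blob
  lab[22:24, 22:25] <- 1L      # 12 px blob
  roi <- roi_mask_from_labels(lab, 1L)
  expect_equal(roi$area, 100)
  expect_equal(unname(roi$centroid), c(9.5, 9.5))
  expect_error(roi_mask_from_labels(lab, 3L), "absent")
  tiny <- matrix(0L, 10, 10); tiny[5, 5] <- 1L
  expect_error(roi_mask_from_labels(tiny, 1L), "< 9")
})

test_that("radial_profile of a disk is flat and normalized", {
  roi <- roi_mask(disk_mask(20))
  prof <- radial_profile(roi)
  expect_length(prof$rl, 32)
  expect_true(all(abs(prof$rl - 20) <= 0.5))
  expect_true(all(prof$nrl >= 0.975 & prof$nrl <= 1))
  expect_equal(max(prof$nrl), 1)
})

test_that("radial_profile resolves a 2:1 ellipse axis ratio", {
  roi <- roi_mask(ellipse_mask(40, 20))
  prof <- radial_profile(roi)
  expect_equal(max(prof$rl) / min(prof$rl), 2, tolerance = 0.1)
})

test_that("shape_features match closed forms for disk and square", {
  img_big <- gray_image(matrix(0.5, 77, 77))
  roi_d <- roi_mask(disk_mask(30))
  sf_d <- shape_features(roi_d, radial_profile(roi_d), img_big)
  expect_lte(abs(sf_d$circularity), 0.15)  # circle: circularity ~ 0
  sq <- roi_mask(square_mask(50))
  img_sq <- gray_image(matrix(0.5, 70, 70))
  sf_s <- shape_features(sq, radial_profile(sq), img_sq)
  expect_lt(abs(sf_s$shape_factor - 16), 0.1 * 16)
  expect_lt(abs(sf_s$circularity - (1 - base::pi / 4)), 0.1)
  # a disk is rounder than a square on both descriptors
  expect_lt(sf_d$shape_factor, sf_s$shape_factor)
})

test_that("ncps is zero for a centered dark pixel, nrl stats degenerate for a disk", {
  m <- disk_mask(15)
  img <- matrix(0.8, nrow(m), ncol(m))
  ctr <- round(nrow(m) / 2)
  img[ctr, ctr] <- 0.1
  roi <- roi_mask(m)
  sf <- shape_features(roi, radial_profile(roi), gray_image(img))
  expect_lte(sf$ncps, 1.5 / sqrt(roi$area / base::pi))
  expect_lte(sf$nrl_sigma, 0.02)
  expect_lte(sf$nrl_entropy, 0.5)
})

test_that("gray_histogram is a normalized masked histogram", {
  img <- gray_image(matrix(c(rep(0.25, 8), rep(0.75, 8)), 4))
  mask <- matrix(TRUE, 4, 4)
  h <- gray_histogram(img, mask, levels = 256)
  expect_equal(sum(h), 1)
  expect_equal(sum(h > 0), 2)
  expect_equal(unname(h[h > 0]), c(0.5, 0.5))
  hc <- gray_histogram(flat_image(0.5, 4), matrix(TRUE, 4, 4))
  expect_equal(max(hc), 1)
  expect_error(gray_histogram(img, matrix(FALSE, 4, 4)), "empty mask")
})

test_that("texture_features reproduce hand-computed moments", {
  # delta histogram
  h <- c(1, rep(0, 9))
  tf <- texture_features(h, levels = seq(0, 1, length.out = 10))
  expect_equal(tf$sigma, 0)
  expect_equal(tf$smoothness, 0)
  expect_equal(tf$uniformity, 1)
  expect_equal(tf$entropy, 0)
  expect_equal(tf$skewness, 0)
  expect_equal(tf$kurtosis, 0)
  # uniform over 4 levels
  tf4 <- texture_features(rep(0.25, 4), levels = c(0, 1/3, 2/3, 1))
  expect_equal(tf4$mean, 0.5)
  expect_equal(tf4$uniformity, 0.25)
  expect_equal(tf4$entropy, 2)
  # two-point histogram on {0, 1}
  tf2 <- texture_features(c(0.5, 0.5), levels = c(0, 1))
  expect_equal(tf2$mean, 0.5)
  expect_equal(tf2$sigma, 0.5)
  expect_equal(tf2$smoothness, 0.2)
  expect_equal(tf2$skewness, 0)
  expect_equal(tf2$kurtosis, 0.0625)
  expect_error(texture_features(c(0.5, 0.4)), "normalized")
})

test_that("texture features depend only on the histogram", {
  set.seed(8)
  img <- gray_image(matrix(runif(400), 20))
  mask <- matrix(FALSE, 20, 20); mask[5:16, 5:16] <- TRUE
  tf1 <- texture_features(gray_histogram(img, mask))
  # spatially permute the masked pixels
  img2 <- img
  idx <- which(mask)
  img2[idx] <- img[sample(idx)]
  tf2 <- texture_features(gray_histogram(gray_image(img2), mask))
  expect_equal(tf1, tf2)
})

test_that("features are invariant to whole-pixel translation", {
  ph <- make_phantom(size = 96, class = "malignant", seed = 55)
  mask <- ph$truth_mask
  f1 <- extract_features(ph$image, roi_mask(mask))
  sh <- function(m, dr, dc) {
    out <- matrix(m[1], nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  img2 <- gray_image(sh(unclass(ph$image), 3, 5))
  mask2 <- sh(mask, 3, 5) > 0
  f2 <- extract_features(img2, roi_mask(mask2))
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("doubling a disk radius preserves shape ratios and scales area", {
  img1 <- gray_image(matrix(0.5, 57, 57))
  img2 <- gray_image(matrix(0.5, 97, 97))
  r1 <- roi_mask(disk_mask(20)); r2 <- roi_mask(disk_mask(40))
  s1 <- shape_features(r1, radial_profile(r1), img1)
  s2 <- shape_features(r2, radial_profile(r2), img2)
  expect_equal(s2$area / s1$area, 4, tolerance = 0.05)
  expect_lt(abs(s1$circularity - s2$circularity), 0.1)
  expect_lt(abs(s1$nrl_mean - s2$nrl_mean), 0.02)
})

test_that("feature_table builds 16 columns and round-trips through CSV", {
  phs <- lapply(1:3, function(s) make_phantom(size = 64, seed = 40 + s,
                                              class = "benign"))
  tab <- feature_table(lapply(phs, `[[`, "image"),
                       lapply(phs, `[[`, "truth_mask"),
                       ids = c("a", "b", "c"),
                       classes = rep("benign", 3))
  expect_equal(nrow(tab), 3)
  expect_true(all(ipfcm:::feature_names %in% names(tab)))
  expect_length(ipfcm:::feature_names, 16)
  path <- file.path(tempdir(), "feat.csv")
  write_feature_csv(tab, path)
  back <- read_feature_csv(path)
  expect_equal(back[ipfcm:::feature_names], tab[ipfcm:::feature_names],
               tolerance = 1e-12)
  expect_identical(names(back), names(tab))
})
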