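# Segmentation, membrane restriction, macro/micro morphometry, blur, puncta.

test_that("blank images and stacks segment to zero clusters", {
  expect_equal(nrow(segment_2d(matrix(0, 50, 50), 20, 0.5)), 0)
  expect_equal(nrow(segment_3d(array(0, c(20, 20, 8)), c(100, 0.13), 0.5)), 0)
})

test_that("calibration is mandatory", {
  expect_error(segment_2d(matrix(0, 10, 10), threshold = 0.5), "pixel_nm")
  expect_error(segment_3d(array(0, c(5, 5, 5)), threshold = 0.5), "voxel_size")
  expect_error(segment_3d(array(0, c(5, 5, 5)), c(-1, 0.13), 0.5), "voxel_size")
})

test_that("a single rendered disk is recovered with its area", {
  f <- gen_localization_field(field_spec(2000, 2000, noise_sd = 0.02,
                                         seed = 4),
                              1, 2500, min_area_nm2 = 2499.9)
  cl <- segment_2d(f$image, 20, 0.5)
  expect_equal(nrow(cl), 1)
  expect_lt(abs(cl$area_nm2 - f$truth$area_nm2) / f$truth$area_nm2, 0.15)
})

test_that("a single rendered sphere is recovered with its volume", {
  st <- gen_confocal_stack(field_spec(4000, 4000, depth_um = 3, pixel_nm = 100,
                                      noise_sd = 0.02, seed = 9),
                           1, 0.09, membrane_shell("all"),
                           min_volume_um3 = 0.0899)
  cl <- segment_3d(st$stack, c(100, 0.13), 0.5)
  expect_equal(nrow(cl), 1)
  expect_lt(abs(cl$volume_um3 - st$truth$volume_um3) / st$truth$volume_um3,
            0.15)
})

test_that("generator -> segmenter -> fitter round trip holds at SNR 10", {
  counts_ok <- scale_err <- numeric(0)
  for (s in 1:8) {
    f <- gen_localization_field(
      field_spec(16000, 16000, noise_sd = 0.1, seed = 100 + s), 600, 2500)
    cl <- segment_2d(f$image, 20, 0.5)
    counts_ok <- c(counts_ok, abs(nrow(cl) - 600) / 600)
    fit <- fit_exponential(cl$area_nm2, min_size = 1200)
    truth_fit <- fit_exponential(f$truth$area_nm2, min_size = 1200)
    scale_err <- c(scale_err, abs(fit$scale - truth_fit$scale) / truth_fit$scale)
  }
  expect_true(all(counts_ok <= 0.05))
  expect_true(all(scale_err <= 0.10))
})

test_that("3D round trip recovers cluster count and volumes at SNR 10", {
  st <- small_stack(seed = 7, n = 150, mean_vol = 0.09, noise_sd = 0.1)
  cl <- segment_3d(st$stack, c(100, 0.13), 0.5)
  expect_lte(abs(nrow(cl) - 150) / 150, 0.05)
  expect_lt(abs(mean(cl$volume_um3) - mean(st$truth$volume_um3)) /
              mean(st$truth$volume_um3), 0.10)
  expect_true(all(cl$n_px >= 2))
})

test_that("raising the threshold never grows the total segmented size", {
  f <- small_field(seed = 55, n = 80)
  totals <- vapply(c(0.3, 0.5, 0.7, 0.9), function(thr) {
    sum(segment_2d(f$image, 20, thr)$n_px)
  }, numeric(1))
  expect_true(all(diff(totals) <= 0))
})

test_that("membrane restriction keeps exactly the constructed subset", {
  st <- small_stack(seed = 12, n = 30, mean_vol = 0.06)
  cl <- segment_3d(st$stack, c(100, 0.13), 0.45)
  expect_equal(nrow(cl), 30)

  # identity and annihilator masks
  all_mask <- array(TRUE, dim(st$stack))
  expect_equal(nrow(restrict_to_membrane(cl, all_mask)), nrow(cl))
  none_mask <- array(FALSE, dim(st$stack))
  expect_equal(nrow(restrict_to_membrane(cl, none_mask)), 0)

  # mask covering a known 60/40 split of the placed clusters
  keep_truth <- st$truth[1:18, ]
  mask <- array(FALSE, dim(st$stack))
  dm <- dim(st$stack)
  xc <- (seq_len(dm[1]) - 0.5) * 0.1
  yc <- (seq_len(dm[2]) - 0.5) * 0.1
  zc <- (seq_len(dm[3]) - 0.5) * 0.13
  for (i in seq_len(nrow(keep_truth))) {
    r <- (3 * keep_truth$volume_um3[i] / (4 * pi))^(1 / 3) + 0.05
    d2 <- outer(outer((xc - keep_truth$x_um[i])^2,
                      (yc - keep_truth$y_um[i])^2, "+"),
                (zc - keep_truth$z_um[i])^2, "+")
    mask <- mask | (d2 <= r^2)
  }
  kept <- restrict_to_membrane(cl, mask, rule = "any")
  expect_equal(nrow(kept), 18)
  expect_true(all(kept$membrane_overlap))
  # the kept centroids are the constructed in-mask ones
  match_truth <- vapply(seq_len(nrow(kept)), function(i) {
    which.min((st$truth$x_um - kept$x_um[i])^2 +
                (st$truth$y_um - kept$y_um[i])^2 +
                (st$truth$z_um - kept$z_um[i])^2)
  }, integer(1))
  expect_setequal(match_truth, 1:18)

  kept_c <- restrict_to_membrane(cl, mask, rule = "centroid")
  expect_equal(nrow(kept_c), 18)

  expect_error(restrict_to_membrane(cl, array(TRUE, c(2, 2, 2))),
               "do not match")
})

test_that("sphere diameter follows the closed form", {
  expect_equal(sphere_diameter_from_volume(0.09, round_to_nm = 10), 560)
  expect_equal(sphere_diameter_from_volume(pi / 6), 1000)
  expect_equal(sphere_diameter_from_volume(0.03), 385.5, tolerance = 1e-3)
  expect_error(sphere_diameter_from_volume(0), "positive")
  expect_error(sphere_diameter_from_volume(-1), "positive")
})

test_that("macro/micro classification uses a strict volume threshold", {
  fr <- macro_micro_fractions(c(0.01, 0.05), macro_threshold(0.03))
  expect_equal(fr$macro_pct, 50)
  expect_equal(fr$micro_pct, 50)

  at_thr <- macro_micro_fractions(rep(0.03, 10), macro_threshold(0.03))
  expect_equal(at_thr$macro_pct, 0)

  cl <- classify_macro_micro(c(0.029, 0.031))
  expect_equal(as.character(cl$class), c("micro", "macro"))

  # invariance under unit-consistent rescaling
  sizes <- gen_cluster_sizes(400, 0.05, seed = 3)
  a <- macro_micro_fractions(sizes, macro_threshold(0.03))
  b <- macro_micro_fractions(sizes * 1e9, macro_threshold(0.03 * 1e9))
  expect_equal(a$macro_pct, b$macro_pct)

  df2d <- tibble::tibble(area_nm2 = c(1000, 2000))
  expect_error(classify_macro_micro(df2d), "unit mismatch")
})

test_that("macro fraction of exponential volumes matches the closed form", {
  sizes <- gen_cluster_sizes(5000, 0.14, seed = 8)
  fr <- macro_micro_fractions(sizes, macro_threshold(0.03))
  expect_lt(abs(fr$macro_pct - 100 * exp(-0.03 / 0.14)), 3)
  expect_equal(fr$macro_pct + fr$micro_pct, 100)
})

test_that("resolution-matching blur conserves mass and merges close points", {
  img <- matrix(0, 120, 120); img[60, 60] <- 1
  b <- gaussian_blur_match(img, 20, 200)
  expect_lt(abs(sum(b) - 1), 1e-6)

  flat <- matrix(1, 60, 60)
  bf <- gaussian_blur_match(flat, 20, 200)
  expect_lt(max(abs(bf - 1)), 1e-9)

  two_points <- function(sep_nm) {
    im <- matrix(0, 120, 120)
    im[50, 60] <- 1
    im[50 + round(sep_nm / 20), 60] <- 1
    bb <- gaussian_blur_match(im, 20, 200)
    lab <- segment_2d(bb, 20, 0.5 * max(bb), min_px = 1)
    nrow(lab)
  }
  expect_equal(two_points(150), 1)
  expect_equal(two_points(400), 2)

  expect_error(gaussian_blur_match(img, 20, 10), "smaller than one pixel")
})

test_that("cluster summaries do the membrane arithmetic", {
  one <- tibble::tibble(volume_um3 = 0.05, footprint_um2 = 0.5)
  s <- summarize_clusters(one, cell_reference = 100, membrane_area_um2 = 10)
  expect_equal(s$pct_membrane_occupied, 5)
  expect_equal(s$clusters_per_cell, 1)

  dup <- dplyr::bind_rows(one, one)
  s2 <- summarize_clusters(dup, cell_reference = 100, membrane_area_um2 = 10)
  expect_equal(s2$clusters_per_cell, 2)
  expect_equal(s2$mean_size, s$mean_size)
  expect_equal(s2$total_size, 2 * s$total_size)

  s0 <- summarize_clusters(tibble::tibble(volume_um3 = numeric()),
                           cell_reference = 50)
  expect_equal(s0$clusters_per_cell, 0)
  expect_equal(s0$total_size, 0)
})

test_that("summaries of a synthetic field match the known truth", {
  f <- small_field(seed = 77, n = 120, width = 10000)
  cl <- segment_2d(f$image, 20, 0.5)
  s <- summarize_clusters(cl, cell_reference = 100, membrane_area_um2 = 100)
  expect_lte(abs(s$clusters_per_cell - 120), 2)  # rare chance adjacencies merge
  truth_pct <- 100 * sum(f$truth$area_nm2) / 1e6 / 100
  expect_lt(abs(s$pct_membrane_occupied - truth_pct) / truth_pct, 0.1)
})

test_that("puncta density is count over area", {
  expect_equal(puncta_density(0, 100), 0)
  expect_equal(puncta_density(35, 1000), 0.035)
  expect_error(puncta_density(10, 0), "cell_area_um2")

  lambda <- 0.05; area <- 4000
  n <- withr::with_seed(5, rpois(1, lambda * area))
  d <- puncta_density(n, area)
  expect_lt(abs(d - lambda), 3 * sqrt(lambda / area))
})
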