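# Generators: determinism, ground-truth statistics, and degenerate inputs.

test_that("localization field handles the empty case and is seed-deterministic", {
  spec <- field_spec(2000, 2000, noise_sd = 0.1, seed = 5)
  blank <- gen_localization_field(spec, 0, 2500)
  expect_equal(nrow(blank$truth), 0)
  expect_lt(max(abs(blank$image)), 1)  # noise only, no unit-intensity disks

  a <- gen_localization_field(spec, 20, 2500)
  b <- gen_localization_field(spec, 20, 2500)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)

  spec2 <- field_spec(2000, 2000, noise_sd = 0.1, seed = 6)
  c <- gen_localization_field(spec2, 20, 2500)
  expect_false(identical(a$image, c$image))
})

test_that("drawn cluster areas have the requested mean", {
  f <- gen_localization_field(field_spec(44000, 44000, seed = 1), 5000, 2500)
  expect_equal(nrow(f$truth), 5000)
  expect_lt(abs(mean(f$truth$area_nm2) - 2500) / 2500, 0.05)
  expect_true(all(f$truth$area_nm2 > 0))
})

test_that("overfull fields fail with a density message", {
  expect_error(
    gen_localization_field(field_spec(1000, 1000, seed = 1), 400, 2500,
                           max_retries = 50),
    "density")
})

test_that("confocal stack ground truth matches request and respects the mask", {
  st <- small_stack(seed = 3, n = 200, mean_vol = 0.09,
                    shell = membrane_shell("all"))
  expect_equal(nrow(st$truth), 200)
  expect_lt(abs(mean(st$truth$volume_um3) - 0.09) / 0.09, 0.10)

  sh <- gen_confocal_stack(
    field_spec(8000, 8000, depth_um = 4, pixel_nm = 100, noise_sd = 0,
               seed = 4),
    30, 0.06, membrane_shell("ellipsoid", thickness_um = 1.2))
  # centroids inside the mask by construction
  vox <- cbind(pmin(pmax(round(sh$truth$x_um / 0.1 + 0.5), 1), dim(sh$mask)[1]),
               pmin(pmax(round(sh$truth$y_um / 0.1 + 0.5), 1), dim(sh$mask)[2]),
               pmin(pmax(round(sh$truth$z_um / 0.13 + 0.5), 1), dim(sh$mask)[3]))
  expect_true(all(sh$mask[vox]))
})

test_that("fully contained placement keeps nearly all intensity inside the mask", {
  sh <- gen_confocal_stack(
    field_spec(8000, 8000, depth_um = 4, pixel_nm = 100, noise_sd = 0,
               seed = 9),
    25, 0.06, membrane_shell("ellipsoid", thickness_um = 1.6),
    contain = "full")
  inside <- sum(sh$stack[sh$mask])
  expect_gte(inside / sum(sh$stack), 0.99)
})

test_that("shells thinner than one voxel are rejected", {
  expect_error(
    gen_confocal_stack(field_spec(4000, 4000, depth_um = 2, pixel_nm = 100,
                                  seed = 1),
                       5, 0.09, membrane_shell("ellipsoid", 0.05)),
    "thinner than one")
})

test_that("rendered intensity mass tracks drawn size", {
  f <- gen_localization_field(field_spec(8000, 8000, noise_sd = 0, seed = 2),
                              40, 3000)
  cl <- segment_2d(f$image, 20, 0.5)
  # match each truth cluster to nearest segmented centroid
  idx <- vapply(seq_len(nrow(f$truth)), function(i) {
    which.min((cl$x_nm - f$truth$x_nm[i])^2 + (cl$y_nm - f$truth$y_nm[i])^2)
  }, integer(1))
  expect_gt(cor(f$truth$area_nm2, cl$area_nm2[idx], method = "spearman"), 0.99)
})

test_that("gen_cluster_sizes is an exponential sampler", {
  expect_length(gen_cluster_sizes(1, 0.08, seed = 3), 1)
  expect_gt(gen_cluster_sizes(1, 0.08, seed = 3), 0)
  s <- gen_cluster_sizes(5000, 0.08, seed = 1)
  expect_lt(abs(mean(s) - 0.08) / 0.08, 0.05)
  expect_identical(s, gen_cluster_sizes(5000, 0.08, seed = 1))
  expect_error(gen_cluster_sizes(10, 0), "scale")
  expect_error(gen_cluster_sizes(0, 1), "n")
})

test_that("sampled sizes pass a KS test against the generating law", {
  pass <- vapply(1:100, function(s) {
    x <- gen_cluster_sizes(400, 0.08, seed = s)
    stats::ks.test(x, stats::pexp, rate = 1 / 0.08)$p.value > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("sparklet traces encode the gating ground truth", {
  prm <- coupled_gating_params(3, 0.1, kappa = 0, n_frames = 500, seed = 7)
  tr0 <- gen_sparklet_trace(prm, quantal_df = 2, noise_sd = 0)
  expect_equal(tr0$df / 2, as.numeric(tr0$k_true))

  prm1 <- coupled_gating_params(3, 0.3, kappa = 1, n_frames = 2000, seed = 8)
  tr1 <- gen_sparklet_trace(prm1, quantal_df = 1, noise_sd = 0.05)
  expect_true(all(tr1$k_true %in% c(0L, 3L)))
  expect_true(all(abs(tr1$df - tr1$k_true) < 0.4))

  prm2 <- coupled_gating_params(3, 0.1, kappa = 0, n_frames = 20000, seed = 9)
  k <- gen_sparklet_trace(prm2, 1, 0)$k_true
  se <- sqrt(3 * 0.1 * 0.9 / 20000)
  expect_lt(abs(mean(k) - 0.3), 3 * se)

  expect_error(coupled_gating_params(0, 0.1), "n_channels")
})
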