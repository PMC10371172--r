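# Lattice self-assembly: update rules, bookkeeping, steady state, and the
# exponential / parameter fitters.

test_that("no nucleation from an empty lattice means no clusters ever", {
  res <- simulate_assembly(assembly_params(0, 0.5, 0.1, 32, 32, 200, seed = 1))
  expect_length(res$sizes, 0)
  expect_true(all(res$trace$occupancy == 0))
})

test_that("pure nucleation in the sparse regime yields mostly singletons", {
  frac <- vapply(1:50, function(s) {
    res <- simulate_assembly(assembly_params(1, 0, 0, 256, 256, 100, seed = s))
    mean(res$sizes == 1)
  }, numeric(1))
  expect_true(all(frac >= 0.9))
})

test_that("channel-count bookkeeping is exact at every step", {
  res <- simulate_assembly(assembly_params(0.6, 0.3, 0.05, 64, 64, 500,
                                           seed = 2))
  tr <- res$trace
  expect_identical(diff(c(0L, tr$occupancy)), tr$inserted - tr$removed)
  expect_equal(tail(tr$occupancy, 1), sum(res$lattice))
})

test_that("without removal, occupancy never decreases", {
  res <- simulate_assembly(assembly_params(0.5, 0.3, 0, 64, 64, 400, seed = 3))
  expect_true(all(diff(res$trace$occupancy) >= 0))
})

test_that("a step applies nucleation and growth before removal", {
  # with P_r = 1 every channel inserted in a step is removed in that same
  # step, so the lattice is empty after each step; the opposite ordering
  # would leave the newly nucleated channel behind
  res <- simulate_assembly(assembly_params(1, 1, 1, 32, 32, 50, seed = 4))
  expect_true(all(res$trace$occupancy == 0))
  expect_true(all(res$trace$inserted == res$trace$removed))
  expect_true(all(res$trace$inserted >= 1))
})

test_that("identical parameters and seed give an identical final lattice", {
  p <- assembly_params(0.4, 0.2, 0.03, 48, 48, 300, seed = 11)
  expect_identical(simulate_assembly(p)$lattice, simulate_assembly(p)$lattice)
})

test_that("steady-state mean cluster size grows with the growth probability", {
  mean_size <- function(p_g, seed) {
    r <- reach_steady_state(assembly_params(0.4, p_g, 0.06, 96, 96, 4000,
                                            seed = seed),
                            window = 300, tol = 0.03)
    mean(r$sizes)
  }
  sweeps <- vapply(1:12, function(s) {
    vapply(c(0.05, 0.2, 0.5), mean_size, numeric(1), seed = s)
  }, numeric(3))
  avg <- rowMeans(sweeps)
  expect_true(all(diff(avg) > 0))
})

test_that("reach_steady_state flags monotone growth and trivial stasis", {
  # pure nucleation without removal: occupancy grows linearly and never
  # stabilizes within the cap (grid large enough not to saturate)
  grow <- reach_steady_state(assembly_params(0.8, 0, 0, 128, 128, 1500,
                                             seed = 5),
                             window = 100, tol = 0.01)
  expect_false(grow$converged)
  expect_equal(grow$steps_used, 1500)

  still <- reach_steady_state(assembly_params(0, 0, 0, 32, 32, 5000, seed = 6),
                              window = 100)
  expect_true(still$converged)
  expect_lte(still$steps_used, 200)

  bal <- reach_steady_state(assembly_params(0.5, 0.2, 0.05, 96, 96, 6000,
                                            seed = 7),
                            window = 300, tol = 0.03)
  expect_true(bal$converged)
  expect_lt(bal$steps_used, 6000)
  # occupancy stationary thereafter: continue and compare windowed means
  cont <- simulate_assembly(assembly_params(0.5, 0.2, 0.05, 96, 96, 600,
                                            seed = 8),
                            lattice = bal$lattice)
  m1 <- mean(head(cont$trace$occupancy, 300))
  m2 <- mean(tail(cont$trace$occupancy, 300))
  expect_lt(abs(m2 - m1) / m1, 0.1)
})

test_that("fit_exponential recovers the sampler scale and flags degeneracy", {
  s <- gen_cluster_sizes(5000, 0.08, seed = 21)
  expect_lt(abs(fit_exponential(s)$scale - 0.08) / 0.08, 0.05)

  expect_error(fit_exponential(rep(1, 100)), "degenerate")
  expect_error(fit_exponential(c(1, 2)), "at least 30")

  f <- fit_exponential(gen_cluster_sizes(3000, 2500, seed = 22))
  expect_gte(f$r_squared, 0.95)
  expect_true(f$r_squared <= 1)
  expect_gt(f$amplitude, 0)
})

test_that("tidy and glance views of an exponential fit are well formed", {
  f <- fit_exponential(gen_cluster_sizes(500, 10, seed = 1))
  td <- tidy(f)
  expect_named(td, c("term", "estimate"))
  expect_setequal(td$term, c("scale", "amplitude", "min_size"))
  gl <- glance(f)
  expect_equal(gl$nobs, 500)
})

test_that("a single-point grid is returned as-is with its distance", {
  obs <- simulate_assembly(assembly_params(0.5, 0.2, 0.05, 64, 64, 500,
                                           seed = 31))$sizes
  g <- data.frame(p_n = 0.3, p_g = 0.1, p_r = 0.05)
  fit <- fit_assembly_params(obs, g, grid_w = 64, grid_h = 64, n_steps = 400)
  expect_equal(fit$best$p_n, 0.3)
  expect_true(fit$distance >= 0 && fit$distance <= 1)
  expect_error(fit_assembly_params(obs, g[0, ]), "empty")
})

test_that("WT-like distributions fit larger nucleation/growth than mutant-like", {
  wt_like <- simulate_assembly(assembly_params(0.7, 0.35, 0.05, 96, 96, 900,
                                               seed = 41))$sizes
  mut_like <- simulate_assembly(assembly_params(0.2, 0.08, 0.05, 96, 96, 900,
                                                seed = 42))$sizes
  g <- expand.grid(p_n = c(0.2, 0.7), p_g = c(0.08, 0.35), p_r = 0.05)
  fit_wt <- fit_assembly_params(wt_like, g, grid_w = 96, grid_h = 96,
                                n_steps = 900, seed = 43)
  fit_mut <- fit_assembly_params(mut_like, g, grid_w = 96, grid_h = 96,
                                 n_steps = 900, seed = 44)
  expect_gte(fit_wt$best$p_g, fit_mut$best$p_g)
  expect_gt(fit_wt$best$p_n * fit_wt$best$p_g,
            fit_mut$best$p_n * fit_mut$best$p_g)
})
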