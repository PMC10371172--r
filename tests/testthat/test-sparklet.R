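# Coupled gating simulation, idealization, nPs, and the kappa estimator.

test_that("fully coupled sites are all-or-none, independent sites binomial", {
  k1 <- simulate_coupled_gating(coupled_gating_params(4, 0.2, 1, 5000,
                                                      seed = 1))
  expect_true(all(k1 %in% c(0L, 4L)))

  k0 <- simulate_coupled_gating(coupled_gating_params(3, 0.1, 0, 20000,
                                                      seed = 2))
  se <- sqrt(3 * 0.1 * 0.9 / 20000)
  expect_lt(abs(mean(k0) - 0.3), 3 * se)
})

test_that("coupling inflates frame-wise variance above the binomial floor", {
  n <- 4; p <- 0.15
  v_ind <- var(simulate_coupled_gating(
    coupled_gating_params(n, p, 0, 40000, seed = 3)))
  v_mid <- var(simulate_coupled_gating(
    coupled_gating_params(n, p, 0.5, 40000, seed = 4)))
  floor_var <- n * p * (1 - p)
  expect_lt(abs(v_ind - floor_var) / floor_var, 0.1)
  expect_gt(v_mid, floor_var * 1.5)
})

test_that("the per-channel marginal open probability is kappa-invariant", {
  for (kap in c(0, 0.5, 1)) {
    k <- simulate_coupled_gating(coupled_gating_params(3, 0.2, kap, 30000,
                                                       seed = 10 + kap * 10))
    expect_lt(abs(mean(k) / 3 - 0.2), 0.01)
  }
})

test_that("idealization recovers noiseless gating and bounds errors at SNR 5", {
  prm <- coupled_gating_params(3, 0.15, 0.2, 5000, seed = 5)
  tr0 <- gen_sparklet_trace(prm, 1, 0)
  expect_equal(idealize_trace(tr0, 1, 3)$k, tr0$k_true)

  base <- tibble::tibble(df = rnorm(1000, 0, 0.05))
  expect_true(all(idealize_trace(base, 1, 3)$k == 0))

  prm2 <- coupled_gating_params(3, 0.15, 0.2, 20000, seed = 6)
  tr <- gen_sparklet_trace(prm2, 1, 0.2)
  expect_lt(mean(idealize_trace(tr, 1, 3)$k != tr$k_true), 0.02)

  expect_error(idealize_trace(tr0, quantal_df = 0), "quantal_df")
})

test_that("quantal amplitude estimation recovers the generating spacing", {
  tr <- gen_sparklet_trace(coupled_gating_params(3, 0.2, 0.3, 3000, seed = 5),
                           1.0, 0.15)
  expect_lt(abs(estimate_quantal_amplitude(tr) - 1), 0.05)

  two <- tibble::tibble(df = rep(c(0, 2), each = 60))
  expect_equal(estimate_quantal_amplitude(two), 2.0, tolerance = 1e-6)

  flat <- tibble::tibble(df = withr::with_seed(1, rnorm(500, 0, 0.1)))
  expect_error(estimate_quantal_amplitude(flat), "unimodal")
})

test_that("nPs is the time-averaged open-channel count", {
  expect_equal(compute_nps(rep(0L, 100)), 0)
  expect_equal(compute_nps(c(1L, 1L, 0L, 0L)), 0.5)
  expect_error(compute_nps(integer(0)), "empty")

  k <- simulate_coupled_gating(coupled_gating_params(3, 0.1, 0, 20000,
                                                     seed = 7))
  expect_equal(compute_nps(k), sum(k) / length(k))  # brute-force identity
  expect_lt(abs(compute_nps(k) - 0.3), 3 * sqrt(3 * 0.1 * 0.9 / 20000))

  # invariance to quantal amplitude
  prm <- coupled_gating_params(2, 0.2, 0.4, 2000, seed = 8)
  for (q in c(0.5, 1, 3)) {
    tr <- gen_sparklet_trace(prm, q, 0)
    expect_equal(compute_nps(idealize_trace(tr, q, 2)),
                 compute_nps(tr$k_true))
  }
})

test_that("sites split into low and high activity at the 0.2 cutoff", {
  expect_equal(as.character(classify_site(0.06)), "low")
  expect_equal(as.character(classify_site(0.29)), "high")
  expect_equal(as.character(classify_site(0.2)), "high")  # boundary is high
  expect_error(classify_site(-0.1), "nps")
})

test_that("kappa is recovered and matches the brute-force grid oracle", {
  for (kap in c(0, 0.3, 0.7)) {
    errs <- gaps <- numeric(0)
    for (s in 1:5) {
      k <- simulate_coupled_gating(
        coupled_gating_params(4, 0.1, kap, 20000, seed = 50 + s))
      fit <- estimate_kappa(k, 4, n_boot = 0)
      errs <- c(errs, abs(fit$kappa - kap))
      gaps <- c(gaps, abs(fit$kappa - kappa_grid_oracle(k, 4)))
    }
    expect_lte(mean(errs), 0.05)
    expect_true(all(gaps <= 0.001))
  }
})

test_that("all-or-none records give kappa = 1 and boundary cases warn", {
  k <- c(rep(0L, 400), rep(4L, 100))
  fit <- estimate_kappa(k, 4, n_boot = 0)
  expect_equal(fit$kappa, 1)

  expect_warning(estimate_kappa(rep(2L, 100), 4, n_boot = 0), "unidentifiable")
  expect_error(estimate_kappa(k, n_channels = 1), "n_channels")
})

test_that("the likelihood at the estimate dominates both endpoints", {
  k <- simulate_coupled_gating(coupled_gating_params(3, 0.15, 0.4, 10000,
                                                     seed = 60))
  fit <- estimate_kappa(k, 3, n_boot = 0)
  counts <- tabulate(k + 1L, nbins = 4L)
  ll <- function(kp) chancluster:::kappa_loglik(kp, counts, 3, fit$p_open)
  expect_gte(fit$log_lik, ll(0))
  expect_gte(fit$log_lik, ll(1))
})

test_that("bootstrap intervals are ordered, bounded, and cover the estimate", {
  k <- simulate_coupled_gating(coupled_gating_params(3, 0.15, 0.5, 5000,
                                                     seed = 61))
  fit <- estimate_kappa(k, 3, n_boot = 200)
  expect_true(fit$conf_low <= fit$kappa && fit$kappa <= fit$conf_high)
  expect_true(fit$conf_low >= 0 && fit$conf_high <= 1)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "kappa"], fit$kappa)
})

test_that("analyze_sparklet assembles the per-site report", {
  tr <- gen_sparklet_trace(coupled_gating_params(3, 0.2, 0.5, 4000, seed = 70),
                           1, 0.15)
  rep <- analyze_sparklet(tr)
  expect_lt(abs(rep$quantal_df - 1), 0.05)
  expect_gte(rep$n_quantal_levels, 2)
  expect_true(rep$kappa >= 0 && rep$kappa <= 1)
  expect_equal(as.character(rep$activity_class),
               ifelse(rep$nps >= 0.2, "high", "low"))
})
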