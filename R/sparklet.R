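#' Parameters for coupled two-state channel gating
#'
#' Generative model for the joint gating of `n_channels` two-state channels
#' at one sparklet site. Each frame, with probability `kappa` a coordination
#' event forces every channel into one common state (open with probability
#' `p_open`); otherwise each channel opens independently with probability
#' `p_open`. The per-channel marginal open probability is exactly `p_open`
#' for every `kappa`; `kappa = 0` gives independent binomial gating and
#' `kappa = 1` all-or-none gating. Frames are exchangeable (no dwell-time
#' kinetics are modeled).
#'
#' @param n_channels Number of channels at the site (>= 1).
#' @param p_open Per-channel marginal open probability, in (0, 1).
#' @param kappa Coupling coefficient, in `[0, 1]`.
#' @param n_frames Number of frames to simulate.
#' @param seed RNG seed.
#' @return A `coupled_gating_params` object.
#' @examples
#' coupled_gating_params(3, 0.1, kappa = 0.5, n_frames = 1000)
#' @export
coupled_gating_params <- function(n_channels, p_open, kappa = 0,
                                  n_frames = 2000, seed = 1L) {
  check_count(n_channels, "n_channels", lower = 1L)
  check_number(p_open, "p_open", lower = 1e-12, upper = 1 - 1e-12)
  check_prob(kappa, "kappa")
  check_count(n_frames, "n_frames", lower = 1L)
  check_count(seed, "seed")
  structure(list(n_channels = as.integer(n_channels), p_open = p_open,
                 kappa = kappa, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "coupled_gating_params")
}

#' Simulate the open-channel count of a coupled sparklet site
#'
#' @param params A [coupled_gating_params()].
#' @return Integer vector `k(t)` of per-frame open-channel counts in
#'   `[0, n_channels]`.
#' @examples
#' k <- simulate_coupled_gating(coupled_gating_params(3, 0.1, 1, 500))
#' unique(k)  # fully coupled: only 0 and 3
#' @export
simulate_coupled_gating <- function(params) {
  stopifnot(inherits(params, "coupled_gating_params"))
  withr::with_seed(params$seed, {
    t_n <- params$n_frames
    coord <- runif(t_n) < params$kappa
    common <- runif(t_n) < params$p_open
    indep <- rbinom(t_n, params$n_channels, params$p_open)
    as.integer(ifelse(coord, common * params$n_channels, indep))
  })
}

#' Generate a synthetic sparklet fluorescence trace with known gating
#'
#' The trace at frame t is `k(t) * quantal_df` plus Gaussian noise, where
#' `k(t)` is the simulated open-channel count — the quantal staircase seen in
#' TIRF sparklet records.
#'
#' @param params A [coupled_gating_params()].
#' @param quantal_df Fluorescence amplitude of one open channel (> 0).
#' @param noise_sd Additive Gaussian noise SD (>= 0).
#' @param fs_hz Sampling rate, Hz (default 100).
#' @return A tibble of class `sparklet_trace`: `time_s`, `df` (fluorescence),
#'   `k_true` (ground-truth open count); `quantal_df` and `fs_hz` ride along
#'   as attributes.
#' @examples
#' tr <- gen_sparklet_trace(coupled_gating_params(3, 0.1, 0, 200), 1, 0.1)
#' head(tr)
#' @export
gen_sparklet_trace <- function(params, quantal_df = 1, noise_sd = 0.1,
                               fs_hz = 100) {
  stopifnot(inherits(params, "coupled_gating_params"))
  check_number(quantal_df, "quantal_df", lower = 1e-12)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(fs_hz, "fs_hz", lower = 1e-12)
  k <- simulate_coupled_gating(params)
  noise <- withr::with_seed(derive_seed(params$seed, "sparklet-noise"),
                            rnorm(params$n_frames, 0, noise_sd))
  out <- tibble::tibble(
    time_s = (seq_len(params$n_frames) - 1) / fs_hz,
    df = k * quantal_df + noise,
    k_true = k)
  attr(out, "quantal_df") <- quantal_df
  attr(out, "fs_hz") <- fs_hz
  attr(out, "params") <- params
  class(out) <- c("sparklet_trace", class(out))
  out
}

#' Idealize a sparklet trace to quantal levels
#'
#' Nearest-integer quantization: `k(t)` is the integer in `[0, n_max]`
#' closest to `df(t) / quantal_df`.
#'
#' @param trace A `sparklet_trace` tibble, or any data frame with a `df`
#'   column (and optionally `time_s`).
#' @param quantal_df Amplitude of one quantal level (> 0); defaults to the
#'   trace attribute when present.
#' @param n_max Largest admissible level.
#' @param fs_hz Sampling rate; defaults to the trace attribute, else 100.
#' @return A tibble of class `sparklet_idealization`: `time_s`, `df`, `k`.
#' @examples
#' tr <- gen_sparklet_trace(coupled_gating_params(3, 0.1, 0, 200), 1, 0)
#' ideal <- idealize_trace(tr, n_max = 3)
#' all(ideal$k == tr$k_true)
#' @export
idealize_trace <- function(trace, quantal_df = attr(trace, "quantal_df"),
                           n_max = 4L, fs_hz = attr(trace, "fs_hz") %||% 100) {
  stopifnot(is.data.frame(trace), "df" %in% names(trace))
  if (is.null(quantal_df)) abort("`quantal_df` is required (no trace attribute).")
  check_number(quantal_df, "quantal_df", lower = 1e-12)
  n_max <- check_count(n_max, "n_max", lower = 1L)
  k <- pmin(pmax(round(trace$df / quantal_df), 0L), n_max)
  out <- tibble::tibble(
    time_s = if ("time_s" %in% names(trace)) trace$time_s
             else (seq_len(nrow(trace)) - 1) / fs_hz,
    df = trace$df,
    k = as.integer(k))
  attr(out, "quantal_df") <- quantal_df
  attr(out, "n_max") <- n_max
  attr(out, "fs_hz") <- fs_hz
  class(out) <- c("sparklet_idealization", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate the quantal amplitude of a sparklet trace
#'
#' Fits the all-points amplitude distribution with equally spaced levels:
#' after locating the baseline (density mode), candidate spacings are the top
#' event level divided by 1..`n_max`; each candidate is scored by the mean
#' squared quantization residual of all points, the smallest number of levels
#' consistent with the data wins (suppressing sub-harmonic spacings), and the
#' winner is refined by local optimization.
#'
#' @param trace A `sparklet_trace` or data frame with a `df` column.
#' @param n_max Largest number of quantal levels considered.
#' @param event_sd_mult Event detection threshold in units of the baseline
#'   noise SD (default 5).
#' @return The estimated quantal amplitude (scalar).
#' @examples
#' tr <- gen_sparklet_trace(coupled_gating_params(3, 0.2, 0.3, 3000), 1, 0.15)
#' estimate_quantal_amplitude(tr)
#' @export
estimate_quantal_amplitude <- function(trace, n_max = 4L, event_sd_mult = 5) {
  stopifnot(is.data.frame(trace), "df" %in% names(trace))
  n_max <- check_count(n_max, "n_max", lower = 1L)
  x <- trace$df
  if (length(x) < 10L) abort("trace too short to estimate a quantal amplitude")

  dens <- density(x, n = 512)
  # baseline = leftmost substantial density peak (the resting level), not
  # necessarily the global mode (a very active site can spend most frames up)
  is_peak <- c(FALSE, diff(sign(diff(dens$y))) == -2, FALSE)
  peaks <- which(is_peak | seq_along(dens$y) == which.max(dens$y))
  peaks <- peaks[dens$y[peaks] >= 0.5 * max(dens$y)]
  baseline <- dens$x[min(peaks)]
  near <- x[abs(x - baseline) < 2 * dens$bw]
  if (length(near) > 0L) baseline <- median(near)
  xs <- x - baseline
  # baseline noise SD from the sub-median part of the record only, so that
  # genuinely discrete (noise-free) traces do not inflate it across levels
  low <- xs[xs < quantile(xs, 0.6)]
  sd0 <- if (length(low) >= 5L) mad(low) else mad(xs)
  if (!is.finite(sd0)) sd0 <- sd(xs)
  ev <- xs[xs > max(event_sd_mult * sd0, 1e-12)]
  if (length(ev) < 5L) {
    abort(paste0("no clear events above baseline: the amplitude histogram is ",
                 "unimodal; supply `quantal_df` manually"))
  }
  top <- quantile(ev, 0.98, names = FALSE)
  objective <- function(d) mean((xs - d * round(xs / d))^2)
  cand <- top / seq_len(n_max)
  cand <- cand[cand > 3 * sd0]
  if (length(cand) == 0L) cand <- top
  objs <- vapply(cand, objective, numeric(1))
  tol <- min(objs) + 0.02 * (sd(xs)^2)
  best_m <- which(objs <= tol)[1L]  # fewest levels within tolerance
  d0 <- cand[best_m]
  opt <- optimize(objective, interval = c(0.8 * d0, 1.25 * d0), tol = 1e-8)
  if (objective(d0) < opt$objective) d0 else opt$minimum
}

#' Sparklet site activity nPs
#'
#' `nPs = sum(k(t)) / T`, the time-averaged open-channel count: the number of
#' quantal levels reached times the probability of sparklet occurrence. It
#' depends only on the idealized levels, never on the quantal amplitude.
#'
#' @param ideal A `sparklet_idealization`, or an integer vector `k(t)`.
#' @return nPs (scalar, >= 0).
#' @examples
#' compute_nps(c(1L, 1L, 0L, 0L))  # 0.5
#' @export
compute_nps <- function(ideal) {
  k <- if (is.data.frame(ideal)) ideal$k else ideal
  if (length(k) == 0L) abort("empty idealization: nPs is undefined")
  if (any(k < 0)) abort("negative quantal levels are invalid")
  mean(k)
}

#' Classify a sparklet site as low or high activity
#'
#' @param nps nPs value(s) (>= 0).
#' @param cutoff Activity cutoff (default 0.2). Sites at or above the cutoff
#'   are classified `"high"` (boundary convention: 0.2 itself is high).
#' @return Factor with levels `"low"`, `"high"`.
#' @examples
#' classify_site(c(0.06, 0.29, 0.2))
#' @export
classify_site <- function(nps, cutoff = 0.2) {
  if (any(!is.finite(nps)) || any(nps < 0)) abort("`nps` must be >= 0.")
  check_number(cutoff, "cutoff", lower = 0)
  factor(ifelse(nps >= cutoff, "high", "low"), levels = c("low", "high"))
}

# Log-likelihood of category counts under the coupling mixture.
kappa_loglik <- function(kappa, counts, n, p) {
  k <- 0:n
  mix <- (1 - kappa) * dbinom(k, n, p)
  mix[1L] <- mix[1L] + kappa * (1 - p)
  mix[n + 1L] <- mix[n + 1L] + kappa * p
  sum(counts * log(pmax(mix, 1e-300)))
}

#' Maximum-likelihood coupling coefficient of a sparklet site
#'
#' Fits the frame-wise coupling mixture (see [coupled_gating_params()]) to an
#' idealized record: each frame's open count is binomial(`n_channels`, p)
#' with probability `1 - kappa` and all-or-none (0 or `n_channels`) with
#' probability `kappa`. `p` defaults to `mean(k) / n_channels`, which is the
#' marginal-preserving estimate under every `kappa`. The estimate is the
#' likelihood maximizer on `[0, 1]` (endpoints included); the confidence
#' interval is a percentile bootstrap over frames.
#'
#' @param ideal A `sparklet_idealization` or integer vector `k(t)`.
#' @param n_channels Number of channels at the site (>= 2).
#' @param p_open Optional known per-channel open probability; estimated from
#'   the record when NULL.
#' @param n_boot Bootstrap resamples for the CI (default 500; 0 disables).
#' @param conf_level CI coverage (default 0.95).
#' @param boot_seed Seed for the bootstrap resampling.
#' @return A `kappa_fit`: list with `kappa`, `conf_low`, `conf_high`,
#'   `p_open`, `n_channels`, `n_frames`, `log_lik`.
#' @examples
#' k <- simulate_coupled_gating(coupled_gating_params(4, 0.1, 0.5, 5000))
#' estimate_kappa(k, n_channels = 4, n_boot = 50)
#' @export
estimate_kappa <- function(ideal, n_channels, p_open = NULL, n_boot = 500,
                           conf_level = 0.95, boot_seed = 1L) {
  k <- if (is.data.frame(ideal)) ideal$k else ideal
  n_channels <- check_count(n_channels, "n_channels", lower = 2L)
  if (length(k) < 2L) abort("need at least 2 frames")
  if (any(k < 0 | k > n_channels)) {
    abort("`k` must lie in [0, n_channels]")
  }
  n_boot <- check_count(n_boot, "n_boot")
  counts <- tabulate(k + 1L, nbins = n_channels + 1L)
  t_n <- length(k)

  if (length(unique(k)) == 1L) {
    warn("all frames identical: coupling is unidentifiable; returning a boundary estimate")
  }

  fit_counts <- function(counts) {
    p <- if (is.null(p_open)) {
      ph <- sum(counts * (0:n_channels)) / (sum(counts) * n_channels)
      min(max(ph, 1e-9), 1 - 1e-9)
    } else p_open
    opt <- optimize(function(kp) kappa_loglik(kp, counts, n_channels, p),
                    interval = c(0, 1), maximum = TRUE, tol = 1e-7)
    cands <- c(0, opt$maximum, 1)
    lls <- vapply(cands, kappa_loglik, numeric(1),
                  counts = counts, n = n_channels, p = p)
    i <- which.max(lls)
    list(kappa = cands[i], ll = lls[i], p = p)
  }
  main <- fit_counts(counts)

  conf_low <- conf_high <- NA_real_
  if (n_boot > 0L) {
    boots <- withr::with_seed(boot_seed, {
      resamp <- rmultinom(n_boot, t_n, counts / t_n)
      apply(resamp, 2, function(cc) fit_counts(cc)$kappa)
    })
    alpha <- (1 - conf_level) / 2
    ci <- quantile(boots, c(alpha, 1 - alpha), names = FALSE)
    conf_low <- ci[1]; conf_high <- ci[2]
  }
  structure(list(kappa = main$kappa, conf_low = conf_low,
                 conf_high = conf_high, p_open = main$p,
                 n_channels = n_channels, n_frames = t_n,
                 log_lik = main$ll,
                 model = "frame-wise coordination mixture"),
            class = "kappa_fit")
}

#' @export
print.kappa_fit <- function(x, ...) {
  ci <- if (is.finite(x$conf_low)) {
    sprintf(" [%.3f, %.3f]", x$conf_low, x$conf_high)
  } else ""
  cat(sprintf("Coupling coefficient: kappa = %.3f%s (N = %d, p = %.3f, %d frames)\n",
              x$kappa, ci, x$n_channels, x$p_open, x$n_frames))
  invisible(x)
}

#' @rdname estimate_kappa
#' @param x A `kappa_fit`.
#' @param ... Unused.
#' @export
tidy.kappa_fit <- function(x, ...) {
  tibble::tibble(term = c("kappa", "p_open"),
                 estimate = c(x$kappa, x$p_open),
                 conf.low = c(x$conf_low, NA_real_),
                 conf.high = c(x$conf_high, NA_real_))
}

#' @rdname estimate_kappa
#' @export
glance.kappa_fit <- function(x, ...) {
  tibble::tibble(logLik = x$log_lik, nobs = x$n_frames,
                 n_channels = x$n_channels)
}

#' Full analysis of one sparklet record
#'
#' Convenience wrapper: idealize, compute nPs, classify, and (when the record
#' reaches more than one channel) estimate the coupling coefficient.
#'
#' @param trace A `sparklet_trace`/data frame with a `df` column.
#' @param quantal_df Quantal amplitude; estimated with
#'   [estimate_quantal_amplitude()] when NULL.
#' @param n_max Largest admissible quantal level.
#' @param cutoff Activity cutoff for [classify_site()].
#' @param n_boot Bootstrap resamples for the kappa CI.
#' @return One-row tibble: `quantal_df`, `nps`, `activity_class`,
#'   `n_quantal_levels`, `kappa`, `kappa_low`, `kappa_high`.
#' @export
analyze_sparklet <- function(trace, quantal_df = NULL, n_max = 4L,
                             cutoff = 0.2, n_boot = 200) {
  if (is.null(quantal_df)) quantal_df <- estimate_quantal_amplitude(trace, n_max)
  ideal <- idealize_trace(trace, quantal_df, n_max)
  nps <- compute_nps(ideal)
  n_levels <- max(ideal$k)
  kp <- if (n_levels >= 2L) {
    fit <- suppressWarnings(
      estimate_kappa(ideal, n_channels = n_levels, n_boot = n_boot))
    c(fit$kappa, fit$conf_low, fit$conf_high)
  } else c(NA_real_, NA_real_, NA_real_)
  tibble::tibble(quantal_df = quantal_df, nps = nps,
                 activity_class = classify_site(nps, cutoff),
                 n_quantal_levels = n_levels,
                 kappa = kp[1], kappa_low = kp[2], kappa_high = kp[3])
}
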