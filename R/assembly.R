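#' Parameters for the stochastic cluster self-assembly model
#'
#' The model describes membrane-protein clustering as a stochastic
#' birth/growth/death process on a square lattice with periodic boundaries:
#' per step, (1) with probability `p_n` a new channel nucleates at a uniformly
#' random empty site; (2) each existing 4-connected cluster grows by one
#' channel at a uniformly random empty perimeter site with probability `p_g`;
#' (3) every channel is independently removed with probability `p_r`. At
#' steady state this process yields exponential cluster-size distributions,
#' the hallmark of stochastic (Poisson-like) cluster formation.
#'
#' The shipped defaults are a plausible reconstruction of a wild-type-like
#' regime; they are not traceable to a published parameter table and should be
#' treated as `unverified_from_supplement`.
#'
#' @param p_n Per-step nucleation probability, in `[0, 1]`.
#' @param p_g Per-cluster per-step growth probability, in `[0, 1]`.
#' @param p_r Per-channel per-step removal probability, in `[0, 1]`.
#' @param grid_w,grid_h Lattice dimensions in sites (>= 8).
#' @param n_steps Number of simulated steps (>= 1).
#' @param seed RNG seed.
#' @param area_per_site Physical calibration, nm2 per lattice site (default
#'   400 = one 20 nm pixel).
#' @return An `assembly_params` object.
#' @examples
#' assembly_params(p_n = 0.5, p_g = 0.2, p_r = 0.02, n_steps = 500)
#' @export
assembly_params <- function(p_n = 0.5, p_g = 0.2, p_r = 0.02,
                            grid_w = 256, grid_h = 256, n_steps = 1000,
                            seed = 1L, area_per_site = 400) {
  check_prob(p_n, "p_n"); check_prob(p_g, "p_g"); check_prob(p_r, "p_r")
  check_count(grid_w, "grid_w", lower = 8L)
  check_count(grid_h, "grid_h", lower = 8L)
  check_count(n_steps, "n_steps", lower = 1L)
  check_count(seed, "seed")
  check_number(area_per_site, "area_per_site", lower = 1e-12)
  structure(list(p_n = p_n, p_g = p_g, p_r = p_r,
                 grid_w = as.integer(grid_w), grid_h = as.integer(grid_h),
                 n_steps = as.integer(n_steps), seed = as.integer(seed),
                 area_per_site = area_per_site),
            class = "assembly_params")
}

#' Simulate cluster self-assembly to a fixed number of steps
#'
#' @param params An [assembly_params()].
#' @param lattice Optional starting lattice (0/1 integer matrix of the
#'   parameterized dimensions); defaults to empty.
#' @return An `assembly_result`: list with `sizes` (cluster sizes in lattice
#'   sites at the final step), `sizes_nm2` (calibrated by `area_per_site`),
#'   `lattice` (final 0/1 matrix), `trace` (tibble: step, occupancy, inserted,
#'   removed), `saturated` (TRUE if occupancy ever exceeded 95%), and `params`.
#' @examples
#' res <- simulate_assembly(assembly_params(n_steps = 200, grid_w = 64,
#'                                          grid_h = 64))
#' length(res$sizes)
#' @export
simulate_assembly <- function(params, lattice = NULL) {
  stopifnot(inherits(params, "assembly_params"))
  if (is.null(lattice)) {
    lattice <- matrix(0L, params$grid_w, params$grid_h)
  }
  stopifnot(is.matrix(lattice),
            nrow(lattice) == params$grid_w, ncol(lattice) == params$grid_h)
  raw <- withr::with_seed(params$seed,
    .assembly_run(lattice, params$p_n, params$p_g, params$p_r,
                  params$n_steps))
  new_assembly_result(raw, params)
}

new_assembly_result <- function(raw, params, steps_offset = 0L) {
  n_sites <- params$grid_w * params$grid_h
  saturated <- any(raw$occupancy > 0.95 * n_sites)
  if (saturated) {
    warn("lattice occupancy exceeded 95%; size distribution is saturation-limited")
  }
  sizes <- as.numeric(.assembly_sizes(raw$lattice))
  structure(
    list(sizes = sizes,
         sizes_nm2 = sizes * params$area_per_site,
         lattice = raw$lattice,
         trace = tibble::tibble(step = steps_offset + seq_along(raw$occupancy),
                                occupancy = as.integer(raw$occupancy),
                                inserted = as.integer(raw$inserted),
                                removed = as.integer(raw$removed)),
         saturated = saturated,
         params = params),
    class = "assembly_result")
}

#' Run the self-assembly model until total occupancy is stationary
#'
#' Advances the simulation in windows of `window` steps and stops when the
#' windowed mean occupancy changes by less than `tol` (relative) between
#' consecutive windows, or when the `n_steps` cap in `params` is reached.
#' Stationarity is judged on at least two full windows, so the minimum
#' `steps_used` is `2 * window`.
#'
#' @param params An [assembly_params()]; `n_steps` acts as the step cap.
#' @param window Window length in steps (>= 100).
#' @param tol Relative change in windowed mean occupancy below which the
#'   process is declared steady.
#' @return An `assembly_result` (see [simulate_assembly()]) with two extra
#'   fields: `steps_used` and `converged` (FALSE when the cap was hit).
#' @examples
#' res <- reach_steady_state(assembly_params(p_r = 0.05, n_steps = 2000,
#'                                           grid_w = 64, grid_h = 64),
#'                           window = 100)
#' res$steps_used
#' @export
reach_steady_state <- function(params, window = 200, tol = 0.05) {
  stopifnot(inherits(params, "assembly_params"))
  check_count(window, "window", lower = 100L)
  check_number(tol, "tol", lower = 0)
  cap <- params$n_steps
  lattice <- matrix(0L, params$grid_w, params$grid_h)
  traces <- list()
  prev_mean <- NULL
  steps_used <- 0L
  converged <- FALSE
  last_raw <- NULL
  withr::with_seed(params$seed, {
    while (steps_used < cap) {
      n_run <- min(window, cap - steps_used)
      raw <- .assembly_run(lattice, params$p_n, params$p_g, params$p_r, n_run)
      lattice <- raw$lattice
      traces[[length(traces) + 1L]] <- raw
      steps_used <- steps_used + n_run
      last_raw <- raw
      m <- mean(raw$occupancy)
      if (!is.null(prev_mean) && n_run == window &&
          abs(m - prev_mean) / max(prev_mean, 1) < tol) {
        converged <- TRUE
        break
      }
      prev_mean <- m
    }
  })
  raw_all <- list(
    lattice = lattice,
    occupancy = unlist(lapply(traces, `[[`, "occupancy")),
    inserted = unlist(lapply(traces, `[[`, "inserted")),
    removed = unlist(lapply(traces, `[[`, "removed")))
  res <- new_assembly_result(raw_all, params)
  res$steps_used <- steps_used
  res$converged <- converged
  res
}

# Two-sample Kolmogorov-Smirnov distance (statistic only; handles ties).
ks_distance <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(1)
  ref <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(ref) - ecdf(b)(ref)))
}

#' Fit self-assembly parameters to an observed size distribution
#'
#' Grid search: every candidate `(p_n, p_g, p_r)` is simulated with
#' `n_reps` replicate seeds, and the candidate minimizing the mean two-sample
#' Kolmogorov-Smirnov distance between simulated and observed cluster-size
#' distributions is returned. Ties are broken towards smaller `p_n`, then
#' smaller `p_g`.
#'
#' @param observed Numeric vector of observed cluster sizes, in lattice units
#'   (divide physical sizes by `area_per_site` first).
#' @param grid Data frame with columns `p_n`, `p_g`, `p_r`: the candidate
#'   parameter combinations.
#' @param n_reps Replicate seeds per candidate (>= 3).
#' @param grid_w,grid_h,n_steps,seed,area_per_site Simulation settings shared
#'   by all candidates (see [assembly_params()]).
#' @return An `assembly_fit`: list with `best` (the winning
#'   [assembly_params()]), `distance` (its mean KS distance), and `results`
#'   (tibble of all candidates with their distances).
#' @examples
#' grid <- expand.grid(p_n = c(0.2, 0.6), p_g = 0.1, p_r = 0.05)
#' obs <- simulate_assembly(assembly_params(0.6, 0.1, 0.05, 64, 64, 400))$sizes
#' fit <- fit_assembly_params(obs, grid, grid_w = 64, grid_h = 64,
#'                            n_steps = 400)
#' fit$best$p_n
#' @export
fit_assembly_params <- function(observed, grid, n_reps = 3,
                                grid_w = 128, grid_h = 128, n_steps = 1000,
                                seed = 1L, area_per_site = 400) {
  if (!is.numeric(observed) || length(observed) == 0L) {
    abort("`observed` must be a nonempty numeric vector of cluster sizes.")
  }
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0L) abort("parameter `grid` is empty")
  stopifnot(all(c("p_n", "p_g", "p_r") %in% names(grid)))
  check_count(n_reps, "n_reps", lower = 3L)

  dist_of <- function(p_n, p_g, p_r, cand) {
    ds <- vapply(seq_len(n_reps), function(rep) {
      prm <- assembly_params(p_n, p_g, p_r, grid_w, grid_h, n_steps,
                             seed = derive_seed(seed, sprintf("fit-%d-%d",
                                                              cand, rep)),
                             area_per_site = area_per_site)
      sizes <- suppressWarnings(simulate_assembly(prm)$sizes)
      ks_distance(sizes, observed)
    }, numeric(1))
    mean(ds)
  }
  results <- grid
  results$distance <- vapply(seq_len(nrow(grid)), function(i) {
    dist_of(grid$p_n[i], grid$p_g[i], grid$p_r[i], i)
  }, numeric(1))
  ord <- order(results$distance, results$p_n, results$p_g)
  best_row <- results[ord[1L], ]
  best <- assembly_params(best_row$p_n, best_row$p_g, best_row$p_r,
                          grid_w, grid_h, n_steps, seed = seed,
                          area_per_site = area_per_site)
  structure(list(best = best, distance = best_row$distance,
                 results = results),
            class = "assembly_fit")
}

#' @export
print.assembly_fit <- function(x, ...) {
  cat(sprintf(
    "Self-assembly parameter fit: p_n = %g, p_g = %g, p_r = %g (KS = %.3f, %d candidates)\n",
    x$best$p_n, x$best$p_g, x$best$p_r, x$distance, nrow(x$results)))
  invisible(x)
}

#' @rdname fit_assembly_params
#' @param x An `assembly_fit`.
#' @param ... Unused.
#' @export
tidy.assembly_fit <- function(x, ...) {
  tibble::tibble(term = c("p_n", "p_g", "p_r"),
                 estimate = c(x$best$p_n, x$best$p_g, x$best$p_r))
}

#' @rdname fit_assembly_params
#' @export
glance.assembly_fit <- function(x, ...) {
  tibble::tibble(ks_distance = x$distance, n_candidates = nrow(x$results))
}
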