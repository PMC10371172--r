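# Shared fixtures for the suite: everything is generated in code, at sizes
# small enough that single tests stay in the seconds range.

small_field <- function(seed, n = 150, mean_area = 2500, noise_sd = 0.1,
                        width = 8000) {
  gen_localization_field(
    field_spec(width, width, noise_sd = noise_sd, seed = seed),
    n_clusters = n, mean_area_nm2 = mean_area)
}

small_stack <- function(seed, n = 40, mean_vol = 0.09, noise_sd = 0.1,
                        shell = membrane_shell("all"), ...) {
  gen_confocal_stack(
    field_spec(10000, 10000, depth_um = 4, pixel_nm = 100,
               noise_sd = noise_sd, seed = seed),
    n_clusters = n, mean_volume_um3 = mean_vol, shell = shell, ...)
}

# brute-force grid-search oracle for the coupling coefficient
kappa_grid_oracle <- function(k, n_channels, step = 0.001) {
  counts <- tabulate(k + 1L, nbins = n_channels + 1L)
  p <- sum(counts * (0:n_channels)) / (sum(counts) * n_channels)
  p <- min(max(p, 1e-9), 1 - 1e-9)
  grid <- seq(0, 1, by = step)
  ll <- vapply(grid, function(kp) {
    lev <- 0:n_channels
    mix <- (1 - kp) * dbinom(lev, n_channels, p)
    mix[1] <- mix[1] + kp * (1 - p)
    mix[n_channels + 1] <- mix[n_channels + 1] + kp * p
    sum(counts * log(pmax(mix, 1e-300)))
  }, numeric(1))
  grid[which.max(ll)]
}
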