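#' Fit a single exponential to a cluster-size distribution
#'
#' Steady-state stochastic self-assembly produces cluster sizes whose
#' frequency distribution decays as a single exponential. The scale is the
#' maximum-likelihood estimate for a (possibly shifted) exponential,
#' `mean(sizes - min_size)`; goodness of fit is summarized as the R-squared
#' of a least-squares line through the log-transformed positive histogram
#' counts, which is linear for exponential data. The regression is weighted
#' by bin count (Poisson counts have log-scale variance of about 1/count, so
#' sparse tail bins should not dominate), and for integer-valued sizes the
#' bin width snaps to an integer so every bin spans equally many size values.
#'
#' `min_size` defaults to the sample minimum (the MLE of the shift). When
#' sizes come from a measurement with a known resolution floor, pass that
#' floor explicitly: a noisy sample minimum is biased low by the most extreme
#' measurement error and would inflate the scale.
#'
#' @param sizes Numeric vector of sizes (>= 30 observations).
#' @param bins Number of histogram bins for the log-linear diagnostic
#'   (default `ceiling(sqrt(n))`, capped at 40).
#' @param min_size Shift (lower limit) of the exponential; default
#'   `min(sizes)`.
#' @return An `exp_fit`: list with `scale`, `amplitude` (histogram prefactor),
#'   `r_squared`, `n_obs`, `min_size` and `histogram` (tibble: mid, count).
#' @examples
#' fit <- fit_exponential(gen_cluster_sizes(5000, 0.08, seed = 1))
#' fit$scale
#' @export
fit_exponential <- function(sizes, bins = NULL, min_size = NULL) {
  if (!is.numeric(sizes) || length(sizes) < 30L) {
    abort("`sizes` must be a numeric vector with at least 30 observations.")
  }
  if (any(!is.finite(sizes))) abort("`sizes` must be finite.")
  if (diff(range(sizes)) == 0) {
    abort("degenerate fit: all sizes are identical, no exponential scale exists")
  }
  if (is.null(min_size)) min_size <- min(sizes)
  check_number(min_size, "min_size")
  scale <- mean(sizes - min_size)
  if (scale <= 0) {
    abort("degenerate fit: nonpositive scale (is `min_size` above the sample mean?)")
  }

  n <- length(sizes)
  if (is.null(bins)) bins <- min(40L, max(8L, ceiling(sqrt(n))))
  check_count(bins, "bins", lower = 2L)
  rng <- range(sizes)
  if (all(sizes == round(sizes))) {
    # integer sizes (lattice units): snap bin width to an integer so bins
    # hold equally many size values (avoids sawtooth aliasing in the counts)
    width <- max(1, round(diff(rng) / bins))
    brks <- seq(rng[1] - 0.5, rng[2] + width, by = width)
  } else {
    brks <- seq(rng[1], rng[2], length.out = bins + 1L)
  }
  idx <- findInterval(sizes, brks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(brks) - 1L)
  mids <- (brks[-1L] + brks[-length(brks)]) / 2
  keep <- counts > 0
  if (sum(keep) >= 3L) {
    # Poisson counts: var(log count) ~ 1/count, so weight by count
    fit <- lm(log(counts[keep]) ~ mids[keep], weights = counts[keep])
    r_squared <- summary(fit)$r.squared
    amplitude <- exp(coef(fit)[[1L]])
  } else {
    r_squared <- NA_real_
    amplitude <- NA_real_
  }
  structure(list(scale = scale, amplitude = amplitude,
                 r_squared = r_squared, n_obs = n, min_size = min_size,
                 histogram = tibble::tibble(mid = mids, count = counts)),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential size-distribution fit: scale = %.4g (shift %.4g), R2(log-counts) = %.3f, n = %d\n",
    x$scale, x$min_size, x$r_squared, x$n_obs))
  invisible(x)
}

#' @rdname fit_exponential
#' @param x An `exp_fit`.
#' @param ... Unused.
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(term = c("scale", "amplitude", "min_size"),
                 estimate = c(x$scale, x$amplitude, x$min_size))
}

#' @rdname fit_exponential
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = x$n_obs)
}

#' @rdname fit_exponential
#' @param object An `exp_fit`.
#' @export
autoplot.exp_fit <- function(object, ...) {
  hist <- dplyr::filter(object$histogram, .data$count > 0)
  pred <- tibble::tibble(
    mid = seq(min(hist$mid), max(hist$mid), length.out = 200))
  pred$count <- object$amplitude * exp(-pred$mid / object$scale)
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(fill = "grey70", width = diff(object$histogram$mid[1:2]) * 0.9) +
    ggplot2::geom_line(data = pred, colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "cluster size", y = "count (log scale)",
                  title = sprintf("Exponential fit: scale %.3g, R2 %.2f",
                                  object$scale, object$r_squared)) +
    ggplot2::theme_minimal()
}
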