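# Internal helpers shared across modules.

# Scalar validation -----------------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    abort(sprintf("`%s` must be in [%s, %s]%s (got %g).",
                  name, format(lower), format(upper),
                  if (allow_zero) "" else ", nonzero", x))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < lower) {
    abort(sprintf("`%s` must be an integer >= %d.", name, lower))
  }
  invisible(as.integer(x))
}

check_prob <- function(x, name) check_number(x, name, lower = 0, upper = 1)

# Seeds ------------------------------------------------------------------------

#' Derive a deterministic per-stage seed from a global seed
#'
#' Each pipeline stage draws its randomness from its own seed, computed from
#' the run's global seed and the stage name by a fixed polynomial string hash.
#' The derivation is stable across sessions and platform-independent, so a run
#' can be reproduced stage by stage.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "assembly")
#' @export
derive_seed <- function(seed, stage) {
  check_count(seed, "seed")
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

with_seed_null <- function(seed, code) {
  # Runs `code` under `seed` if non-NULL, otherwise with the ambient RNG.
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Geometry ---------------------------------------------------------------------

# Anti-aliased coverage of a pixel (center distance d, in pixel units) by a
# disk/ball of radius r (pixel units): linear ramp over one pixel width.
edge_coverage <- function(d, r) {
  pmin(pmax(r - d + 0.5, 0), 1)
}

# Separable Gaussian convolution with reflect padding; kernel normalized to
# unit mass. sigma in pixels; works on matrices.
gaussian_smooth_2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  img <- conv_dim(img, k, 1L)
  conv_dim(img, k, 2L)
}

conv_dim <- function(img, k, dim) {
  half <- (length(k) - 1L) %/% 2L
  n <- base::dim(img)[dim]
  pad_idx <- c(rev(seq_len(half)), seq_len(n), n + 1L - seq_len(half))
  pad_idx <- pmin(pmax(pad_idx, 1L), n)  # reflect (edge-repeat beyond range)
  if (dim == 1L) {
    padded <- img[pad_idx, , drop = FALSE]
    out <- matrix(0, nrow(img), ncol(img))
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[(j - 1L) + seq_len(n), , drop = FALSE]
    }
  } else {
    padded <- img[, pad_idx, drop = FALSE]
    out <- matrix(0, nrow(img), ncol(img))
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[, (j - 1L) + seq_len(n), drop = FALSE]
    }
  }
  out
}

# 3D separable Gaussian smoothing (sigma per axis, in voxel units).
gaussian_smooth_3d <- function(arr, sigma) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- exp(-((-half:half)^2) / (2 * s^2))
    k <- k / sum(k)
    arr <- apply_conv_axis(arr, k, ax)
  }
  arr
}

apply_conv_axis <- function(arr, k, ax) {
  d <- dim(arr)
  half <- (length(k) - 1L) %/% 2L
  n <- d[ax]
  idx <- c(rev(seq_len(half)), seq_len(n), n + 1L - seq_len(half))
  idx <- pmin(pmax(idx, 1L), n)
  out <- array(0, d)
  for (j in seq_along(k)) {
    sel <- idx[(j - 1L) + seq_len(n)]
    out <- out + k[j] * slice_axis(arr, sel, ax)
  }
  out
}

slice_axis <- function(arr, sel, ax) {
  switch(ax,
         arr[sel, , , drop = FALSE],
         arr[, sel, , drop = FALSE],
         arr[, , sel, drop = FALSE])
}

#' Nernst equilibrium potential
#'
#' @param c_out,c_in Extracellular / intracellular concentrations (same units).
#' @param temp_k Absolute temperature in kelvin (default 295, i.e. 22 degC).
#' @param z Ion valence (default +1).
#' @return Potential in mV.
#' @examples
#' nernst_potential(5, 107)  # K+ under typical whole-cell solutions
#' @export
nernst_potential <- function(c_out, c_in, temp_k = 295, z = 1) {
  check_number(c_out, "c_out", lower = 1e-12)
  check_number(c_in, "c_in", lower = 1e-12)
  1000 * (8.31446 * temp_k / (z * 96485.33)) * log(c_out / c_in)
}
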