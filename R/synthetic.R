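#' Specify the geometry of a synthetic imaging field
#'
#' Physical extent, render pitch and noise model for the synthetic
#' localization-field and confocal-stack generators. The defaults mirror
#' common acquisition settings for ground-state-depletion renders (20 nm/px)
#' and spinning-disk confocal stacks (0.13 um z-step).
#'
#' @param width_nm,height_nm Lateral physical extent, nm.
#' @param depth_um Axial extent, um (only needed for stacks).
#' @param pixel_nm Lateral render pitch, nm/px.
#' @param voxel_z_um Axial step, um.
#' @param psf_sigma_nm Gaussian point-spread sigma, nm. The default 0 renders
#'   sharp (binary-export-like) footprints with anti-aliased edges; set > 0 to
#'   emulate optical blur.
#' @param noise_sd Additive Gaussian noise SD, in units of the unit-intensity
#'   cluster plateau (so `noise_sd = 0.1` is a signal-to-noise ratio of 10).
#' @param seed RNG seed; identical specs with identical seeds generate
#'   bit-identical output.
#' @return A `field_spec` object (list).
#' @examples
#' field_spec(4000, 4000, noise_sd = 0.1, seed = 7)
#' @export
field_spec <- function(width_nm, height_nm, depth_um = NULL, pixel_nm = 20,
                       voxel_z_um = 0.13, psf_sigma_nm = 0, noise_sd = 0.05,
                       seed = 1L) {
  check_number(width_nm, "width_nm", lower = 1e-9)
  check_number(height_nm, "height_nm", lower = 1e-9)
  if (!is.null(depth_um)) check_number(depth_um, "depth_um", lower = 1e-9)
  check_number(pixel_nm, "pixel_nm", lower = 1e-9)
  check_number(voxel_z_um, "voxel_z_um", lower = 1e-9)
  check_number(psf_sigma_nm, "psf_sigma_nm", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_count(seed, "seed")
  structure(
    list(width_nm = width_nm, height_nm = height_nm, depth_um = depth_um,
         pixel_nm = pixel_nm, voxel_z_um = voxel_z_um,
         psf_sigma_nm = psf_sigma_nm, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "field_spec")
}

#' Sample cluster sizes from an exponential distribution
#'
#' Direct i.i.d. sampler for the size law that steady-state stochastic
#' self-assembly produces; used as ground truth for the exponential fitter.
#'
#' @param n Number of draws (>= 1).
#' @param scale Exponential mean (> 0), in whatever physical unit the caller
#'   works in (nm2, um3, lattice sites).
#' @param seed Optional RNG seed.
#' @return Numeric vector of `n` positive sizes.
#' @examples
#' mean(gen_cluster_sizes(5000, scale = 0.08, seed = 1))
#' @export
gen_cluster_sizes <- function(n, scale, seed = NULL) {
  check_count(n, "n", lower = 1L)
  check_number(scale, "scale", lower = 1e-300)
  with_seed_null(seed, rexp(n, rate = 1 / scale))
}

#' Generate a synthetic 2D localization render with known ground truth
#'
#' Places `n_clusters` non-overlapping disks uniformly at random on the field,
#' with areas drawn as `min_area_nm2 + Exp(mean_area_nm2 - min_area_nm2)`
#' (so the mean equals `mean_area_nm2`), renders them as unit-intensity
#' anti-aliased footprints, optionally blurs with the spec's PSF, and adds
#' Gaussian noise. The floor reflects that a localization render cannot
#' contain footprints below its resolution limit.
#'
#' @param spec A [field_spec()].
#' @param n_clusters Number of clusters (>= 0).
#' @param mean_area_nm2 Mean drawn cluster area, nm2.
#' @param min_area_nm2 Resolution-limited minimum footprint, nm2 (default 1200,
#'   roughly the area of a 40 nm-resolution point image). Must be smaller than
#'   `mean_area_nm2`.
#' @param margin_nm Extra center-to-center clearance between disks, nm.
#' @param max_retries Placement retries per cluster before failing.
#' @return A list of class `localization_field` with `image` (matrix indexed
#'   `[x, y]`), `truth` (tibble: id, x_nm, y_nm, area_nm2) and `spec`.
#' @examples
#' f <- gen_localization_field(field_spec(2000, 2000, seed = 1), 10, 2500)
#' f$truth
#' @export
gen_localization_field <- function(spec, n_clusters, mean_area_nm2,
                                   min_area_nm2 = 1200, margin_nm = 100,
                                   max_retries = 1000) {
  stopifnot(inherits(spec, "field_spec"))
  check_count(n_clusters, "n_clusters", lower = 0L)
  nx <- max(1L, round(spec$width_nm / spec$pixel_nm))
  ny <- max(1L, round(spec$height_nm / spec$pixel_nm))

  if (n_clusters == 0L) {
    img <- withr::with_seed(spec$seed,
      matrix(rnorm(nx * ny, 0, spec$noise_sd), nx, ny))
    truth <- tibble::tibble(id = integer(), x_nm = numeric(),
                            y_nm = numeric(), area_nm2 = numeric())
    return(structure(list(image = img, truth = truth, spec = spec),
                     class = "localization_field"))
  }
  check_number(mean_area_nm2, "mean_area_nm2", lower = 1e-9)
  check_number(min_area_nm2, "min_area_nm2", lower = 0)
  if (min_area_nm2 >= mean_area_nm2) {
    abort("`min_area_nm2` must be smaller than `mean_area_nm2`.")
  }

  out <- withr::with_seed(spec$seed, {
    areas <- min_area_nm2 + rexp(n_clusters, 1 / (mean_area_nm2 - min_area_nm2))
    radii <- sqrt(areas / pi)
    xs <- ys <- numeric(n_clusters)
    for (i in seq_len(n_clusters)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        x <- runif(1, radii[i], spec$width_nm - radii[i])
        y <- runif(1, radii[i], spec$height_nm - radii[i])
        if (i == 1L) { placed <- TRUE } else {
          j <- seq_len(i - 1L)
          ok <- all((xs[j] - x)^2 + (ys[j] - y)^2 >
                      (radii[j] + radii[i] + margin_nm)^2)
          placed <- ok
        }
        if (placed) { xs[i] <- x; ys[i] <- y; break }
      }
      if (!placed) {
        abort(sprintf(paste0(
          "could not place cluster %d after %d retries: requested density ",
          "(%d clusters, mean area %.0f nm2 + %.0f nm margin) exceeds what ",
          "the %.0f x %.0f nm field admits without overlap"),
          i, max_retries, n_clusters, mean_area_nm2, margin_nm,
          spec$width_nm, spec$height_nm))
      }
    }

    img <- matrix(0, nx, ny)
    px <- spec$pixel_nm
    for (i in seq_len(n_clusters)) {
      r_px <- radii[i] / px
      cx <- xs[i] / px + 0.5  # pixel-center coordinates (pixel k center = k)
      cy <- ys[i] / px + 0.5
      i0 <- max(1L, floor(cx - r_px - 1)); i1 <- min(nx, ceiling(cx + r_px + 1))
      j0 <- max(1L, floor(cy - r_px - 1)); j1 <- min(ny, ceiling(cy + r_px + 1))
      ii <- i0:i1; jj <- j0:j1
      d <- sqrt(outer((ii - cx)^2, (jj - cy)^2, "+"))
      cov <- edge_coverage(d, r_px)
      s <- sum(cov)
      # rescale so the rendered mass equals the drawn area exactly (the
      # linear edge ramp otherwise adds pi/12 px^2 per disk)
      if (s > 0) cov <- cov * (pi * r_px^2 / s)
      img[ii, jj] <- img[ii, jj] + cov
    }
    if (spec$psf_sigma_nm > 0) {
      img <- gaussian_smooth_2d(img, spec$psf_sigma_nm / px)
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(nx * ny, 0, spec$noise_sd), nx, ny)
    }
    list(image = img,
         truth = tibble::tibble(id = seq_len(n_clusters), x_nm = xs,
                                y_nm = ys, area_nm2 = areas))
  })
  structure(c(out, list(spec = spec)), class = "localization_field")
}

#' Describe the membrane shell geometry for synthetic stacks
#'
#' @param type `"ellipsoid"` restricts the membrane to a shell just inside the
#'   inscribed ellipsoid of the imaged volume (a smooth closed surface, like a
#'   WGA-stained sarcolemma); `"all"` marks the whole volume as membrane
#'   (placement unconstrained).
#' @param thickness_um Shell thickness, um; must be at least one axial voxel.
#' @return A `membrane_shell` object.
#' @export
membrane_shell <- function(type = c("ellipsoid", "all"), thickness_um = 1) {
  type <- match.arg(type)
  check_number(thickness_um, "thickness_um", lower = 1e-9)
  structure(list(type = type, thickness_um = thickness_um),
            class = "membrane_shell")
}

#' Generate a synthetic confocal-like stack with a membrane mask
#'
#' Places non-overlapping spheres with volumes drawn as
#' `min_volume_um3 + Exp(mean_volume_um3 - min_volume_um3)` at centroids
#' sampled uniformly within the membrane shell, renders them with
#' partial-volume anti-aliasing (plus optional PSF blur) and additive noise,
#' and returns the binary membrane mask alongside the ground truth.
#'
#' @param spec A [field_spec()] with `depth_um` set.
#' @param n_clusters Number of clusters (>= 0).
#' @param mean_volume_um3 Mean drawn cluster volume, um3.
#' @param shell A [membrane_shell()].
#' @param min_volume_um3 Resolution-limited minimum volume, um3 (default 0.02,
#'   a sphere of ~340 nm diameter, about the confocal lateral resolution).
#' @param margin_nm Extra center clearance between spheres, nm.
#' @param max_retries Placement retries per cluster before failing.
#' @param contain `"centroid"` (default) requires only the centroid inside
#'   the membrane shell; `"full"` rejects placements whose whole sphere is
#'   not inside the shell (conservative ellipsoid bound), guaranteeing that
#'   the mask covers the rendered cluster mass.
#' @return A list of class `confocal_stack` with `stack` (3D array `[x, y, z]`),
#'   `mask` (logical array, membrane voxels), `truth`
#'   (tibble: id, x_um, y_um, z_um, volume_um3), `spec`, `shell`.
#' @examples
#' spec <- field_spec(6000, 6000, depth_um = 3, pixel_nm = 100, seed = 2)
#' st <- gen_confocal_stack(spec, 20, 0.09, membrane_shell("all"))
#' dim(st$stack)
#' @export
gen_confocal_stack <- function(spec, n_clusters, mean_volume_um3,
                               shell = membrane_shell(),
                               min_volume_um3 = 0.02, margin_nm = 150,
                               max_retries = 1000,
                               contain = c("centroid", "full")) {
  contain <- match.arg(contain)
  stopifnot(inherits(spec, "field_spec"), inherits(shell, "membrane_shell"))
  if (is.null(spec$depth_um)) abort("`spec$depth_um` is required for stacks.")
  check_count(n_clusters, "n_clusters", lower = 0L)
  if (shell$thickness_um < spec$voxel_z_um) {
    abort(sprintf(
      "membrane shell thickness (%.3g um) is thinner than one axial voxel (%.3g um)",
      shell$thickness_um, spec$voxel_z_um))
  }

  px_um <- spec$pixel_nm / 1000
  nx <- max(1L, round(spec$width_nm / spec$pixel_nm))
  ny <- max(1L, round(spec$height_nm / spec$pixel_nm))
  nz <- max(1L, round(spec$depth_um / spec$voxel_z_um))

  # voxel-center physical coordinates, um
  xc <- (seq_len(nx) - 0.5) * px_um
  yc <- (seq_len(ny) - 0.5) * px_um
  zc <- (seq_len(nz) - 0.5) * spec$voxel_z_um
  w_um <- spec$width_nm / 1000; h_um <- spec$height_nm / 1000
  d_um <- spec$depth_um

  mask <- array(TRUE, c(nx, ny, nz))
  semi <- NULL
  rho_inner <- -Inf
  if (shell$type == "ellipsoid") {
    semi <- c(w_um, h_um, d_um) / 2
    rho <- sqrt(outer(outer(((xc - w_um / 2) / semi[1])^2,
                            ((yc - h_um / 2) / semi[2])^2, "+"),
                      ((zc - d_um / 2) / semi[3])^2, "+"))
    rho_inner <- 1 - shell$thickness_um / min(semi)
    mask <- rho <= 1 & rho >= rho_inner
    if (!any(mask)) abort("membrane shell is empty at this geometry")
  }

  if (n_clusters == 0L) {
    stk <- withr::with_seed(spec$seed,
      array(rnorm(nx * ny * nz, 0, spec$noise_sd), c(nx, ny, nz)))
    truth <- tibble::tibble(id = integer(), x_um = numeric(), y_um = numeric(),
                            z_um = numeric(), volume_um3 = numeric())
    return(structure(list(stack = stk, mask = mask, truth = truth,
                          spec = spec, shell = shell),
                     class = "confocal_stack"))
  }
  check_number(mean_volume_um3, "mean_volume_um3", lower = 1e-12)
  check_number(min_volume_um3, "min_volume_um3", lower = 0)
  if (min_volume_um3 >= mean_volume_um3) {
    abort("`min_volume_um3` must be smaller than `mean_volume_um3`.")
  }

  mask_idx <- which(mask, arr.ind = TRUE)
  margin_um <- margin_nm / 1000

  out <- withr::with_seed(spec$seed, {
    vols <- min_volume_um3 +
      rexp(n_clusters, 1 / (mean_volume_um3 - min_volume_um3))
    radii <- (3 * vols / (4 * pi))^(1 / 3)
    xs <- ys <- zs <- numeric(n_clusters)
    for (i in seq_len(n_clusters)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        v <- mask_idx[sample.int(nrow(mask_idx), 1L), ]
        x <- (v[1] - 1 + runif(1)) * px_um
        y <- (v[2] - 1 + runif(1)) * px_um
        z <- (v[3] - 1 + runif(1)) * spec$voxel_z_um
        r <- radii[i]
        if (x < r || x > w_um - r || y < r || y > h_um - r ||
            z < r || z > d_um - r) next
        if (contain == "full" && !is.null(semi)) {
          # conservative: consecutive rho level sets are at least
          # (delta rho) * min(semi) apart, so these bounds keep the whole
          # sphere inside the shell
          rho_pt <- sqrt(((x - w_um / 2) / semi[1])^2 +
                           ((y - h_um / 2) / semi[2])^2 +
                           ((z - d_um / 2) / semi[3])^2)
          if (rho_pt > 1 - r / min(semi) ||
              rho_pt < rho_inner + r / min(semi)) next
        }
        if (i > 1L) {
          j <- seq_len(i - 1L)
          if (any((xs[j] - x)^2 + (ys[j] - y)^2 + (zs[j] - z)^2 <=
                    (radii[j] + r + margin_um)^2)) next
        }
        xs[i] <- x; ys[i] <- y; zs[i] <- z
        placed <- TRUE
        break
      }
      if (!placed) {
        abort(sprintf(paste0(
          "could not place cluster %d after %d retries: shell too thin or ",
          "field too dense for %d non-overlapping spheres of mean volume ",
          "%.3g um3"), i, max_retries, n_clusters, mean_volume_um3))
      }
    }

    stk <- array(0, c(nx, ny, nz))
    for (i in seq_len(n_clusters)) {
      r <- radii[i]
      i0 <- max(1L, floor((xs[i] - r) / px_um)); i1 <- min(nx, ceiling((xs[i] + r) / px_um) + 1L)
      j0 <- max(1L, floor((ys[i] - r) / px_um)); j1 <- min(ny, ceiling((ys[i] + r) / px_um) + 1L)
      k0 <- max(1L, floor((zs[i] - r) / spec$voxel_z_um))
      k1 <- min(nz, ceiling((zs[i] + r) / spec$voxel_z_um) + 1L)
      ii <- i0:i1; jj <- j0:j1; kk <- k0:k1
      d2 <- outer(outer((xc[ii] - xs[i])^2, (yc[jj] - ys[i])^2, "+"),
                  (zc[kk] - zs[i])^2, "+")
      # linear-ramp partial volume over one lateral pixel width
      cov <- pmin(pmax((r - sqrt(d2)) / px_um + 0.5, 0), 1)
      s <- sum(cov)
      # rescale so rendered mass equals the drawn volume (in voxel units)
      # exactly; the ramp otherwise adds (pi/3) r w^2 of volume per sphere
      if (s > 0) cov <- cov * (vols[i] / (px_um^2 * spec$voxel_z_um) / s)
      stk[ii, jj, kk] <- stk[ii, jj, kk] + cov
    }
    if (spec$psf_sigma_nm > 0) {
      sig <- c(spec$psf_sigma_nm / spec$pixel_nm,
               spec$psf_sigma_nm / spec$pixel_nm,
               spec$psf_sigma_nm / (spec$voxel_z_um * 1000))
      stk <- gaussian_smooth_3d(stk, sig)
    }
    if (spec$noise_sd > 0) {
      stk <- stk + array(rnorm(nx * ny * nz, 0, spec$noise_sd), c(nx, ny, nz))
    }
    list(stack = stk,
         truth = tibble::tibble(id = seq_len(n_clusters), x_um = xs,
                                y_um = ys, z_um = zs, volume_um3 = vols))
  })
  structure(list(stack = out$stack, mask = mask, truth = out$truth,
                 spec = spec, shell = shell),
            class = "confocal_stack")
}
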