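# Cluster segmentation from 2D renders and 3D stacks.
#
# Sizes are reported two ways: `n_px` (supra-threshold pixel/voxel count) and
# the primary size column (integrated intensity over the one-pixel-dilated
# component, scaled by pixel/voxel size, floored at threshold * n_px). The
# intensity integral is a partial-volume-corrected size: it is unbiased for
# anti-aliased footprints where pure pixel counting quantizes small clusters
# by a pixel, and zero-mean noise cancels in expectation. Threshold
# monotonicity (raising the threshold never grows the total) is guaranteed
# for the pixel-count size.

shift_2d <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

dilate_labels_2d <- function(labels) {
  out <- labels
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sh <- shift_2d(labels, dr, dc)
    fill <- out == 0L & sh > 0L
    out[fill] <- sh[fill]
  }
  out
}

shift_3d <- function(a, d) {
  dm <- dim(a)
  out <- array(0L, dm)
  idx <- lapply(1:3, function(ax) {
    s <- seq_len(dm[ax]) - d[ax]
    s
  })
  ok <- lapply(1:3, function(ax) idx[[ax]] >= 1L & idx[[ax]] <= dm[ax])
  out[ok[[1]], ok[[2]], ok[[3]]] <-
    a[idx[[1]][ok[[1]]], idx[[2]][ok[[2]]], idx[[3]][ok[[3]]]]
  out
}

dilate_labels_3d <- function(labels) {
  out <- labels
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    sh <- shift_3d(labels, c(dx, dy, dz))
    fill <- out == 0L & sh > 0L
    out[fill] <- sh[fill]
  }
  out
}

labeled_tbl <- function(df, labels, dim, size_unit, threshold, calibration) {
  out <- tibble::as_tibble(df)
  attr(out, "labels") <- labels
  attr(out, "img_dim") <- dim
  attr(out, "size_unit") <- size_unit
  attr(out, "threshold") <- threshold
  attr(out, "calibration") <- calibration
  class(out) <- c("labeled_clusters", class(out))
  out
}

#' Segment clusters from a 2D localization render
#'
#' Thresholds the image and extracts 8-connected components; components below
#' `min_px` pixels are discarded. Areas are reported in nm2 from the pixel
#' pitch, using the partial-volume-corrected intensity integral (see
#' Details in [segment_3d()]).
#'
#' @param image Numeric matrix (intensity render, indexed `[x, y]`).
#' @param pixel_nm Pixel pitch, nm/px (required; units are never assumed).
#' @param threshold Fixed intensity threshold.
#' @param min_px Minimum component size in pixels (default 2, suppressing
#'   single-pixel noise excursions).
#' @return A `labeled_clusters` tibble: id, x_nm, y_nm, area_nm2, n_px,
#'   membrane_overlap (NA until [restrict_to_membrane()] is applied). The
#'   label matrix and calibration ride along as attributes.
#' @examples
#' f <- gen_localization_field(field_spec(2000, 2000, seed = 1), 5, 2500)
#' segment_2d(f$image, pixel_nm = 20, threshold = 0.5)
#' @export
segment_2d <- function(image, pixel_nm, threshold, min_px = 2L) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("`image` must be a numeric matrix.")
  }
  if (missing(pixel_nm)) abort("`pixel_nm` calibration is required.")
  check_number(pixel_nm, "pixel_nm", lower = 1e-9)
  check_number(threshold, "threshold")
  min_px <- check_count(min_px, "min_px", lower = 1L)

  labels <- .cc_label_2d(image > threshold)
  n_lab <- attr(labels, "n_labels")
  empty <- tibble::tibble(id = integer(), x_nm = numeric(), y_nm = numeric(),
                          area_nm2 = numeric(), n_px = integer(),
                          membrane_overlap = logical())
  if (n_lab == 0L) {
    return(labeled_tbl(empty, labels, dim(image), "nm2", threshold,
                       list(pixel_nm = pixel_nm)))
  }
  npx <- tabulate(labels[labels > 0L], nbins = n_lab)
  keep <- which(npx >= min_px)
  if (length(keep) == 0L) {
    labels[labels > 0L] <- 0L
    return(labeled_tbl(empty, labels, dim(image), "nm2", threshold,
                       list(pixel_nm = pixel_nm)))
  }
  # drop rejected labels, renumber kept ones 1..k
  remap <- integer(n_lab)
  remap[keep] <- seq_along(keep)
  pos <- labels > 0L
  labels[pos] <- remap[labels[pos]]

  pos <- which(labels > 0L)
  lab_v <- labels[pos]
  rows <- (pos - 1L) %% nrow(image) + 1L
  cols <- (pos - 1L) %/% nrow(image) + 1L
  x_nm <- (tapply(rows, lab_v, mean) - 0.5) * pixel_nm
  y_nm <- (tapply(cols, lab_v, mean) - 0.5) * pixel_nm

  labd <- dilate_labels_2d(labels)
  posd <- which(labd > 0L)
  isum <- as.numeric(rowsum(image[posd], labd[posd]))
  # zero-mean noise on the dilated ring cancels in expectation; floor at the
  # guaranteed mass of the supra-threshold core so sizes stay positive
  isum <- pmax(isum, max(threshold, 0) * npx[keep])
  area_nm2 <- isum * pixel_nm^2

  out <- tibble::tibble(id = seq_along(keep),
                        x_nm = as.numeric(x_nm), y_nm = as.numeric(y_nm),
                        area_nm2 = area_nm2, n_px = npx[keep],
                        membrane_overlap = NA)
  labeled_tbl(out, labels, dim(image), "nm2", threshold,
              list(pixel_nm = pixel_nm))
}

#' Segment clusters from a 3D intensity stack
#'
#' Thresholds the stack and extracts 26-connected components. Components are
#' kept only if they span at least two voxels and their bounding box exceeds
#' the minimum lateral/axial diameters (defaults 100 nm in x/y and 150 nm in
#' z, the usual puncta-size floor for confocal spot detection). Volumes are
#' in um3; the primary volume is the integrated intensity over the
#' one-voxel-dilated component times the voxel volume (partial-volume
#' corrected), with the raw voxel count in `n_px`.
#'
#' @param stack Numeric 3D array, indexed `[x, y, z]`.
#' @param voxel_size Numeric pair `c(xy_nm, z_um)`: lateral pitch in nm and
#'   axial step in um. Required; units are never assumed.
#' @param threshold Fixed intensity threshold.
#' @param min_diameter_nm Numeric pair `c(xy, z)` in nm; bounding-box floor.
#' @param min_voxels Minimum voxel count (default 2).
#' @return A `labeled_clusters` tibble: id, x_um, y_um, z_um, volume_um3,
#'   footprint_um2 (area of the cluster's x/y projection), n_px,
#'   membrane_overlap.
#' @examples
#' spec <- field_spec(4000, 4000, depth_um = 2.6, pixel_nm = 100, seed = 3)
#' st <- gen_confocal_stack(spec, 5, 0.09, membrane_shell("all"))
#' segment_3d(st$stack, voxel_size = c(100, 0.13), threshold = 0.5)
#' @export
segment_3d <- function(stack, voxel_size, threshold,
                       min_diameter_nm = c(100, 150), min_voxels = 2L) {
  if (!is.array(stack) || length(dim(stack)) != 3L) {
    abort("`stack` must be a 3D numeric array.")
  }
  if (missing(voxel_size)) abort("`voxel_size` calibration is required.")
  if (!is.numeric(voxel_size) || length(voxel_size) != 2L ||
      any(voxel_size <= 0)) {
    abort("`voxel_size` must be c(xy_nm, z_um), both positive.")
  }
  check_number(threshold, "threshold")
  stopifnot(length(min_diameter_nm) == 2L)
  min_voxels <- check_count(min_voxels, "min_voxels", lower = 1L)

  xy_nm <- voxel_size[1]; z_um <- voxel_size[2]
  dm <- dim(stack)
  labels_v <- .cc_label_3d(as.vector(stack > threshold), as.integer(dm))
  n_lab <- attr(labels_v, "n_labels")
  labels <- array(labels_v, dm)
  empty <- tibble::tibble(id = integer(), x_um = numeric(), y_um = numeric(),
                          z_um = numeric(), volume_um3 = numeric(),
                          footprint_um2 = numeric(), n_px = integer(),
                          membrane_overlap = logical())
  cal <- list(xy_nm = xy_nm, z_um = z_um)
  if (n_lab == 0L) {
    return(labeled_tbl(empty, labels, dm, "um3", threshold, cal))
  }

  pos <- which(labels > 0L)
  lab_v <- labels[pos]
  ix <- (pos - 1L) %% dm[1] + 1L
  iy <- ((pos - 1L) %/% dm[1]) %% dm[2] + 1L
  iz <- (pos - 1L) %/% (dm[1] * dm[2]) + 1L

  npx <- tabulate(lab_v, nbins = n_lab)
  ext_x <- (tapply(ix, lab_v, max) - tapply(ix, lab_v, min) + 1L) * xy_nm
  ext_y <- (tapply(iy, lab_v, max) - tapply(iy, lab_v, min) + 1L) * xy_nm
  ext_z <- (tapply(iz, lab_v, max) - tapply(iz, lab_v, min) + 1L) * z_um * 1000
  keep <- which(npx >= min_voxels &
                  ext_x >= min_diameter_nm[1] & ext_y >= min_diameter_nm[1] &
                  ext_z >= min_diameter_nm[2])
  if (length(keep) == 0L) {
    labels[labels > 0L] <- 0L
    return(labeled_tbl(empty, labels, dm, "um3", threshold, cal))
  }
  remap <- integer(n_lab)
  remap[keep] <- seq_along(keep)
  sel <- labels > 0L
  labels[sel] <- remap[labels[sel]]

  pos <- which(labels > 0L)
  lab_v <- labels[pos]
  ix <- (pos - 1L) %% dm[1] + 1L
  iy <- ((pos - 1L) %/% dm[1]) %% dm[2] + 1L
  iz <- (pos - 1L) %/% (dm[1] * dm[2]) + 1L
  px_um <- xy_nm / 1000
  x_um <- (tapply(ix, lab_v, mean) - 0.5) * px_um
  y_um <- (tapply(iy, lab_v, mean) - 0.5) * px_um
  z_um_c <- (tapply(iz, lab_v, mean) - 0.5) * z_um

  # footprint: distinct (x, y) columns per cluster
  colkey <- ix + (iy - 1L) * dm[1]
  fp <- vapply(split(colkey, lab_v), function(v) length(unique(v)), integer(1))
  footprint_um2 <- as.numeric(fp) * px_um^2

  labd <- dilate_labels_3d(labels)
  posd <- which(labd > 0L)
  isum <- as.numeric(rowsum(stack[posd], labd[posd]))
  isum <- pmax(isum, max(threshold, 0) * npx[keep])
  voxel_um3 <- px_um^2 * z_um
  volume_um3 <- isum * voxel_um3

  out <- tibble::tibble(id = seq_along(keep),
                        x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                        z_um = as.numeric(z_um_c),
                        volume_um3 = volume_um3,
                        footprint_um2 = footprint_um2,
                        n_px = npx[keep], membrane_overlap = NA)
  labeled_tbl(out, labels, dm, "um3", threshold, cal)
}

#' Keep only clusters overlapping a membrane mask
#'
#' Restricts a segmented cluster set to those that touch the (WGA-style)
#' membrane mask. Under `rule = "any"` a cluster is kept if at least one of
#' its voxels lies inside the mask; under `rule = "centroid"` its centroid
#' voxel must be inside.
#'
#' @param clusters A `labeled_clusters` tibble from [segment_2d()] or
#'   [segment_3d()].
#' @param mask Logical array with the same dimensions as the source image.
#' @param rule `"any"` (default) or `"centroid"`.
#' @return The filtered `labeled_clusters` tibble with `membrane_overlap`
#'   set to TRUE for the retained clusters.
#' @export
restrict_to_membrane <- function(clusters, mask, rule = c("any", "centroid")) {
  rule <- match.arg(rule)
  if (!inherits(clusters, "labeled_clusters")) {
    abort("`clusters` must come from segment_2d()/segment_3d().")
  }
  labels <- attr(clusters, "labels")
  dm <- attr(clusters, "img_dim")
  if (!isTRUE(all.equal(dim(mask), dm)) &&
      !identical(as.integer(dim(mask)), as.integer(dm))) {
    abort(sprintf("mask dimensions (%s) do not match source image (%s)",
                  paste(dim(mask), collapse = "x"),
                  paste(dm, collapse = "x")))
  }
  mask <- array(as.logical(mask), dm)
  if (nrow(clusters) == 0L) return(clusters)

  if (rule == "any") {
    inside <- sort(unique(labels[labels > 0L & mask]))
    keep <- clusters$id %in% inside
  } else {
    cal <- attr(clusters, "calibration")
    if (length(dm) == 2L) {
      ixs <- pmin(pmax(round(clusters$x_nm / cal$pixel_nm + 0.5), 1L), dm[1])
      iys <- pmin(pmax(round(clusters$y_nm / cal$pixel_nm + 0.5), 1L), dm[2])
      keep <- mask[cbind(ixs, iys)]
    } else {
      px_um <- cal$xy_nm / 1000
      ixs <- pmin(pmax(round(clusters$x_um / px_um + 0.5), 1L), dm[1])
      iys <- pmin(pmax(round(clusters$y_um / px_um + 0.5), 1L), dm[2])
      izs <- pmin(pmax(round(clusters$z_um / cal$z_um + 0.5), 1L), dm[3])
      keep <- mask[cbind(ixs, iys, izs)]
    }
  }
  out <- clusters[keep, , drop = FALSE]
  out$membrane_overlap <- TRUE
  kept_ids <- clusters$id[keep]
  labels[!(labels %in% kept_ids)] <- 0L
  attr(out, "labels") <- labels
  attr(out, "img_dim") <- dm
  attr(out, "size_unit") <- attr(clusters, "size_unit")
  attr(out, "threshold") <- attr(clusters, "threshold")
  attr(out, "calibration") <- attr(clusters, "calibration")
  class(out) <- class(clusters)
  out
}

#' Reduce a super-resolution render to confocal-like resolution
#'
#' Gaussian blur whose kernel radius in pixels equals
#' `kernel_radius_nm / pixel_nm`; the Gaussian sigma is half the radius, so
#' the kernel effectively averages intensity over the stated neighborhood.
#' The kernel is normalized, conserving total intensity away from the image
#' border (reflect padding is used at the border).
#'
#' @param image Numeric matrix.
#' @param pixel_nm Pixel pitch, nm/px.
#' @param kernel_radius_nm Blur radius, nm (default 200, which degrades a
#'   ~40 nm-resolution render to confocal-like resolution).
#' @return Blurred matrix of the same dimensions.
#' @export
gaussian_blur_match <- function(image, pixel_nm, kernel_radius_nm = 200) {
  if (!is.matrix(image)) abort("`image` must be a matrix.")
  check_number(pixel_nm, "pixel_nm", lower = 1e-9)
  check_number(kernel_radius_nm, "kernel_radius_nm", lower = 0)
  if (kernel_radius_nm < pixel_nm) {
    abort(sprintf("blur kernel radius (%g nm) is smaller than one pixel (%g nm)",
                  kernel_radius_nm, pixel_nm))
  }
  gaussian_smooth_2d(image, (kernel_radius_nm / 2) / pixel_nm)
}
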