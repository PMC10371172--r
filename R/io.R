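# Disk round-trips for synthetic fields, stacks and traces: TIFF images with
# a JSON sidecar carrying the physical calibration (the sidecar is the
# authoritative source of pixel sizes), and CSV ground truth / traces.

need_tiff <- function() {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("writing/reading TIFF requires the 'tiff' package")
  }
}

# tiff stores [0,1] floats; remember the affine rescale in the sidecar.
scale_unit <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) rng[2] <- rng[1] + 1
  list(data = (x - rng[1]) / (rng[2] - rng[1]),
       offset = rng[1], scale = rng[2] - rng[1])
}

write_json_pretty <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
}

#' Write a synthetic localization field to disk
#'
#' Emits `<name>.tif` (intensity render), `<name>_truth.csv` (one row per
#' cluster) and `<name>_spec.json` (field geometry plus the intensity
#' rescale used for the TIFF).
#'
#' @param field A `localization_field` from [gen_localization_field()].
#' @param dir Output directory (created if needed).
#' @param name File stem.
#' @return Invisibly, the paths written.
#' @export
write_localization_field <- function(field, dir, name = "field") {
  stopifnot(inherits(field, "localization_field"))
  need_tiff()
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- scale_unit(field$image)
  tif <- file.path(dir, paste0(name, ".tif"))
  # transpose: TIFF rows are y
  tiff::writeTIFF(t(sc$data), tif, bits.per.sample = 16L)
  truth_csv <- file.path(dir, paste0(name, "_truth.csv"))
  readr::write_csv(field$truth, truth_csv)
  side <- file.path(dir, paste0(name, "_spec.json"))
  write_json_pretty(c(unclass(field$spec),
                      list(intensity_offset = sc$offset,
                           intensity_scale = sc$scale)), side)
  invisible(c(tif, truth_csv, side))
}

#' Read a localization field written by [write_localization_field()]
#'
#' @param dir Directory holding the files.
#' @param name File stem.
#' @return List with `image` (matrix, intensity rescaled back) and `spec`
#'   (named list from the sidecar).
#' @export
read_localization_field <- function(dir, name = "field") {
  need_tiff()
  side <- jsonlite::read_json(file.path(dir, paste0(name, "_spec.json")),
                              simplifyVector = TRUE)
  img <- t(tiff::readTIFF(file.path(dir, paste0(name, ".tif"))))
  img <- img * side$intensity_scale + side$intensity_offset
  list(image = img, spec = side)
}

#' Write a synthetic confocal stack to disk
#'
#' Emits a multi-page `<name>.tif` (one page per z-plane), a binary
#' `<name>_mask.tif`, `<name>_truth.csv` and `<name>_spec.json`.
#'
#' @param stack A `confocal_stack` from [gen_confocal_stack()].
#' @param dir Output directory.
#' @param name File stem.
#' @return Invisibly, the paths written.
#' @export
write_confocal_stack <- function(stack, dir, name = "stack") {
  stopifnot(inherits(stack, "confocal_stack"))
  need_tiff()
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- scale_unit(stack$stack)
  nz <- dim(stack$stack)[3]
  pages <- lapply(seq_len(nz), function(k) t(sc$data[, , k]))
  tif <- file.path(dir, paste0(name, ".tif"))
  tiff::writeTIFF(pages, tif, bits.per.sample = 16L)
  mask_tif <- file.path(dir, paste0(name, "_mask.tif"))
  tiff::writeTIFF(lapply(seq_len(nz), function(k) t(stack$mask[, , k]) * 1),
                  mask_tif, bits.per.sample = 8L)
  truth_csv <- file.path(dir, paste0(name, "_truth.csv"))
  readr::write_csv(stack$truth, truth_csv)
  side <- file.path(dir, paste0(name, "_spec.json"))
  write_json_pretty(c(unclass(stack$spec),
                      list(shell_type = stack$shell$type,
                           shell_thickness_um = stack$shell$thickness_um,
                           intensity_offset = sc$offset,
                           intensity_scale = sc$scale)), side)
  invisible(c(tif, mask_tif, truth_csv, side))
}

#' Write a sparklet trace as CSV with a JSON sidecar
#'
#' @param trace A `sparklet_trace` (or data frame with `time_s`, `df`).
#' @param path CSV path; the sidecar is written next to it as
#'   `<path basename>.json`.
#' @return Invisibly, the paths written.
#' @export
write_sparklet_trace <- function(trace, path) {
  stopifnot(is.data.frame(trace))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  keep <- intersect(c("time_s", "df"), names(trace))
  readr::write_csv(tibble::as_tibble(trace)[keep], path)
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  write_json_pretty(list(fs_hz = attr(trace, "fs_hz") %||% 100,
                         quantal_df = attr(trace, "quantal_df")), side)
  invisible(c(path, side))
}

#' Read a sparklet trace written by [write_sparklet_trace()]
#'
#' @param path CSV path (sidecar `<stem>.json` is read when present).
#' @return A `sparklet_trace` tibble with `fs_hz`/`quantal_df` attributes.
#' @export
read_sparklet_trace <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(out, "fs_hz") <- meta$fs_hz
    attr(out, "quantal_df") <- meta$quantal_df
  }
  class(out) <- c("sparklet_trace", class(out))
  out
}
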