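#' Sphere diameter implied by a cluster volume
#'
#' Treating a cluster volume as spherical, `d = (6 V / pi)^(1/3)`. The result
#' is in nm for a volume in um3.
#'
#' @param volume_um3 Volume(s) in um3, all > 0.
#' @param round_to_nm Optional rounding grain in nm (e.g. 10 to report to the
#'   nearest 10 nm); default no rounding.
#' @return Diameter(s) in nm.
#' @examples
#' sphere_diameter_from_volume(0.09, round_to_nm = 10)  # 560
#' sphere_diameter_from_volume(pi / 6)                  # 1000
#' @export
sphere_diameter_from_volume <- function(volume_um3, round_to_nm = NULL) {
  if (!is.numeric(volume_um3) || length(volume_um3) == 0L ||
      any(!is.finite(volume_um3)) || any(volume_um3 <= 0)) {
    abort("`volume_um3` must be positive and finite.")
  }
  d <- (6 * volume_um3 / pi)^(1 / 3) * 1000
  if (!is.null(round_to_nm)) {
    check_number(round_to_nm, "round_to_nm", lower = 1e-9)
    d <- round(d / round_to_nm) * round_to_nm
  }
  d
}

#' Macro-cluster volume threshold
#'
#' A cluster larger than the threshold volume counts as a macro-cluster;
#' anything at or below it is a micro-cluster. The default 0.03 um3
#' (sphere-equivalent diameter ~385 nm) is the conventional lower limit of a
#' confocally resolvable macro-cluster; 0.025 um3 is also in circulation for
#' native myocytes and can be passed instead.
#'
#' @param volume_um3 Threshold volume, um3.
#' @return A `macro_threshold` object with the volume and its
#'   sphere-equivalent diameter in nm.
#' @examples
#' macro_threshold()
#' macro_threshold(0.025)
#' @export
macro_threshold <- function(volume_um3 = 0.03) {
  check_number(volume_um3, "volume_um3", lower = 1e-12)
  structure(list(volume_um3 = volume_um3,
                 diameter_nm = sphere_diameter_from_volume(volume_um3)),
            class = "macro_threshold")
}

#' @export
print.macro_threshold <- function(x, ...) {
  cat(sprintf("Macro-cluster threshold: %.3g um3 (sphere diameter %.0f nm)\n",
              x$volume_um3, x$diameter_nm))
  invisible(x)
}

#' Classify clusters as macro or micro
#'
#' Macro iff size strictly exceeds the threshold volume; classification is
#' invariant under any unit-consistent rescaling of sizes and threshold.
#'
#' @param x Either a numeric vector of volumes in um3, or a
#'   `labeled_clusters`/data frame with a `volume_um3` column. A cluster table
#'   carrying only areas (nm2) is rejected: the threshold is a volume.
#' @param thr A [macro_threshold()] (or a single volume in um3).
#' @return A tibble with the sizes and a `class` factor (`"macro"`/`"micro"`).
#'   Use [macro_micro_fractions()] for the summary percentages.
#' @examples
#' classify_macro_micro(c(0.01, 0.05))
#' @export
classify_macro_micro <- function(x, thr = macro_threshold()) {
  if (is.numeric(thr)) thr <- macro_threshold(thr)
  stopifnot(inherits(thr, "macro_threshold"))
  if (is.numeric(x)) {
    sizes <- x
  } else if (is.data.frame(x)) {
    if (!"volume_um3" %in% names(x)) {
      abort(paste0("unit mismatch: the macro threshold is a volume (um3) but ",
                   "`x` has no `volume_um3` column (2D areas cannot be ",
                   "classified against a volume threshold)"))
    }
    sizes <- x$volume_um3
  } else {
    abort("`x` must be numeric sizes or a cluster table.")
  }
  if (any(!is.finite(sizes)) || any(sizes <= 0)) {
    abort("cluster sizes must be positive and finite")
  }
  tibble::tibble(volume_um3 = sizes,
                 class = factor(ifelse(sizes > thr$volume_um3,
                                       "macro", "micro"),
                                levels = c("macro", "micro")))
}

#' Macro/micro percentages of a classified cluster set
#'
#' @param x Numeric volumes (um3) or a cluster table (see
#'   [classify_macro_micro()]).
#' @param thr A [macro_threshold()].
#' @return One-row tibble: `n`, `macro_pct`, `micro_pct` (percentages of all
#'   classified clusters; they sum to 100 whenever `n > 0`).
#' @examples
#' macro_micro_fractions(c(0.01, 0.05))
#' @export
macro_micro_fractions <- function(x, thr = macro_threshold()) {
  cl <- classify_macro_micro(x, thr)
  n <- nrow(cl)
  if (n == 0L) {
    return(tibble::tibble(n = 0L, macro_pct = NA_real_, micro_pct = NA_real_))
  }
  macro <- 100 * mean(cl$class == "macro")
  tibble::tibble(n = n, macro_pct = macro, micro_pct = 100 - macro)
}

#' Per-cell summary of a segmented cluster set
#'
#' @param clusters A `labeled_clusters` tibble (2D or 3D), or any data frame
#'   with a size column (`area_nm2` or `volume_um3`) and, for membrane
#'   occupancy, a `footprint_um2` column (for 2D tables the footprint is the
#'   area itself).
#' @param cell_reference Cell footprint area (um2, for 2D/GSD data) or cell
#'   volume (um3, for stacks); used for the per-cell density.
#' @param membrane_area_um2 Optional membrane surface area, um2; enables
#'   `pct_membrane_occupied` = 100 * total cluster footprint / membrane area.
#' @param macro_thr Optional [macro_threshold()]; enables macro/micro
#'   percentages (3D volumes only).
#' @return One-row tibble: `clusters_per_cell`, `mean_size`, `total_size`,
#'   `density_per_unit` (clusters per unit of `cell_reference`),
#'   `pct_membrane_occupied`, and (when `macro_thr` is given) `macro_pct`,
#'   `micro_pct`. An empty cluster set gives a row of zeros, not an error.
#' @export
summarize_clusters <- function(clusters, cell_reference,
                               membrane_area_um2 = NULL, macro_thr = NULL) {
  check_number(cell_reference, "cell_reference", lower = 1e-12)
  df <- tibble::as_tibble(clusters)
  size_col <- if ("volume_um3" %in% names(df)) "volume_um3"
              else if ("area_nm2" %in% names(df)) "area_nm2"
              else abort("`clusters` needs an `area_nm2` or `volume_um3` column.")
  n <- nrow(df)
  sizes <- df[[size_col]]
  footprint_um2 <- if ("footprint_um2" %in% names(df)) df$footprint_um2
                   else if (size_col == "area_nm2") sizes / 1e6
                   else NULL
  out <- tibble::tibble(
    clusters_per_cell = n,
    mean_size = if (n > 0) mean(sizes) else 0,
    total_size = sum(sizes),
    density_per_unit = n / cell_reference,
    pct_membrane_occupied = NA_real_)
  if (!is.null(membrane_area_um2)) {
    check_number(membrane_area_um2, "membrane_area_um2", lower = 1e-12)
    if (is.null(footprint_um2)) {
      abort("membrane occupancy needs a `footprint_um2` column for 3D clusters")
    }
    out$pct_membrane_occupied <- 100 * sum(footprint_um2) / membrane_area_um2
  }
  if (!is.null(macro_thr) && n > 0) {
    fr <- macro_micro_fractions(if (size_col == "volume_um3") sizes else
      abort("macro/micro classification needs volumes in um3"), macro_thr)
    out$macro_pct <- fr$macro_pct
    out$micro_pct <- fr$micro_pct
  }
  out
}

#' Puncta density per unit membrane area
#'
#' Simple count-per-area metric for proximity-ligation (PLA) style puncta.
#'
#' @param points A data frame of detected puncta (one row each) or a single
#'   count.
#' @param cell_area_um2 Cell footprint area, um2 (> 0).
#' @return Density in puncta per um2.
#' @examples
#' puncta_density(35, 1000)  # 0.035
#' @export
puncta_density <- function(points, cell_area_um2) {
  check_number(cell_area_um2, "cell_area_um2", lower = 1e-12,
               allow_zero = FALSE)
  n <- if (is.data.frame(points)) nrow(points)
       else check_count(points, "points")
  n / cell_area_um2
}
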