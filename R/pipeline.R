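# Orchestration: run the synthetic-data -> analysis stages as one seeded,
# manifest-tracked pipeline. Every stage draws its randomness from a seed
# derived deterministically from the global seed and the stage name, so a
# run is reproducible stage by stage and bit-identical end to end.

pipeline_stage_names <- c("sizes", "field", "segment", "assembly",
                          "sparklets", "iv")

default_pipeline_config <- function() {
  list(
    sizes = list(n = 2000, scale = 0.08),
    field = list(width_nm = 12000, height_nm = 12000, pixel_nm = 20,
                 noise_sd = 0.1, n_clusters = 150, mean_area_nm2 = 2500,
                 min_area_nm2 = 1200),
    segment = list(threshold = 0.5),
    assembly = list(p_n = 0.5, p_g = 0.2, p_r = 0.02, grid_w = 128,
                    grid_h = 128, n_steps = 800),
    sparklets = list(n_sites = 3, n_channels = 3, p_open = 0.1,
                     kappa = 0.5, n_frames = 5000, quantal_df = 1,
                     noise_sd = 0.15),
    iv = list(density_100 = 7006, at_voltage = 50,
              fractions = c(1, 0.5, 0.1, 0.01))
  )
}

#' Run the synthetic-data and analysis pipeline
#'
#' Executes the requested stages in dependency order, writes each stage's
#' outputs under `out_dir`, and returns a manifest listing every file with
#' its checksum. Stage seeds are derived from `seed` with [derive_seed()];
#' re-running with the same configuration and seed reproduces every output
#' bit for bit.
#'
#' Stages: `"sizes"` (exponential size sample + fit), `"field"` (synthetic
#' localization render + ground truth), `"segment"` (segmentation and
#' exponential fit of the field; requires `"field"` in the same run or its
#' files already on disk), `"assembly"` (lattice self-assembly simulation +
#' fit), `"sparklets"` (coupled-gating traces + nPs/kappa analysis), `"iv"`
#' (functional-fraction current scan).
#'
#' @param stages Character vector of stage names (possibly empty).
#' @param out_dir Output directory.
#' @param seed Global integer seed.
#' @param config Named list of per-stage settings overriding the defaults
#'   (see `chancluster:::default_pipeline_config()` for the full set).
#' @return A `pipeline_manifest`: tibble with one row per output file
#'   (`stage`, `file`, `bytes`, `md5`); the run metadata (config hash, stage
#'   seeds, package version) is attached as attributes and written to
#'   `manifest.json`.
#' @examples
#' \donttest{
#' dir <- tempfile()
#' m <- run_pipeline(c("sizes", "iv"), dir, seed = 1)
#' m
#' }
#' @export
run_pipeline <- function(stages, out_dir, seed = 1L, config = list()) {
  stopifnot(is.character(stages) || length(stages) == 0L)
  stages <- as.character(stages)
  bad <- setdiff(stages, pipeline_stage_names)
  if (length(bad) > 0L) {
    abort(sprintf("unknown stage(s): %s (available: %s)",
                  paste(bad, collapse = ", "),
                  paste(pipeline_stage_names, collapse = ", ")))
  }
  check_count(seed, "seed")
  cfg <- default_pipeline_config()
  for (nm in names(config)) {
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], config[[nm]])
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # dependency order
  stages <- pipeline_stage_names[pipeline_stage_names %in% stages]

  files <- character()
  stage_of <- character()
  seeds <- lapply(setNames(stages, stages), derive_seed, seed = seed)
  state <- new.env(parent = emptyenv())

  add_files <- function(paths, stage) {
    files <<- c(files, paths)
    stage_of <<- c(stage_of, rep(stage, length(paths)))
  }

  for (stage in stages) {
    s <- seeds[[stage]]
    c_s <- cfg[[stage]]
    if (stage == "sizes") {
      sizes <- gen_cluster_sizes(c_s$n, c_s$scale, seed = s)
      p <- file.path(out_dir, "sizes.csv")
      readr::write_csv(tibble::tibble(size = sizes), p)
      fit <- fit_exponential(sizes)
      pj <- file.path(out_dir, "sizes_fit.json")
      write_json_pretty(list(scale = fit$scale, r_squared = fit$r_squared,
                             n_obs = fit$n_obs), pj)
      add_files(c(p, pj), stage)
    } else if (stage == "field") {
      spec <- field_spec(c_s$width_nm, c_s$height_nm, pixel_nm = c_s$pixel_nm,
                         noise_sd = c_s$noise_sd, seed = s)
      fld <- gen_localization_field(spec, c_s$n_clusters, c_s$mean_area_nm2,
                                    min_area_nm2 = c_s$min_area_nm2)
      state$field <- fld
      add_files(write_localization_field(fld, out_dir), stage)
    } else if (stage == "segment") {
      if (!is.null(state$field)) {
        img <- state$field$image
        pixel_nm <- state$field$spec$pixel_nm
        min_area <- cfg$field$min_area_nm2
      } else if (file.exists(file.path(out_dir, "field_spec.json"))) {
        fl <- read_localization_field(out_dir)
        img <- fl$image
        pixel_nm <- fl$spec$pixel_nm
        min_area <- cfg$field$min_area_nm2
      } else {
        abort("stage 'segment' needs a field image: run stage 'field' first")
      }
      cl <- segment_2d(img, pixel_nm, c_s$threshold)
      p <- file.path(out_dir, "clusters.csv")
      readr::write_csv(tibble::as_tibble(cl), p)
      fit <- fit_exponential(cl$area_nm2, min_size = min_area)
      pj <- file.path(out_dir, "clusters_fit.json")
      write_json_pretty(list(n_clusters = nrow(cl), scale = fit$scale,
                             r_squared = fit$r_squared), pj)
      add_files(c(p, pj), stage)
    } else if (stage == "assembly") {
      prm <- assembly_params(c_s$p_n, c_s$p_g, c_s$p_r, c_s$grid_w,
                             c_s$grid_h, c_s$n_steps, seed = s)
      res <- simulate_assembly(prm)
      p <- file.path(out_dir, "assembly_sizes.csv")
      readr::write_csv(tibble::tibble(size_sites = res$sizes,
                                      size_nm2 = res$sizes_nm2), p)
      pt <- file.path(out_dir, "assembly_trace.csv")
      readr::write_csv(res$trace, pt)
      out <- list(n_clusters = length(res$sizes), saturated = res$saturated)
      if (length(res$sizes) >= 30L && diff(range(res$sizes)) > 0) {
        fit <- fit_exponential(res$sizes)
        out$scale_sites <- fit$scale
        out$r_squared <- fit$r_squared
      }
      pj <- file.path(out_dir, "assembly_fit.json")
      write_json_pretty(out, pj)
      add_files(c(p, pt, pj), stage)
    } else if (stage == "sparklets") {
      site_rows <- purrr::map_dfr(seq_len(c_s$n_sites), function(i) {
        prm <- coupled_gating_params(c_s$n_channels, c_s$p_open, c_s$kappa,
                                     c_s$n_frames,
                                     seed = derive_seed(s, paste0("site", i)))
        tr <- gen_sparklet_trace(prm, c_s$quantal_df, c_s$noise_sd)
        write_sparklet_trace(tr, file.path(out_dir,
                                           sprintf("sparklet_site%02d.csv", i)))
        dplyr::mutate(analyze_sparklet(tr, quantal_df = c_s$quantal_df),
                      site = i, .before = 1)
      })
      tr_files <- file.path(out_dir, sprintf("sparklet_site%02d.%s",
                                             rep(seq_len(c_s$n_sites), each = 2),
                                             c("csv", "json")))
      p <- file.path(out_dir, "sparklet_sites.csv")
      readr::write_csv(site_rows, p)
      add_files(c(tr_files, p), stage)
    } else if (stage == "iv") {
      scan <- functional_fraction_scan(c_s$density_100,
                                       fractions = c_s$fractions,
                                       at_voltage = c_s$at_voltage)
      p <- file.path(out_dir, "iv_scan.csv")
      readr::write_csv(scan, p)
      add_files(p, stage)
    }
  }

  manifest <- tibble::tibble(
    stage = stage_of,
    file = basename(files),
    bytes = if (length(files)) file.size(files) else numeric(),
    md5 = if (length(files)) unname(tools::md5sum(files)) else character())
  meta <- list(
    package_version = as.character(utils::packageVersion("chancluster")),
    global_seed = as.integer(seed),
    stage_seeds = seeds,
    config_hash = unname(tools::md5sum(write_config_tmp(cfg[stages]))),
    stages = stages,
    files = as.list(setNames(manifest$md5, manifest$file)))
  write_json_pretty(meta, file.path(out_dir, "manifest.json"))
  attr(manifest, "meta") <- meta
  class(manifest) <- c("pipeline_manifest", class(manifest))
  manifest
}

write_config_tmp <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  write_json_pretty(cfg, tmp)
  tmp
}
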