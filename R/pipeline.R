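# End-to-end pipeline composition with a reproducibility manifest.
#
# A run is configured by a plain list (or YAML file) with these blocks:
#   seed:      integer driving every stochastic stage (split per stage)
#   simulate:  sim_params() overrides - when present, inputs are simulated
#   inputs:    rna_stack / granule_stack / cell_mask / nucleus_mask TIFF
#              paths and a lineage label - used when `simulate` is absent
#   config:    pipeline_config() overrides
#   unit_intensity: optional known single-molecule intensity; when absent
#              in simulation mode, a somatic companion embryo is simulated
#              and calibrated
# Outputs (spot/granule tables, summaries, manifest) are written under
# `out_dir`; deterministic stages reproduce bit-identical files from an
# identical manifest.

#' Run the full quantification pipeline
#'
#' Executes simulate (optional) -> detect -> calibrate/quantify -> segment
#' -> colocalize and writes all tables plus a run manifest. When no granule
#' channel is configured the segmentation and colocalization stages are
#' skipped with a warning and the remaining stages still run.
#'
#' @param config a list as described above, or the path of a YAML file.
#' @param out_dir output directory (created if needed).
#' @return the run manifest (a list), invisibly written to
#'   `manifest.json` as well.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  cfg <- do.call(pipeline_config, config$config %||% list())
  timings <- c()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- expr
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    gf_log("stage %-10s %7.2fs", stage, timings[[stage]])
    res
  }

  ## inputs -----------------------------------------------------------------
  granule_stack <- NULL; roi <- NULL; truth <- NULL
  if (!is.null(config$simulate)) {
    sp <- do.call(sim_params, config$simulate)
    sp$rng_seed <- sp$rng_seed %||% seed
    emb <- tick("simulate", generate_embryo(sp))
    rna_stack <- emb$rna; granule_stack <- emb$granule; roi <- emb$roi
    truth <- emb$truth
  } else if (!is.null(config$inputs)) {
    ins <- config$inputs
    rna_stack <- tick("read", read_stack(ins$rna_stack,
                                         pixel_size_xy = cfg$pixel_size_xy,
                                         z_step = cfg$z_step))
    if (!is.null(ins$granule_stack))
      granule_stack <- read_stack(ins$granule_stack,
                                  pixel_size_xy = cfg$pixel_size_xy,
                                  z_step = cfg$z_step, channel = "granule")
    if (!is.null(ins$cell_mask)) {
      cm <- read_stack(ins$cell_mask)$voxels > 0
      nm <- read_stack(ins$nucleus_mask)$voxels > 0
      roi <- cell_roi(cm, nm, lineage = ins$lineage %||% "somatic")
    }
  } else stop("config must name either a `simulate` block or `inputs`")

  ## detection + quantification --------------------------------------------
  spots <- tick("detect", detect_spots(rna_stack, cfg, roi = roi))
  unit <- config$unit_intensity
  calib <- NULL
  if (is.null(unit) && !is.null(config$simulate)) {
    # somatic companion: same optics, granule-free, single molecules
    sp2 <- do.call(sim_params, config$simulate)
    sp2$rng_seed <- (sp2$rng_seed %||% seed) + 104729L
    sp2$lineage <- "somatic"; sp2$p_granule <- 0
    sp2$cluster_size_mean <- 1; sp2$granule_channel <- FALSE
    emb2 <- tick("somatic", generate_embryo(sp2))
    som <- detect_spots(emb2$rna, cfg, roi = emb2$roi)
    calib <- calibrate_unit_intensity(som, min_spots = cfg$min_calibration_spots)
    unit <- calib$unit_intensity
  }
  if (!is.null(unit))
    spots <- tick("quantify",
                  assign_molecule_counts(spots, unit, cfg$cluster_min_molecules))

  ## granule segmentation + colocalization ----------------------------------
  granules <- NULL; coloc <- NULL
  if (is.null(granule_stack)) {
    warning("no granule channel configured; skipping segmentation and colocalization")
  } else {
    seg <- tick("segment", segment_granules(granule_stack, cfg))
    granules <- seg$granules
    cubes <- granule_bounding_cube(granules, cfg$cube_pad_px)
    if (!is.null(unit) && nrow(spots)) {
      spots$granule_id <- spot_in_granule(spots, cubes)
      coloc <- tick("colocalize", {
        pct <- pct_molecules_in_granules(spots, cubes)
        base <- if (!is.null(roi)) granule_occupancy_fraction(cubes, roi) else NA_real_
        list(pct_molecules_in_granules = pct,
             occupancy_baseline_pct = base,
             enrichment_above_baseline = pct - base,
             cytoplasm_fraction_pct =
               if (!is.null(roi)) cytoplasm_fraction(granules, roi) else NA_real_)
      })
    }
  }

  ## outputs -----------------------------------------------------------------
  paths <- list(spots = file.path(out_dir, "spots.csv"))
  write_table(spots, paths$spots)
  if (!is.null(granules) && nrow(granules)) {
    paths$granules <- file.path(out_dir, "granules.csv")
    write_table(granules, paths$granules)
  }
  summary <- list(n_spots = nrow(spots),
                  molecule_summary = if (!is.null(unit))
                    molecule_count_summary(spots) else NULL,
                  calibration = if (!is.null(calib))
                    calib[c("unit_intensity", "dispersion", "n_spots_used")]
                  else list(unit_intensity = unit),
                  colocalization = coloc)
  paths$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  manifest <- list(package_version = as.character(utils::packageVersion("granulefish")),
                   seed = seed,
                   config = unclass(cfg[!vapply(cfg, is.null, logical(1))]),
                   simulate = config$simulate,
                   inputs = config$inputs,
                   outputs = lapply(paths, function(p)
                     list(path = p, md5 = unname(tools::md5sum(p)))),
                   timings_s = as.list(timings))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
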