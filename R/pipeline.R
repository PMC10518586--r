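.known_stage_keys <- list(
  simulate = c("n_frames", "lipids_per_leaflet", "lateral_box",
               "head_plane_offset", "beads_per_lipid", "bead_spacing",
               "positional_jitter_sigma", "flavonoid_count", "box_height",
               "patch", "aggregate", "water", "format"),
  traj_analyze = c("input", "bin_width", "thickness_cell", "rdf_bin_width",
                   "hbond_dist_cutoff", "hbond_angle_cutoff", "z_cut",
                   "oo_cutoff", "window", "map_window"),
  saxs_fit = c("input", "q_min", "q_max", "n_layers", "generate",
               "fit_structure"),
  epr = c("input", "axx", "ayy", "azz", "calibrate"),
  afm = c("force_curve", "height_map", "modulus", "tip_radius",
          "breakthrough", "noise", "n_regions", "region_size",
          "map_shape", "waveform", "amplitude", "period", "sigma", "pixel")
)

.check_keys <- function(block, known, where) {
  bad <- setdiff(names(block), known)
  if (length(bad))
    stop("unknown configuration key(s) in ", where, ": ",
         paste(bad, collapse = ", "))
}

#' Run the full analysis pipeline from a YAML configuration
#'
#' Executes the requested stages in order (simulate, traj_analyze, saxs_fit,
#' epr, afm), writing per-stage TSV/JSON outputs and a combined JSON report
#' under the output directory. One top-level seed fans out deterministically
#' to per-stage seeds (stage seed = global seed + stage position in the run
#' order), so a rerun with the same configuration reproduces every number.
#' Stage failures are isolated: each failing stage is recorded in the report
#' with its error message and the report's `ok` flag is FALSE.
#'
#' Unknown configuration keys, at the top level or inside a stage block, are
#' rejected by name.
#'
#' @param config path to a YAML file or an equivalent named list with keys
#'   `seed`, `output_dir` and `stages` (named stage blocks).
#' @param output_dir overrides the configured output directory.
#' @return The report (list) invisibly; also written as `report.json`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  .check_keys(cfg, c("seed", "output_dir", "stages"), "top level")
  seed <- as.integer(cfg$seed %||% 1L)
  out <- output_dir %||% cfg$output_dir %||% stop("output_dir required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages <- cfg$stages
  if (is.null(stages) || !length(stages)) stop("no stages configured")
  order_all <- c("simulate", "traj_analyze", "saxs_fit", "epr", "afm")
  bad <- setdiff(names(stages), order_all)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  run_order <- intersect(order_all, names(stages))
  # configuration validation is a hard error, before any stage runs
  for (st in run_order)
    .check_keys(stages[[st]] %||% list(), .known_stage_keys[[st]],
                paste0("stage '", st, "'"))

  report <- list(package_version = as.character(utils::packageVersion("membraneprobe")),
                 r_version = R.version.string,
                 seed = seed, output_dir = out, stages = list())
  state <- new.env(parent = emptyenv())
  ok <- TRUE
  for (st in run_order) {
    stage_seed <- seed + match(st, order_all)
    message("[membraneprobe] stage ", st, " (seed ", stage_seed, ")")
    res <- tryCatch(
      .run_stage(st, stages[[st]] %||% list(), stage_seed, out, state),
      error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    if (is.null(res$ok)) res$ok <- TRUE
    res$seed <- stage_seed
    report$stages[[st]] <- res
    if (!res$ok) { ok <- FALSE; message("  stage failed: ", res$error) }
  }
  report$ok <- ok
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

.run_stage <- function(stage, block, seed, out, state) {
  .check_keys(block, .known_stage_keys[[stage]], paste0("stage '", stage, "'"))
  switch(stage,
    simulate = {
      patch <- if (!is.null(block$patch)) do.call(thin_patch_spec, block$patch)
      agg <- if (!is.null(block$aggregate)) do.call(aggregate_spec, block$aggregate)
      wat <- if (!is.null(block$water)) {
        wb <- block$water
        water_spec(wb$slab_bounds, wb$count,
                   wire = if (!is.null(wb$wire)) do.call(wire_spec, wb$wire))
      }
      args <- block[intersect(names(block),
                              c("lipids_per_leaflet", "lateral_box",
                                "head_plane_offset", "beads_per_lipid",
                                "bead_spacing", "positional_jitter_sigma",
                                "flavonoid_count", "box_height"))]
      spec <- do.call(bilayer_spec,
                      c(args, list(patch = patch, aggregate = agg,
                                   water = wat, seed = seed)))
      traj <- build_trajectory(spec, n_frames = block$n_frames %||% 5)
      fmt <- block$format %||% "gro"
      path <- file.path(out, paste0("trajectory.", fmt))
      write_trajectory(traj, path, fmt)
      write_manifest(traj, file.path(out, "manifest.json"))
      state$traj <- traj
      list(trajectory = path, manifest = file.path(out, "manifest.json"),
           n_frames = length(traj), n_particles = nrow(traj$frames[[1]]$positions))
    },
    traj_analyze = {
      traj <- if (!is.null(block$input)) read_trajectory(block$input)
              else state$traj %||% stop("no trajectory: run simulate or give 'input'")
      lf <- assign_leaflets(traj$frames[[1]])
      tmap <- interleaflet_distance_map(traj, cell = block$thickness_cell %||% 0.5,
                                        window = block$map_window %||% c(0.75, 1))
      utils::write.table(tmap$distance, file.path(out, "thickness_map.tsv"),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
      prof <- electron_density_profile(traj, bin_width = block$bin_width %||% 0.1)
      utils::write.table(prof, file.path(out, "electron_density.tsv"),
                         sep = "\t", row.names = FALSE)
      summary <- list(leaflet_counts = as.list(lf$counts),
                      midplane = lf$midplane,
                      thickness_mean = mean(tmap$distance[tmap$defined]))
      fam <- .species_family(traj$frames[[1]]$species)
      if (any(fam == "DDA")) {
        hb <- hbond_statistics(traj, window = block$window %||% c(0.25, 1),
                               dist_cutoff = block$hbond_dist_cutoff %||% 0.35,
                               angle_cutoff = block$hbond_angle_cutoff %||% 150)
        cl <- molecule_clusters(traj$frames[[length(traj)]])
        summary$hbonds <- list(mean = hb$mean, sd = hb$sd)
        summary$largest_cluster <- list(size = cl$sizes[1],
                                        z_span = cl$largest_z_span)
        rdf <- com_rdf(traj, family = "DDA", bin_width = block$rdf_bin_width %||% 0.05)
        utils::write.table(rdf, file.path(out, "rdf_dda.tsv"), sep = "\t",
                           row.names = FALSE)
      }
      if (any(traj$frames[[1]]$species == "WATER_O")) {
        wr <- water_analysis(traj, z_cut = block$z_cut %||% 1.0,
                             oo_cutoff = block$oo_cutoff %||% 0.35)
        summary$water <- list(penetrating = wr$penetrating_waters,
                              wire_present = wr$wire_present)
      }
      jsonlite::write_json(summary, file.path(out, "traj_summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      summary
    },
    saxs_fit = {
      curve <- if (!is.null(block$input)) read_saxs_curve(block$input)
      else {
        g <- block$generate %||% list()
        edp <- edp_params(g$rho %||% c(333, 250, 160, 270),
                          g$R %||% c(0.6, 1.4, 2.15),
                          g$sigma %||% c(0.30, 0.30, 0.28))
        mct <- mct_params(g$n_layers %||% 10, g$d_spacing %||% 6.3,
                          g$eta %||% 0.1, g$diffuse_fraction %||% 0.3)
        gen <- generate_saxs_curve(edp, mct, noise = g$noise %||% 0.01,
                                   seed = seed)
        write_saxs_curve(gen, file.path(out, "saxs_curve.dat"))
        gen
      }
      fit <- fit_saxs(curve,
                      q_window = c(block$q_min %||% 0.5, block$q_max %||% 2.5),
                      fit_structure = block$fit_structure %||% TRUE)
      res <- list(rho = fit$edp$rho, R = fit$edp$R, sigma = fit$edp$sigma,
                  d_spacing = fit$mct$d_spacing, eta = fit$mct$eta,
                  scale = fit$scale, reduced_chisq = fit$reduced_chisq,
                  converged = fit$converged,
                  uncertainties = as.list(fit$uncertainties))
      jsonlite::write_json(res, file.path(out, "saxs_fit.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      res
    },
    epr = {
      path <- block$input %||% system.file("extdata", "dsa_hyperfine.csv",
                                           package = "membraneprobe")
      tab <- read_epr_table(path)
      tensor <- if (isTRUE(block$calibrate) && "S_ref" %in% names(tab))
        calibrate_tensor(tab)$tensor
      else tensor_constants(block$axx %||% 6.1, block$ayy %||% 6.1,
                            block$azz %||% 32.9)
      res <- epr_analysis(tab, tensor)
      utils::write.table(res, file.path(out, "epr_order_parameters.tsv"),
                         sep = "\t", row.names = FALSE)
      list(n = nrow(res), S = res$S, samples = res$sample,
           tensor = unclass(tensor))
    },
    afm = {
      fc <- if (!is.null(block$force_curve)) read_force_curve(block$force_curve)
      else generate_force_curve(as.numeric(block$modulus %||% 2e7),
                                tip_radius = as.numeric(block$tip_radius %||% 2),
                                breakthrough = as.numeric(unlist(block$breakthrough) %||% c(200, 4)),
                                noise = as.numeric(block$noise %||% 5),
                                seed = seed)
      bt <- detect_breakthrough(fc)
      em <- fit_modulus(fc, breakthrough = bt)
      hm <- if (!is.null(block$height_map)) read_height_map(block$height_map)
      else generate_height_map(shape = block$map_shape %||% c(128, 128),
                               waveform = block$waveform %||% "gaussian_noise",
                               amplitude = block$amplitude %||% 1,
                               period = block$period %||% 8,
                               sigma = block$sigma %||% 0.3,
                               pixel = block$pixel %||% 0.1, seed = seed)
      rg <- roughness(hm, n_regions = block$n_regions %||% 4,
                      region_size = block$region_size %||% 64, seed = seed)
      res <- list(breakthrough = bt, modulus = em$modulus,
                  roughness = list(Ra = rg$Ra, Ra_se = rg$Ra_se,
                                   rms = rg$rms, rms_se = rg$rms_se))
      jsonlite::write_json(res, file.path(out, "afm_summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      res
    })
}
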