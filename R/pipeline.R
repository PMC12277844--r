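#' Classify every unit of a spike dataset and fit intensity-response curves
#'
#' Runs the full MEA per-unit analysis: for each unit, a PSTH of the
#' reference-intensity flash (the strongest flash by default) is computed at
#' the configured bin width, dark-segment baseline statistics give the
#' mean + 4 SD threshold, the smoothed PSTH is classified by the response
#' rules, and baseline-corrected peak responses at every intensity
#' (subthreshold peaks as 0) feed the Naka-Rushton fit. ON and ON-OFF units
#' contribute onset peaks, OFF units offset peaks.
#'
#' @param dataset a `spike_dataset`.
#' @param config a [grafteval_config].
#' @param reference_intensity intensity whose PSTH shape determines the
#'   label; defaults to the protocol's strongest flash.
#' @return list with `classes` (data frame `unit_id, electrode_id, label,
#'   onset_peak, offset_peak, threshold, mean_dark`), `ir_points` (data
#'   frame `unit_id, intensity, corrected_peak`) and `ir_fits` (data frame
#'   `unit_id, Rmin, Rmax, I50, n, sse, degenerate`).
#' @export
analyze_mea <- function(dataset, config = grafteval_config(),
                        reference_intensity = NULL) {
  stopifnot(inherits(dataset, "spike_dataset"),
            inherits(config, "grafteval_config"))
  protocol <- dataset$protocol
  ref <- reference_intensity %||% max(protocol$intensities)
  if (!ref %in% protocol$intensities)
    stopf("reference intensity %g is not in the protocol", ref)

  classes <- list(); ir_points <- list(); fits <- list()
  for (u in dataset$units$unit_id) {
    psths <- lapply(protocol$intensities, function(I)
      compute_psth(unit_trials(dataset, u, I), protocol, config$bin_width))
    names(psths) <- as.character(protocol$intensities)
    smooths <- lapply(psths, binomial_smooth, order = config$filter_order)
    # threshold statistics live on the same smoothing scale as the peaks
    # they gate: SD of the smoothed trace's dark bins
    base <- baseline_stats(smooths[[as.character(ref)]],
                           window = protocol$dark_window,
                           sd_multiplier = config$sd_multiplier,
                           min_duration = config$dark_duration)
    cls <- classify_rgc(smooths[[as.character(ref)]], base, protocol,
                        onset_window = config$onset_window,
                        offset_window = config$offset_window,
                        low_cutoff = config$low_signal_cutoff)
    el <- dataset$units$electrode_id[dataset$units$unit_id == u]
    classes[[u]] <- data.frame(unit_id = u, electrode_id = el,
                               label = cls$label,
                               onset_peak = cls$onset_peak,
                               offset_peak = cls$offset_peak,
                               threshold = base$threshold,
                               mean_dark = base$mean_rate,
                               stringsAsFactors = FALSE)
    win <- if (cls$label == "OFF") protocol$t_off + config$offset_window
           else c(protocol$t_on, protocol$t_on + config$onset_window)
    peaks <- vapply(smooths, peak_response, 0, baseline = base, window = win)
    ir_points[[u]] <- data.frame(unit_id = u,
                                 intensity = protocol$intensities,
                                 corrected_peak = unname(peaks),
                                 stringsAsFactors = FALSE)
    if (length(unique(peaks)) >= 2L && length(peaks) >= 3L) {
      f <- fit_intensity_response(
        ir_points[[u]][, c("intensity", "corrected_peak")],
        grid_size = config$ir_grid_size, n_range = config$ir_n_range)
      fits[[u]] <- data.frame(unit_id = u, Rmin = f$Rmin, Rmax = f$Rmax,
                              I50 = f$I50, n = f$n, sse = f$sse,
                              degenerate = f$degenerate,
                              stringsAsFactors = FALSE)
    }
  }
  list(classes = do.call(rbind, c(classes, list(make.row.names = FALSE))),
       ir_points = do.call(rbind, c(ir_points, list(make.row.names = FALSE))),
       ir_fits = if (length(fits))
         do.call(rbind, c(fits, list(make.row.names = FALSE)))
       else data.frame(unit_id = character(), Rmin = numeric(),
                       Rmax = numeric(), I50 = numeric(), n = numeric(),
                       sse = numeric(), degenerate = logical()))
}

write_table <- function(df, dir, name, log) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  log$stages[[length(log$stages) + 1L]] <- list(
    output = name, rows = nrow(df), time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  log
}

#' Run the full analysis pipeline on synthetic or file inputs
#'
#' Orchestrates the three analysis tracks in the published order — MEA
#' classification and intensity-response fitting, horizontal-cell mosaic
#' statistics, host-graft synapse quantification — and writes all result
#' tables, the configuration, a manifest and a run log to `out_dir`.
#' Without `inputs`, seeded generators produce a demonstration dataset
#' (a mixed RGC population on the 60-electrode layout with a central graft,
#' a control and a patchily thinned horizontal-cell mosaic, and a puncta
#' scene with planted synapses); all randomness flows from `config$seed`,
#' so identical configurations give byte-identical tables.
#'
#' @param config a [grafteval_config].
#' @param out_dir output directory (created; existing files overwritten).
#' @param inputs optional named list of file inputs replacing the
#'   generators: `spike_table` (CSV from [write_spike_table]),
#'   `pattern_control` / `pattern_degenerate` (CSVs from
#'   [write_point_pattern]), `scene_dir` (directory from
#'   [write_puncta_scene]). Missing files raise an error naming the path.
#' @return invisibly, a list with the main result objects and `out_dir`.
#' @export
run_pipeline <- function(config = grafteval_config(), out_dir,
                         inputs = NULL) {
  stopifnot(inherits(config, "grafteval_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = config$seed, stages = list())
  seed <- config$seed

  ## --- MEA track ---------------------------------------------------------
  if (!is.null(inputs$spike_table)) {
    dataset <- read_spike_table(inputs$spike_table)
  } else {
    layout <- electrode_layout()
    electrodes <- layout$positions$electrode_id
    types <- rep(c("ON", "ON", "OFF", "ON_OFF", "LOW", "NONE"), length.out = 12)
    # LOW cells need a quiet baseline for a sub-10-Hz peak to clear mean + 4SD
    cells <- lapply(seq_along(types), function(i)
      cell_spec(sprintf("u%02d", i), types[i],
                baseline_rate = if (types[i] == "LOW") 0.5 else 3,
                electrode_id = electrodes[(i * 5 - 4) %% length(electrodes) + 1]))
    dataset <- gen_spike_trains(
      stimulus_protocol(trials_per_intensity = 10), cells, seed = seed)
  }
  mea <- analyze_mea(dataset, config)
  layout <- electrode_layout()
  mask <- disc_mask(nrow = 150, ncol = 150, pixel_size = 10,
                    center = c(700, 700), radius = 250)
  areas <- assign_electrode_areas(mask, pixel_size = 10, layout,
                                  base_radius = config$dilation_base_radius,
                                  magnifications = config$dilation_magnifications)
  known <- mea$classes$electrode_id %in% areas$assignment$electrode_id
  summary_tab <- summarize_responses(mea$classes[known, , drop = FALSE], areas)
  log <- write_table(mea$classes, out_dir, "mea_classes.csv", log)
  log <- write_table(mea$ir_points, out_dir, "mea_ir_points.csv", log)
  log <- write_table(mea$ir_fits, out_dir, "mea_ir_fits.csv", log)
  log <- write_table(summary_tab, out_dir, "mea_summary.csv", log)

  ## --- Horizontal-cell track --------------------------------------------
  if (!is.null(inputs$pattern_control)) {
    pat_ctrl <- read_point_pattern(inputs$pattern_control)
    pat_deg <- read_point_pattern(inputs$pattern_degenerate)
  } else {
    field_ctrl <- field_spec()
    patches <- lapply(1:6, function(i)
      list(center = 900 * c(cos(i), sin(i)), radius = 250,
           deletion_prob = 0.8))
    field_deg <- field_spec(thinning_patches = patches)
    pat_ctrl <- gen_hc_pattern(field_ctrl, seed = seed + 1000L)
    pat_deg <- gen_hc_pattern(field_deg, seed = seed + 2000L)
  }
  circles <- place_sampling_circles(pat_ctrl$disc_center,
                                    pat_ctrl$disc_diameter,
                                    circle_diameter = config$circle_diameter)
  dens <- rbind(cbind(group = "control", circle_densities(pat_ctrl, circles)),
                cbind(group = "degenerate", circle_densities(pat_deg, circles)))
  nnd_ctrl <- nnd(pat_ctrl, bin_width = config$nnd_bin_width,
                  range_max = config$nnd_range_max)
  nnd_deg <- nnd(pat_deg, bin_width = config$nnd_bin_width,
                 range_max = config$nnd_range_max)
  comp <- do.call(rbind, lapply(c("proximal", "middle", "distal"), function(rg) {
    a <- dens$density_mm2[dens$group == "control" & dens$region == rg]
    b <- dens$density_mm2[dens$group == "degenerate" & dens$region == rg]
    ct <- compare_groups(a[!is.na(a)], b[!is.na(b)])
    data.frame(region = rg, U = ct$U, p = ct$p, exact = ct$exact)
  }))
  log <- write_table(dens, out_dir, "hc_densities.csv", log)
  log <- write_table(nnd_ctrl$histogram, out_dir, "hc_nnd_control.csv", log)
  log <- write_table(nnd_deg$histogram, out_dir, "hc_nnd_degenerate.csv", log)
  log <- write_table(comp, out_dir, "hc_comparison.csv", log)

  ## --- Synapse track -----------------------------------------------------
  if (!is.null(inputs$scene_dir)) {
    scene <- read_puncta_scene(inputs$scene_dir)
    truth <- NULL
  } else {
    gen <- gen_puncta_scene(scene_spec(), seed = seed + 3000L)
    scene <- gen$scene
    truth <- gen$ground_truth
  }
  records <- detect_synapses(scene, radius = config$synapse_radius)
  # demonstration rosette: a ball in the volume center, 1-um voxels
  ext <- c(60, 60, 30)
  vox <- c(2, 2, 2)
  dims <- ceiling(ext / vox)
  centers <- lapply(1:3, function(i) (seq_len(dims[i]) - 0.5) * vox[i])
  ball <- array(FALSE, dims)
  for (k in seq_len(dims[3])) {
    d2 <- outer((centers[[1]] - ext[1] / 2)^2,
                (centers[[2]] - ext[2] / 2)^2, "+") +
      (centers[[3]][k] - ext[3] / 2)^2
    ball[, , k] <- d2 <= 12^2
  }
  surface <- rosette_surface(ball, voxel_size = vox)
  selected <- select_rbcs_near_rosette(scene$dendrites, surface,
                                       reach = config$rbc_reach)
  per_rbc <- synapses_per_rbc(records, selected)
  proj_area_mm2 <- sum(apply(ball, c(1, 2), any)) * vox[1] * vox[2] / 1e6
  density <- forming_rbc_density(per_rbc$forming, proj_area_mm2)
  rbc_tab <- data.frame(cell_id = names(per_rbc$counts),
                        n_synapses = as.integer(per_rbc$counts),
                        forming = names(per_rbc$counts) %in% per_rbc$forming,
                        stringsAsFactors = FALSE)
  log <- write_table(records, out_dir, "synapse_records.csv", log)
  log <- write_table(rbc_tab, out_dir, "rbc_counts.csv", log)

  ## --- Manifest, config, log --------------------------------------------
  cfg_path <- file.path(out_dir, "config.yaml")
  save_config(config, cfg_path)
  manifest <- list(
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_units = nrow(dataset$units),
    n_spikes = nrow(dataset$spikes),
    n_hc_control = nrow(pat_ctrl$points),
    n_hc_degenerate = nrow(pat_deg$points),
    n_synapse_records = nrow(records),
    n_rbc_selected = length(selected),
    mean_synapses_per_rbc = per_rbc$mean_count,
    forming_rbc_density_mm2 = density,
    graft_projected_area_mm2 = proj_area_mm2)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(log, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(out_dir = out_dir, mea = mea, summary = summary_tab,
                 densities = dens, comparison = comp, records = records,
                 per_rbc = per_rbc, forming_density = density,
                 ground_truth = truth, manifest = manifest))
}
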