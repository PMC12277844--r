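# Canonical on-disk formats: CSV with header, UTF-8, "." decimal; geometry
# and ground truth as JSON sidecars.

require_file <- function(path) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  path
}

#' Write / read a spike table
#'
#' Delimited text with columns
#' `(unit_id, electrode_id, intensity, trial, t_spike_s)` plus a JSON
#' sidecar carrying the stimulus protocol, so a dataset round-trips.
#'
#' @param dataset a `spike_dataset`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.protocol.json`.
#' @return `path` (write) or a `spike_dataset` (read), the latter without
#'   ground truth (files carry measurements, not generator truth).
#' @export
write_spike_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "spike_dataset"))
  utils::write.csv(dataset$spikes, path, row.names = FALSE, quote = FALSE)
  p <- dataset$protocol
  jsonlite::write_json(
    list(trial_duration = p$trial_duration, t_on = p$t_on, t_off = p$t_off,
         intensities = p$intensities,
         trials_per_intensity = p$trials_per_intensity,
         dark_window = p$dark_window),
    paste0(path, ".protocol.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path) {
  require_file(path)
  sidecar <- require_file(paste0(path, ".protocol.json"))
  spikes <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(unit_id = "character",
                                           electrode_id = "character"))
  pj <- jsonlite::fromJSON(sidecar)
  protocol <- stimulus_protocol(trial_duration = pj$trial_duration,
                                t_on = pj$t_on, t_off = pj$t_off,
                                intensities = pj$intensities,
                                trials_per_intensity = pj$trials_per_intensity,
                                dark_window = pj$dark_window)
  units <- unique(spikes[, c("unit_id", "electrode_id")])
  rownames(units) <- NULL
  structure(list(spikes = spikes, units = units, protocol = protocol,
                 ground_truth = NULL),
            class = "spike_dataset")
}

#' Write / read a horizontal-cell point pattern
#'
#' Centroids as CSV `(x_um, y_um)` plus a JSON sidecar with the field and
#' optic-disc geometry.
#'
#' @param pattern a [point_pattern].
#' @param path CSV path; the sidecar is `<path>.field.json`.
#' @return `path` (write) or a [point_pattern] (read).
#' @export
write_point_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "point_pattern"))
  utils::write.csv(pattern$points, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(field_radius = pattern$field_radius,
         disc_center = pattern$disc_center,
         disc_diameter = pattern$disc_diameter),
    paste0(path, ".field.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_point_pattern
#' @export
read_point_pattern <- function(path) {
  require_file(path)
  sidecar <- require_file(paste0(path, ".field.json"))
  pts <- utils::read.csv(path)
  g <- jsonlite::fromJSON(sidecar)
  point_pattern(pts, field_radius = g$field_radius,
                disc_center = g$disc_center,
                disc_diameter = g$disc_diameter)
}

#' Write / read a 3D puncta scene
#'
#' One CSV per channel (`ctbp2.csv`, `mglur6.csv` with
#' `(id, x_um, y_um, z_um)`), dendrite skeletons as `dendrites.csv`
#' (`cell_id, polyline_id, vertex, x_um, y_um, z_um`).
#'
#' @param scene a [puncta_scene].
#' @param dir directory for the scene files (created if needed).
#' @return `dir` (write) or a [puncta_scene] (read).
#' @export
write_puncta_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "puncta_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(scene$ctbp2, file.path(dir, "ctbp2.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(scene$mglur6, file.path(dir, "mglur6.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(scene$dendrites, file.path(dir, "dendrites.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_puncta_scene
#' @export
read_puncta_scene <- function(dir) {
  chr <- function(df, cols) {
    for (cc in intersect(cols, names(df))) df[[cc]] <- as.character(df[[cc]])
    df
  }
  ctbp2 <- chr(utils::read.csv(require_file(file.path(dir, "ctbp2.csv"))), "id")
  mglur6 <- chr(utils::read.csv(require_file(file.path(dir, "mglur6.csv"))), "id")
  dend <- chr(utils::read.csv(require_file(file.path(dir, "dendrites.csv"))),
              "cell_id")
  puncta_scene(ctbp2, mglur6, dend)
}
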