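#' Full-field flash stimulus protocol
#'
#' Describes the trial structure of a dark-adapted full-field flash
#' experiment: a 2-s flash presented on a dark background, repeated over an
#' increasing ladder of light intensities, with a 10-s in-trial dark segment
#' from which spontaneous activity is measured.
#'
#' @param trial_duration trial length in seconds.
#' @param t_on,t_off flash onset/offset times in seconds (default a 2-s flash
#'   from 2 to 4 s).
#' @param intensities strictly increasing flash intensities in
#'   photoisomerizations per rod per second (R*/rod/s). The default ladder
#'   runs from 0.83 to 95.23 R*/rod/s.
#' @param trials_per_intensity number of repeats at each intensity.
#' @param dark_window two-element vector (start, end) in seconds of the
#'   in-trial dark segment used for spontaneous-activity statistics; must be
#'   disjoint from the flash and its offset transient.
#' @return an object of class `stimulus_protocol`.
#' @examples
#' stimulus_protocol()
#' @export
stimulus_protocol <- function(trial_duration = 16,
                              t_on = 2, t_off = 4,
                              intensities = c(0.83, 1.49, 4.32, 15.32,
                                              49.38, 95.23),
                              trials_per_intensity = 20,
                              dark_window = c(6, 16)) {
  check_number(trial_duration, "trial_duration", lower = 0, strict_lower = TRUE)
  check_number(t_on, "t_on", lower = 0)
  check_number(t_off, "t_off", lower = t_on, strict_lower = TRUE,
               upper = trial_duration)
  if (!is.numeric(intensities) || length(intensities) < 1L ||
      any(intensities <= 0) || is.unsorted(intensities, strictly = TRUE))
    stopf("'intensities' must be strictly positive and strictly increasing")
  check_number(trials_per_intensity, "trials_per_intensity", lower = 1)
  if (length(dark_window) != 2L || dark_window[1] >= dark_window[2] ||
      dark_window[1] < 0 || dark_window[2] > trial_duration)
    stopf("'dark_window' must be an increasing (start, end) pair within the trial")
  # dark segment must not overlap the flash or its immediate offset transient
  if (dark_window[1] < t_off + 0.3 && dark_window[2] > t_on)
    stopf("'dark_window' overlaps the flash window [t_on, t_off + 0.3]")
  structure(list(trial_duration = trial_duration, t_on = t_on, t_off = t_off,
                 intensities = intensities,
                 trials_per_intensity = as.integer(trials_per_intensity),
                 dark_window = dark_window),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("Flash protocol: %g-s trials, flash %g-%g s, dark window %g-%g s\n",
              x$trial_duration, x$t_on, x$t_off,
              x$dark_window[1], x$dark_window[2]))
  cat(sprintf("  %d intensities (R*/rod/s): %s; %d trials each\n",
              length(x$intensities),
              paste(x$intensities, collapse = ", "),
              x$trials_per_intensity))
  invisible(x)
}

#' Generative specification of a simulated retinal ganglion cell
#'
#' Ground-truth description of one unit for [gen_spike_trains]: its response
#' type, spontaneous (baseline) firing rate, Naka-Rushton intensity-response
#' parameters that set the transient amplitude at each flash intensity, and
#' the width of the onset/offset transients.
#'
#' @param cell_id unit identifier (coerced to character).
#' @param response_type one of `"ON"`, `"OFF"`, `"ON_OFF"`, `"LOW"`, `"NONE"`.
#' @param baseline_rate spontaneous firing rate, spikes/s.
#' @param ir_params named numeric vector `c(Rmin, Rmax, I50, n)`: lowest and
#'   largest transient amplitudes (spikes/s), half-saturation intensity
#'   (R*/rod/s) and Hill exponent. For `"LOW"` cells the default amplitude
#'   ceiling is 8 spikes/s so that corrected peaks fall under the 10-Hz
#'   low-signal rule; other responsive types default to a 25 spikes/s ceiling.
#' @param transient_width width of the half-cosine response transient, s.
#' @param electrode_id electrode the unit is recorded on (optional).
#' @return an object of class `cell_spec`.
#' @examples
#' cell_spec("u1", "ON", ir_params = c(Rmin = 0, Rmax = 30, I50 = 5, n = 1.2))
#' @export
cell_spec <- function(cell_id,
                      response_type = c("ON", "OFF", "ON_OFF", "LOW", "NONE"),
                      baseline_rate = 3,
                      ir_params = NULL,
                      transient_width = 0.3,
                      electrode_id = NA_character_) {
  response_type <- match.arg(response_type)
  check_number(baseline_rate, "baseline_rate", lower = 0)
  check_number(transient_width, "transient_width", lower = 0, strict_lower = TRUE)
  if (is.null(ir_params)) {
    rmax <- if (response_type == "LOW") 8 else 25
    ir_params <- c(Rmin = 0, Rmax = rmax, I50 = 10, n = 1)
  }
  ir_params <- ir_params[c("Rmin", "Rmax", "I50", "n")]
  if (anyNA(ir_params))
    stopf("'ir_params' must be named c(Rmin, Rmax, I50, n)")
  if (ir_params[["Rmin"]] < 0 || ir_params[["Rmax"]] < ir_params[["Rmin"]])
    stopf("ir_params must satisfy Rmax >= Rmin >= 0")
  if (ir_params[["I50"]] <= 0 || ir_params[["n"]] <= 0)
    stopf("ir_params must satisfy I50 > 0 and n > 0")
  structure(list(cell_id = as.character(cell_id),
                 response_type = response_type,
                 baseline_rate = baseline_rate,
                 ir_params = ir_params,
                 transient_width = transient_width,
                 electrode_id = as.character(electrode_id)),
            class = "cell_spec")
}

# unit-peak half-cosine bump on [0, width]
bump <- function(u, width) {
  out <- numeric(length(u))
  inside <- u >= 0 & u <= width
  out[inside] <- sin(pi * u[inside] / width)
  out
}

# transient amplitudes (A_on, A_off) for a cell at one intensity
transient_amplitudes <- function(cell, intensity) {
  p <- cell$ir_params
  amp <- naka_rushton(intensity, p[["Rmin"]], p[["Rmax"]], p[["I50"]], p[["n"]])
  switch(cell$response_type,
         ON     = c(amp, 0),
         OFF    = c(0, amp),
         ON_OFF = c(amp, amp),
         LOW    = c(amp, 0),
         NONE   = c(0, 0),
         stopf("unknown response_type '%s'", cell$response_type))
}

#' Simulate flash-evoked spike trains with known ground truth
#'
#' Draws spikes for each unit, intensity and trial from an inhomogeneous
#' Poisson process with rate
#' `lambda(t) = baseline + A_on * g(t - t_on) + A_off * g(t - t_off)`,
#' where `g` is a unit-peak half-cosine bump of width `transient_width` and
#' the amplitudes follow each cell's Naka-Rushton curve at the trial
#' intensity (onset transient for ON cells, offset for OFF, both for ON-OFF,
#' a small onset transient for LOW, none for NONE). Trials are independent;
#' sampling is by thinning of a homogeneous process at the rate envelope.
#'
#' @param protocol a [stimulus_protocol].
#' @param cells list of [cell_spec] objects.
#' @param seed integer seed; identical `(protocol, cells, seed)` give
#'   identical output. The caller's RNG state is left untouched.
#' @return an object of class `spike_dataset`: a list with
#'   \describe{
#'     \item{spikes}{data frame `(unit_id, electrode_id, intensity, trial,
#'       t_spike_s)`, spike times sorted within each trial,}
#'     \item{units}{data frame `(unit_id, electrode_id)`,}
#'     \item{protocol}{the protocol,}
#'     \item{ground_truth}{list with `true_labels` (named character vector,
#'       simulator response types mapped to classifier labels) and
#'       `true_ir_params` (data frame of the generative parameters).}
#'   }
#' @examples
#' ds <- gen_spike_trains(stimulus_protocol(trials_per_intensity = 2),
#'                        list(cell_spec("u1", "ON")), seed = 1)
#' head(ds$spikes)
#' @export
gen_spike_trains <- function(protocol, cells, seed) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (!length(cells) || !all(vapply(cells, inherits, TRUE, "cell_spec")))
    stopf("'cells' must be a non-empty list of cell_spec objects")
  ids <- vapply(cells, `[[`, "", "cell_id")
  if (anyDuplicated(ids)) stopf("duplicate cell_id in 'cells'")
  local_rng(seed)

  dur <- protocol$trial_duration
  n_tr <- protocol$trials_per_intensity
  out <- vector("list", length(cells) * length(protocol$intensities))
  k <- 0L
  for (cell in cells) {
    w <- cell$transient_width
    for (intensity in protocol$intensities) {
      amps <- transient_amplitudes(cell, intensity)
      lam_max <- cell$baseline_rate + sum(amps)
      k <- k + 1L
      if (lam_max <= 0) next
      # candidate spikes for all trials of this block at once
      n_cand <- stats::rpois(n_tr, lam_max * dur)
      t_cand <- stats::runif(sum(n_cand), 0, dur)
      trial <- rep.int(seq_len(n_tr), n_cand)
      lam <- cell$baseline_rate +
        amps[1] * bump(t_cand - protocol$t_on, w) +
        amps[2] * bump(t_cand - protocol$t_off, w)
      keep <- stats::runif(length(t_cand)) < lam / lam_max
      if (!any(keep)) next
      t_keep <- t_cand[keep]; trial_keep <- trial[keep]
      ord <- order(trial_keep, t_keep)
      out[[k]] <- data.frame(unit_id = cell$cell_id,
                             electrode_id = cell$electrode_id,
                             intensity = intensity,
                             trial = trial_keep[ord],
                             t_spike_s = t_keep[ord],
                             stringsAsFactors = FALSE)
    }
  }
  spikes <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(spikes))
    spikes <- data.frame(unit_id = character(), electrode_id = character(),
                         intensity = numeric(), trial = integer(),
                         t_spike_s = numeric())
  rownames(spikes) <- NULL

  label_map <- c(ON = "ON", OFF = "OFF", ON_OFF = "ON_OFF",
                 LOW = "LOW_SIGNAL", NONE = "NOT_CLASSIFIED")
  truth <- list(
    true_labels = stats::setNames(
      label_map[vapply(cells, `[[`, "", "response_type")], ids),
    true_ir_params = data.frame(
      unit_id = ids,
      response_type = vapply(cells, `[[`, "", "response_type"),
      Rmin = vapply(cells, function(c) c$ir_params[["Rmin"]], 0),
      Rmax = vapply(cells, function(c) c$ir_params[["Rmax"]], 0),
      I50 = vapply(cells, function(c) c$ir_params[["I50"]], 0),
      n = vapply(cells, function(c) c$ir_params[["n"]], 0),
      baseline_rate = vapply(cells, `[[`, 0, "baseline_rate"),
      stringsAsFactors = FALSE))

  structure(list(spikes = spikes,
                 units = data.frame(
                   unit_id = ids,
                   electrode_id = vapply(cells, `[[`, "", "electrode_id"),
                   stringsAsFactors = FALSE),
                 protocol = protocol,
                 ground_truth = truth),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat(sprintf("spike_dataset: %d units, %d spikes, %d intensities x %d trials\n",
              nrow(x$units), nrow(x$spikes),
              length(x$protocol$intensities),
              x$protocol$trials_per_intensity))
  invisible(x)
}

#' Extract per-trial spike-time lists for one unit at one intensity
#'
#' @param dataset a `spike_dataset`.
#' @param unit_id unit identifier.
#' @param intensity flash intensity (must match a protocol intensity).
#' @return list of numeric vectors, one per trial (empty trials included).
#' @export
unit_trials <- function(dataset, unit_id, intensity) {
  stopifnot(inherits(dataset, "spike_dataset"))
  if (!unit_id %in% dataset$units$unit_id)
    stopf("unknown unit_id '%s'", unit_id)
  s <- dataset$spikes
  sel <- s$unit_id == unit_id & s$intensity == intensity
  n_tr <- dataset$protocol$trials_per_intensity
  split_trials(s$t_spike_s[sel], s$trial[sel], n_tr)
}
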