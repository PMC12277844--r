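#' Rule-based classification of flash-evoked RGC responses
#'
#' Applies the response-shape rules to a smoothed PSTH of the 2-s flash:
#' a response peak strictly above the mean + 4 SD dark threshold within
#' 500 ms of light onset classifies the unit as ON; a suprathreshold peak
#' 50-300 ms after light offset classifies it as OFF; peaks at both onset
#' and offset give ON-OFF. When some window responds but the largest
#' baseline-corrected peak is below 10 spikes/s the unit is labeled
#' LOW_SIGNAL; when no window responds it is NOT_CLASSIFIED.
#'
#' Window conventions: onset window `(t_on, t_on + onset_window]` (half-open),
#' offset window `[t_off + offset_window[1], t_off + offset_window[2]]`
#' (closed); a bin belongs to a window if its center does. The threshold
#' comparison is strict (`>`), the low-signal comparison is strict (`<`) and
#' is applied to the baseline-corrected peak. Ties across bins resolve to the
#' earliest bin.
#'
#' @param psth a smoothed `psth` (see [binomial_smooth]).
#' @param baseline [baseline_stats] for the same unit.
#' @param protocol the [stimulus_protocol] (supplies `t_on`, `t_off`).
#' @param onset_window length of the onset response window, s (default 0.5).
#' @param offset_window `(start, end)` offsets after `t_off`, s (default
#'   `c(0.05, 0.3)`, i.e. 50-300 ms after light offset).
#' @param low_cutoff low-signal cutoff on the corrected peak, spikes/s
#'   (default 10).
#' @return object of class `response_class`: list with `label` (one of
#'   `"ON"`, `"OFF"`, `"ON_OFF"`, `"LOW_SIGNAL"`, `"NOT_CLASSIFIED"`),
#'   corrected `onset_peak` and `offset_peak` (0 when subthreshold) and
#'   `peak_times` (named, `NA` for non-responding windows).
#' @export
classify_rgc <- function(psth, baseline, protocol,
                         onset_window = 0.5,
                         offset_window = c(0.05, 0.3),
                         low_cutoff = 10) {
  stopifnot(inherits(psth, "psth"), inherits(baseline, "baseline_stats"),
            inherits(protocol, "stimulus_protocol"))
  if (!isTRUE(psth$smoothed))
    stopf("classification requires a smoothed PSTH (see binomial_smooth)")
  win_on <- c(protocol$t_on, protocol$t_on + onset_window)
  win_off <- protocol$t_off + offset_window
  if (win_off[2] > protocol$trial_duration + 1e-9)
    stopf("offset window extends past the trial end")

  probe <- function(window, closed_left) {
    sel <- window_bins(psth, window, closed_left = closed_left)
    if (!any(sel)) stopf("response window contains no PSTH bins")
    r <- psth$rates[sel]
    mx <- max(r)
    responds <- mx > baseline$threshold
    list(responds = responds,
         corrected = if (responds) max(0, mx - baseline$mean_rate) else 0,
         t_peak = if (responds)
           psth$centers[sel][which.max(r)] else NA_real_)
  }
  on <- probe(win_on, closed_left = FALSE)
  off <- probe(win_off, closed_left = TRUE)

  label <- if (!on$responds && !off$responds) {
    "NOT_CLASSIFIED"
  } else if (max(on$corrected, off$corrected) < low_cutoff) {
    "LOW_SIGNAL"
  } else if (on$responds && off$responds) {
    "ON_OFF"
  } else if (on$responds) "ON" else "OFF"

  structure(list(label = label,
                 onset_peak = on$corrected,
                 offset_peak = off$corrected,
                 peak_times = c(onset = on$t_peak, offset = off$t_peak)),
            class = "response_class")
}

#' @export
print.response_class <- function(x, ...) {
  cat(sprintf("RGC response: %s (onset peak %.1f, offset peak %.1f spikes/s)\n",
              x$label, x$onset_peak, x$offset_peak))
  invisible(x)
}

response_labels <- c("ON", "OFF", "ON_OFF", "LOW_SIGNAL", "NOT_CLASSIFIED")

#' Tabulate response classes per graft-centric area
#'
#' Counts units of each response label within each electrode area and pooled
#' over areas; fractions sum to 1 within each group.
#'
#' @param classes data frame with columns `unit_id`, `electrode_id`, `label`.
#' @param areas an `area_map` from [assign_electrode_areas], or `NULL` to
#'   tabulate pooled counts only.
#' @return data frame `(area, label, count, fraction)`; `area` is `"all"`
#'   for the pooled rows. Empty input gives an empty table.
#' @export
summarize_responses <- function(classes, areas = NULL) {
  classes <- as.data.frame(classes)
  if (nrow(classes) == 0L)
    return(data.frame(area = character(), label = character(),
                      count = integer(), fraction = numeric()))
  if (!all(c("unit_id", "label") %in% names(classes)))
    stopf("'classes' needs columns 'unit_id' and 'label'")
  bad <- setdiff(unique(classes$label), response_labels)
  if (length(bad)) stopf("unknown response label '%s'", bad[1])

  tab_group <- function(labels, group) {
    counts <- table(factor(labels, levels = response_labels))
    data.frame(area = group, label = names(counts),
               count = as.integer(counts),
               fraction = as.integer(counts) / length(labels),
               stringsAsFactors = FALSE)
  }
  out <- tab_group(classes$label, "all")
  if (!is.null(areas)) {
    stopifnot(inherits(areas, "area_map"))
    if (!"electrode_id" %in% names(classes))
      stopf("'classes' needs an 'electrode_id' column to split by area")
    idx <- match(classes$electrode_id, areas$assignment$electrode_id)
    if (anyNA(idx))
      stopf("unit '%s' sits on an electrode with no area assignment",
            classes$unit_id[which(is.na(idx))[1]])
    area_of <- areas$assignment$area[idx]
    for (a in sort(unique(area_of)))
      out <- rbind(out, tab_group(classes$label[area_of == a],
                                  as.character(a)))
  }
  rownames(out) <- NULL
  out
}
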