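#' Peri-stimulus time histogram
#'
#' Pools spike times over trials into fixed-width bins and converts counts to
#' firing rates: `rate = pooled count / (bin_width * n_trials)`. The
#' conservation identity `sum(rates) * bin_width * n_trials == total spikes`
#' holds exactly for the unsmoothed histogram. Bins are left-closed,
#' right-open, with the final bin closed at `trial_duration`.
#'
#' @param trials list of numeric spike-time vectors, one per trial (empty
#'   vectors allowed), times in seconds within `[0, trial_duration]`.
#' @param protocol a [stimulus_protocol] (supplies the trial duration).
#' @param bin_width bin width in seconds; the default 0.020 s (20 ms).
#' @return object of class `psth`: list with `bin_width`, `edges`, `centers`,
#'   `rates` (spikes/s), `n_trials`, `smoothed = FALSE`.
#' @examples
#' p <- stimulus_protocol()
#' compute_psth(list(c(0.010, 0.015)), p)$rates[1] # 100 spikes/s
#' @export
compute_psth <- function(trials, protocol, bin_width = 0.020) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (!is.list(trials) || length(trials) == 0L)
    stopf("'trials' must be a non-empty list of spike-time vectors")
  check_number(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  dur <- protocol$trial_duration
  n_bins <- round(dur / bin_width)
  if (abs(n_bins * bin_width - dur) > 1e-9)
    stopf("bin_width %g does not divide the trial duration %g", bin_width, dur)
  t <- unlist(trials, use.names = FALSE)
  if (length(t) && (min(t) < 0 || max(t) > dur))
    stopf("spike times outside [0, trial_duration]")
  edges <- seq(0, dur, length.out = n_bins + 1L)
  idx <- findInterval(t, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  n_trials <- length(trials)
  structure(list(bin_width = bin_width, edges = edges,
                 centers = edges[-length(edges)] + bin_width / 2,
                 rates = counts / (bin_width * n_trials),
                 n_trials = n_trials, smoothed = FALSE),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("PSTH: %d bins x %g ms, %d trials, peak %.1f spikes/s%s\n",
              length(x$rates), x$bin_width * 1000, x$n_trials,
              if (length(x$rates)) max(x$rates) else 0,
              if (x$smoothed) " (smoothed)" else ""))
  invisible(x)
}

binomial_kernel <- function(order) {
  choose(order, 0:order) / 2^order
}

#' Binomial smoothing of a PSTH
#'
#' Convolves the bin rates with the unit-sum binomial kernel of the given
#' order (coefficients `choose(n, k) / 2^n`; order 4 gives
#' `[1, 4, 6, 4, 1] / 16`). Edges are handled by symmetric reflection
#' padding, so constant histograms are left exactly unchanged.
#'
#' @param psth a [compute_psth] result.
#' @param order filter order `n >= 1`; the default 4.
#' @return the smoothed `psth` (`smoothed = TRUE`).
#' @export
binomial_smooth <- function(psth, order = 4) {
  stopifnot(inherits(psth, "psth"))
  check_number(order, "order", lower = 1)
  order <- as.integer(order)
  k <- binomial_kernel(order)
  x <- psth$rates
  n <- length(x)
  pad_l <- floor(order / 2); pad_r <- order - pad_l
  if (n < max(pad_l, pad_r) + 1L)
    stopf("PSTH too short (%d bins) for order-%d smoothing", n, order)
  xp <- c(x[pad_l:1][seq_len(pad_l)], x, x[n:(n - pad_r + 1L)][seq_len(pad_r)])
  sm <- stats::convolve(xp, rev(k), type = "filter")
  psth$rates <- as.numeric(sm)
  psth$smoothed <- TRUE
  psth
}

#' Spontaneous-activity statistics and response threshold
#'
#' Mean and sample SD of the bin firing rates over a dark segment of the
#' (unsmoothed) PSTH, and the response threshold
#' `threshold = mean + sd_multiplier * SD` (the default multiplier 4 gives
#' the mean + 4 SD rule). Spontaneous activity is measured over 10 s in the
#' dark by default; shorter segments raise an error unless `min_duration`
#' is lowered.
#'
#' @param psth a `psth` (typically unsmoothed).
#' @param window optional `(start, end)` seconds restricting to the bins
#'   whose centers fall inside; default uses all bins of `psth`.
#' @param sd_multiplier multiplier on the SD, default 4.
#' @param min_duration minimum dark-segment duration in seconds (default 10).
#' @return object of class `baseline_stats`: list with `mean_rate`,
#'   `sd_rate`, `threshold` (spikes/s) and `n_bins`.
#' @examples
#' p <- stimulus_protocol()
#' ps <- compute_psth(list(numeric(0)), p)
#' baseline_stats(ps, window = p$dark_window)
#' @export
baseline_stats <- function(psth, window = NULL, sd_multiplier = 4,
                           min_duration = 10) {
  stopifnot(inherits(psth, "psth"))
  check_number(sd_multiplier, "sd_multiplier", lower = 0)
  rates <- psth$rates
  if (!is.null(window)) {
    if (length(window) != 2L || window[1] >= window[2])
      stopf("'window' must be an increasing (start, end) pair")
    inside <- psth$centers > window[1] & psth$centers < window[2] |
      abs(psth$centers - window[1]) < 1e-12 |
      abs(psth$centers - window[2]) < 1e-12
    rates <- rates[inside]
  }
  if (length(rates) * psth$bin_width < min_duration - 1e-9)
    stopf("dark segment (%.3g s) shorter than the required %g s",
          length(rates) * psth$bin_width, min_duration)
  m <- mean(rates)
  s <- if (length(rates) > 1L) stats::sd(rates) else 0
  structure(list(mean_rate = m, sd_rate = s,
                 threshold = m + sd_multiplier * s,
                 n_bins = length(rates)),
            class = "baseline_stats")
}

#' @export
print.baseline_stats <- function(x, ...) {
  cat(sprintf("Dark activity: mean %.3g, SD %.3g spikes/s -> threshold %.3g spikes/s\n",
              x$mean_rate, x$sd_rate, x$threshold))
  invisible(x)
}

# bins whose centers fall inside a window; onset-type windows are half-open
# (lo, hi], offset-type closed [lo, hi]
window_bins <- function(psth, window, closed_left) {
  eps <- 1e-12
  lo <- window[1]; hi <- window[2]
  c_ <- psth$centers
  left <- if (closed_left) c_ >= lo - eps else c_ > lo + eps
  left & (c_ <= hi + eps)
}

#' Baseline-corrected peak response in a window
#'
#' Maximum bin rate within the window, corrected by subtracting the dark mean
#' firing rate; subthreshold peaks (max not strictly above the mean + 4 SD
#' threshold) are reported as 0 spikes/s. Never negative.
#'
#' @param psth a smoothed `psth`.
#' @param baseline a [baseline_stats] from the same unit.
#' @param window `(start, end)` in seconds; a bin belongs to the window if
#'   its center does (closed at both ends here).
#' @return corrected peak firing rate, spikes/s.
#' @export
peak_response <- function(psth, baseline, window) {
  stopifnot(inherits(psth, "psth"), inherits(baseline, "baseline_stats"))
  if (length(window) != 2L || window[1] >= window[2])
    stopf("'window' must be an increasing (start, end) pair")
  sel <- window_bins(psth, window, closed_left = TRUE)
  if (!any(sel)) stopf("window contains no PSTH bins")
  mx <- max(psth$rates[sel])
  if (mx > baseline$threshold) max(0, mx - baseline$mean_rate) else 0
}
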