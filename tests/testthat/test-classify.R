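protocol <- stimulus_protocol()
dark_win <- protocol$dark_window

classify_constructed <- function(psth) {
  base <- baseline_stats(psth, window = dark_win)
  classify_rgc(psth, base, protocol)
}

test_that("each response rule fires on its constructed PSTH", {
  expect_identical(classify_constructed(flash_psth())$label, "NOT_CLASSIFIED")
  on <- classify_constructed(flash_psth(onset_amp = 30))
  expect_identical(on$label, "ON")
  expect_equal(on$onset_peak, 30)
  expect_equal(on$offset_peak, 0)
  expect_equal(unname(on$peak_times["onset"]), 2.11)
  off <- classify_constructed(flash_psth(offset_amp = 30))
  expect_identical(off$label, "OFF")
  expect_equal(off$offset_peak, 30)
  onoff <- classify_constructed(flash_psth(onset_amp = 25, offset_amp = 18))
  expect_identical(onoff$label, "ON_OFF")
  low <- classify_constructed(flash_psth(onset_amp = 6, offset_amp = 6))
  expect_identical(low$label, "LOW_SIGNAL")
  expect_equal(low$onset_peak, 6)
})

test_that("threshold and 10-Hz boundaries are strict", {
  # peak exactly at mean + 4 SD: not a response
  thr_amp <- 4 * dark_sd_alt()
  expect_identical(classify_constructed(flash_psth(onset_amp = thr_amp))$label,
                   "NOT_CLASSIFIED")
  # just above threshold but corrected peak < 10: LOW
  expect_identical(
    classify_constructed(flash_psth(onset_amp = thr_amp + 0.01))$label,
    "LOW_SIGNAL")
  # corrected peak exactly 10 is not "< 10": ON
  expect_identical(classify_constructed(flash_psth(onset_amp = 10))$label, "ON")
  expect_identical(classify_constructed(flash_psth(onset_amp = 9.999))$label,
                   "LOW_SIGNAL")
})

test_that("upscaling a suprathreshold bump never flips ON/OFF or creates LOW", {
  for (amps in list(c(12, 0), c(0, 12), c(15, 11))) {
    base_label <- classify_constructed(flash_psth(amps[1], amps[2]))$label
    for (k in c(1.5, 3, 10)) {
      lab <- classify_constructed(flash_psth(k * amps[1], k * amps[2]))$label
      expect_identical(lab, base_label)
      expect_false(lab == "LOW_SIGNAL")
    }
  }
})

test_that("classification refuses unsmoothed PSTHs and bad windows", {
  ps <- flash_psth(onset_amp = 30)
  ps$smoothed <- FALSE
  base <- baseline_stats(ps, window = dark_win)
  expect_error(classify_rgc(ps, base, protocol), "smoothed")
  ps$smoothed <- TRUE
  expect_error(classify_rgc(ps, base, protocol,
                            offset_window = c(0.05, 12.5)),
               "past the trial end")
})

test_that("response summaries count labels per area with unit fractions", {
  classes <- data.frame(
    unit_id = sprintf("u%d", 1:10),
    electrode_id = rep("el_24", 10),
    label = rep("ON", 10), stringsAsFactors = FALSE)
  layout <- electrode_layout()
  mask <- disc_mask(150, 150, 10, center = c(300, 600), radius = 120)
  areas <- assign_electrode_areas(mask, 10, layout)
  tab <- summarize_responses(classes, areas)
  on_rows <- tab[tab$label == "ON", ]
  expect_true(all(on_rows$count == 10))
  expect_true(all(on_rows$fraction == 1))
  # fractions sum to 1 within each group
  for (a in unique(tab$area))
    expect_equal(sum(tab$fraction[tab$area == a]), 1)
  expect_identical(nrow(summarize_responses(data.frame())), 0L)
  classes$electrode_id[1] <- "el_99"
  expect_error(summarize_responses(classes, areas), "no area assignment")
})
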