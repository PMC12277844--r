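test_that("protocol and cell specifications validate their invariants", {
  expect_error(stimulus_protocol(t_on = 5, t_off = 4), "t_off")
  expect_error(stimulus_protocol(intensities = c(3, 2, 1)), "increasing")
  expect_error(stimulus_protocol(dark_window = c(3, 13)), "overlaps")
  expect_error(cell_spec("u", "ON", baseline_rate = -1), "baseline_rate")
  expect_error(cell_spec("u", "ON", ir_params = c(Rmin = 5, Rmax = 1,
                                                  I50 = 10, n = 1)), "Rmax")
  expect_error(cell_spec("u", "WIBBLE"), "arg")
})

test_that("identical protocol, cells and seed give byte-identical spike tables", {
  p <- stimulus_protocol(trials_per_intensity = 3)
  cells <- list(cell_spec("a", "ON"), cell_spec("b", "OFF"))
  d1 <- gen_spike_trains(p, cells, seed = 42)
  d2 <- gen_spike_trains(p, cells, seed = 42)
  expect_identical(d1$spikes, d2$spikes)
  d3 <- gen_spike_trains(p, cells, seed = 43)
  expect_false(identical(d1$spikes, d3$spikes))
})

test_that("background firing is Poisson with mean rate x duration", {
  # unresponsive cell at 5 spikes/s, 16-s trials: expect 80 spikes/trial
  p <- stimulus_protocol(intensities = 1, trials_per_intensity = 200)
  ds <- gen_spike_trains(p, list(cell_spec("u", "NONE", baseline_rate = 5)),
                         seed = 7)
  counts <- tabulate(ds$spikes$trial, nbins = 200)
  expected <- 5 * p$trial_duration
  se <- sqrt(expected / 200)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("a zero-rate process emits no spikes at all", {
  p <- stimulus_protocol(trials_per_intensity = 5)
  ds <- gen_spike_trains(p, list(cell_spec("u", "NONE", baseline_rate = 0)),
                         seed = 1)
  expect_identical(nrow(ds$spikes), 0L)
})

test_that("transient peaks track the cell's intensity-response curve", {
  # many trials: empirical smoothed PSTH peak near baseline + amplitude
  p <- stimulus_protocol(intensities = c(4.32, 95.23),
                         trials_per_intensity = 500)
  cell <- cell_spec("u", "ON", baseline_rate = 2,
                    ir_params = c(Rmin = 0, Rmax = 30, I50 = 10, n = 1))
  ds <- gen_spike_trains(p, list(cell), seed = 21)
  for (I in p$intensities) {
    ps <- binomial_smooth(compute_psth(unit_trials(ds, "u", I), p))
    sel <- ps$centers > p$t_on & ps$centers <= p$t_on + 0.5
    amp <- naka_rushton(I, 0, 30, 10, 1)
    # half-sine bump peak, bin-averaged, atop baseline; SE from Poisson bins
    se <- sqrt((2 + amp) / (0.02 * 500))
    expect_lt(abs(max(ps$rates[sel]) - (2 + amp)), 3 * se + 1)
  }
})

test_that("ground truth carries classifier-ready labels and parameters", {
  p <- stimulus_protocol(trials_per_intensity = 2)
  ds <- gen_spike_trains(p, list(cell_spec("a", "LOW"),
                                 cell_spec("b", "NONE")), seed = 3)
  expect_identical(unname(ds$ground_truth$true_labels),
                   c("LOW_SIGNAL", "NOT_CLASSIFIED"))
  expect_identical(ds$ground_truth$true_ir_params$unit_id, c("a", "b"))
  expect_identical(ds$ground_truth$true_ir_params$Rmax[1], 8)
})

test_that("unit_trials returns one (possibly empty) vector per trial", {
  p <- stimulus_protocol(trials_per_intensity = 4)
  ds <- gen_spike_trains(p, list(cell_spec("u", "NONE", baseline_rate = 0.2)),
                         seed = 5)
  tr <- unit_trials(ds, "u", p$intensities[1])
  expect_length(tr, 4L)
  expect_identical(sum(lengths(tr)),
                   sum(ds$spikes$intensity == p$intensities[1]))
  expect_error(unit_trials(ds, "nope", p$intensities[1]), "unknown unit_id")
})
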