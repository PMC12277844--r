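protocol <- stimulus_protocol()

test_that("PSTH rates are pooled counts over bin width and trial count", {
  ps <- compute_psth(list(c(0.010, 0.015)), protocol)
  expect_equal(ps$rates[1], 100)
  expect_true(all(ps$rates[-1] == 0))
  # two trials halve the rate
  ps2 <- compute_psth(list(c(0.010, 0.015), numeric(0)), protocol)
  expect_equal(ps2$rates[1], 50)
  # empty input: all-zero PSTH
  ps0 <- compute_psth(list(numeric(0)), protocol)
  expect_true(all(ps0$rates == 0))
})

test_that("PSTH conserves the total spike count exactly", {
  withr::with_seed(11, {
    for (k in 1:5) {
      trials <- lapply(1:10, function(i)
        sort(runif(rpois(1, 60), 0, protocol$trial_duration)))
      ps <- compute_psth(trials, protocol)
      expect_equal(sum(ps$rates) * ps$bin_width * ps$n_trials,
                   sum(lengths(trials)), tolerance = 1e-12)
    }
  })
})

test_that("PSTH input validation rejects malformed spikes and bins", {
  expect_error(compute_psth(list(), protocol), "non-empty")
  expect_error(compute_psth(list(c(-0.1)), protocol), "outside")
  expect_error(compute_psth(list(c(17)), protocol), "outside")
  expect_error(compute_psth(list(c(1)), protocol, bin_width = 0.023),
               "does not divide")
})

test_that("binomial filter has the order-4 impulse response and unit sum", {
  r <- rep(0, 101); r[51] <- 1
  sm <- binomial_smooth(make_psth(r))
  expect_equal(sm$rates[49:53], c(1, 4, 6, 4, 1) / 16, tolerance = 1e-14)
  expect_true(all(abs(sm$rates[-(49:53)]) < 1e-14))
  expect_true(sm$smoothed)
  # order n kernel is choose(n, k)/2^n for other orders too
  r2 <- rep(0, 21); r2[11] <- 1
  sm2 <- binomial_smooth(make_psth(r2), order = 2)
  expect_equal(sm2$rates[10:12], c(1, 2, 1) / 4, tolerance = 1e-14)
})

test_that("smoothing leaves constant histograms exactly invariant", {
  sm <- binomial_smooth(make_psth(rep(7.25, 64)))
  expect_equal(sm$rates, rep(7.25, 64), tolerance = 1e-13)
  # and preserves the mean of arbitrary inputs away from the padded edges
  withr::with_seed(2, x <- runif(400, 0, 50))
  sm2 <- binomial_smooth(make_psth(x))
  expect_equal(mean(sm2$rates[3:398]), mean(x[3:398]), tolerance = 0.05)
})

test_that("dark-activity statistics implement mean + 4 SD", {
  b <- baseline_stats(make_psth(rep(5, 500)))
  expect_equal(b$mean_rate, 5)
  expect_equal(b$sd_rate, 0)
  expect_equal(b$threshold, 5)

  b2 <- baseline_stats(make_psth(c(2, 4, 6, 8)), min_duration = 0)
  expect_equal(b2$mean_rate, 5)
  expect_equal(b2$sd_rate, sqrt(20 / 3), tolerance = 1e-12)
  expect_equal(b2$threshold, 5 + 4 * sqrt(20 / 3), tolerance = 1e-12)

  # threshold never below the mean; multiplier configurable
  withr::with_seed(3, x <- rpois(500, 3) / 0.4)
  b3 <- baseline_stats(make_psth(x))
  expect_gte(b3$threshold, b3$mean_rate)
  b4 <- baseline_stats(make_psth(x), sd_multiplier = 2)
  expect_equal(b4$threshold, b3$mean_rate + 2 * b3$sd_rate)
})

test_that("dark segments shorter than the configured minimum are rejected", {
  expect_error(baseline_stats(make_psth(c(2, 4, 6, 8))), "shorter")
  # window restriction picks exactly the dark bins
  ps <- compute_psth(list(c(1, 7, 8)), protocol)
  b <- baseline_stats(ps, window = protocol$dark_window)
  expect_identical(b$n_bins, 500L)
})

test_that("peak responses are baseline-corrected and zeroed when subthreshold", {
  base <- make_baseline(5, 1.75) # threshold 12
  expect_equal(peak_response(make_psth(c(30, 5, 5), smoothed = TRUE),
                             base, c(0, 0.06)), 25)
  expect_equal(peak_response(make_psth(c(11, 5, 5), smoothed = TRUE),
                             base, c(0, 0.06)), 0)
  # a peak exactly at threshold does not count (strict >)
  expect_equal(peak_response(make_psth(c(12, 5, 5), smoothed = TRUE),
                             base, c(0, 0.06)), 0)
  expect_error(peak_response(make_psth(c(1, 2), smoothed = TRUE),
                             base, c(0.5, 0.6)), "no PSTH bins")
})
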