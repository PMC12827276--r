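# Spike binning, time-locked classification, dose-response and spatial fits.

test_that("binning follows the 180 x 5 ms trial layout", {
  trials <- data.frame(trial_id = 1, onset_s = 10)
  # spike 10 ms after onset: 1-based global bin 43 (third stimulus bin)
  tc <- bin_trials(data.frame(unit_id = "a", time_s = 10.010), trials)
  expect_equal(which(tc$counts[1, 1, ] > 0), 43)
  # spike exactly at onset: first stimulus bin (half-open convention)
  tc <- bin_trials(data.frame(unit_id = "a", time_s = 10), trials)
  expect_equal(which(tc$counts[1, 1, ] > 0), 41)
  # spike at onset + 700 ms is outside the window
  tc <- bin_trials(data.frame(unit_id = "a", time_s = 10.7), trials)
  expect_equal(sum(tc$counts), 0)
  # empty spike table gives an all-zero tensor
  tc <- bin_trials(data.frame(unit_id = character(), time_s = numeric()),
                   trials)
  expect_equal(sum(tc$counts), 0)
  expect_error(bin_trials(data.frame(unit_id = "a", time_s = 1),
                          data.frame(trial_id = 1:2, onset_s = c(5, 4))),
               "increasing")
  expect_warning(bin_trials(data.frame(unit_id = "a", time_s = 1),
                            data.frame(trial_id = 1:2, onset_s = c(5, 5.3))),
                 "overlap")
})

test_that("binning conserves in-window spikes and 25 ms re-binning sums 5", {
  gen <- gen_ephys(seed = 13, n_units = 4, n_trials = 5)
  tc <- bin_trials(gen$spikes, gen$trials)
  w0 <- gen$trials$onset_s - 0.2
  in_win <- vapply(gen$spikes$time_s,
                   function(t) any(t >= w0 & t < w0 + 0.9), TRUE)
  expect_equal(sum(tc$counts), sum(in_win))
  r25 <- rebin_25ms(tc)
  expect_equal(dim(r25)[3], 36)
  expect_equal(sum(r25), sum(tc$counts))
  expect_equal(r25[1, 1, 1], sum(tc$counts[1, 1, 1:5]))
})

test_that("time-locked classification applies the one-sided 2-sigma rule", {
  # constant deterministic rate: stimulus equals background, not locked
  flat <- make_counts(array(1L, dim = c(1, 10, 180)))
  expect_false(classify_time_locked(flat)$time_locked)
  # silent background, a single stimulus spike: locked
  arr <- array(0L, dim = c(1, 10, 180)); arr[1, 3, 50] <- 1L
  expect_true(classify_time_locked(make_counts(arr))$time_locked)
  expect_error(background_stats(make_counts(array(0L, c(1, 0, 180)))),
               "trial")
})

test_that("null false-positive rate matches an independent oracle", {
  n_units <- 1000; n_trials <- 50; rate <- 5
  tc <- null_counts(n_units, n_trials, rate, seed = 31)
  fp_pipe <- mean(classify_time_locked(tc)$time_locked)
  # oracle: the same decision rule applied to fresh Poisson draws with
  # plain column sums (no package code)
  withr::with_seed(77, {
    fp_oracle <- mean(vapply(seq_len(n_units), function(u) {
      stim <- stats::rpois(n_trials, rate * 0.5)
      bg <- stats::rpois(n_trials, rate * 0.4) * 1.25
      mean(stim) > mean(bg) + 2 * stats::sd(bg)
    }, TRUE))
  })
  # the across-trial 2-sigma criterion is conservative: both rates are
  # near zero and must agree within a binomial band
  pbar <- max((fp_pipe + fp_oracle) / 2, 1 / n_units)
  bound <- 2.58 * sqrt(2 * pbar * (1 - pbar) / n_units) + 1 / n_units
  expect_lte(abs(fp_pipe - fp_oracle), bound)
  expect_lt(fp_pipe, 0.05)   # a one-sided 2-sigma rule is a small tail
})

test_that("PSTH is background-subtracted and stimulus-locked", {
  gen <- gen_ephys(seed = 5, truth = ground_truth(baseline_hz = 5,
                                                  max_spikes_per_trial = 20),
                   n_units = 8, n_trials = 30,
                   levels = c(1, 3, 6), positions_um = 0)
  tc <- bin_trials(gen$spikes, gen$trials)
  tr <- psth(tc)
  # background bins average to zero by construction
  bg25 <- c(1:8, 29:36)
  expect_lt(abs(mean(tr$rate[bg25])), 1e-12)
  # pulse-on 25 ms bins (odd stimulus bins) are elevated over pulse-off
  stim <- tr$rate[9:28]
  expect_gt(mean(stim[seq(1, 20, by = 2)]), mean(stim[seq(2, 20, by = 2)]) + 0.1)
  # flat Poisson input gives a flat trace
  tc0 <- null_counts(20, 30, 5, seed = 41)
  expect_lt(max(abs(psth(tc0)$rate)), 0.5)
  expect_error(psth(tc, units = "nope"), "unknown")
})

test_that("dose-response threshold interpolates the 5-spike criterion", {
  gen <- gen_ephys(seed = 42)
  sub <- gen$trials[gen$trials$position_um == 0, ]
  tc <- bin_trials(gen$spikes, sub)
  cl <- classify_time_locked(tc)
  dr <- dose_response(tc, units = cl$unit[cl$time_locked])
  expect_equal(dr$flag, "ok")
  truth_thr <- cortiled:::truth_threshold(gen$truth)
  expect_lt(abs(dr$threshold / truth_thr - 1), 0.15)
  # all-zero responses are flagged with no threshold
  z <- make_counts(array(0L, c(3, 30, 180)),
                   irradiance = rep(c(1, 3, 5), 10))
  dz <- dose_response(z)
  expect_true(is.na(dz$threshold))
  expect_true(dz$flag %in% c("no_crossing", "fit_failed"))
  # saturating step: threshold lies between the bracketing levels
  arr <- array(0L, c(1, 30, 180))
  lev <- rep(c(1, 2, 3, 4, 5, 6), 5)
  arr[1, lev >= 4, 41:140] <- 1L   # 100 spikes/trial at levels >= 4
  ds <- dose_response(make_counts(arr, irradiance = lev))
  expect_gt(ds$threshold, 3)
  expect_lt(ds$threshold, 4)
  expect_error(dose_response(make_counts(array(0L, c(1, 4, 180)),
                                         irradiance = rep(1:2, 2))),
               "3 irradiance levels")
})

test_that("weighted Gaussian fit recovers exact and noisy profiles", {
  x <- seq(-900, 0, by = 100)
  # noise-free with sigma = 250: FWHM is the closed form 588.7
  y <- 30 * exp(-(x + 400)^2 / (2 * 250^2))
  sf <- spatial_fit(data.frame(position_um = x, mean = y,
                               sem = rep(0.1, length(x))))
  expect_equal(sf$fwhm_um, 2 * sqrt(2 * log(2)) * 250, tolerance = 1e-4)
  expect_lt(sf$chisq_red, 1e-8)
  expect_equal(sf$dof, length(x) - 4)
  # bounds are honoured
  expect_gte(sf$coef[["sigma"]], 100)
  expect_lte(sf$coef[["mu"]], 0)
  expect_error(spatial_fit(data.frame(position_um = 1:3, mean = 1:3,
                                      sem = rep(1, 3))),
               "4 points")
  expect_error(spatial_fit(data.frame(position_um = 1:5, mean = 1:5,
                                      sem = c(1, 1, 0, 1, 1))),
               "positive")
})

test_that("preprocessing removes DC and common-mode signal", {
  fs <- 20000
  n <- 4000
  t <- seq_len(n) / fs
  common <- sin(2 * pi * 1000 * t)
  x <- cbind(common + 2, common - 1, common + 0.5)   # common + DC offsets
  f <- preprocess_raw(x, fs)
  expect_lt(max(abs(f[500:3500, ])), 1e-6)
  expect_error(preprocess_raw(x, fs = 10000), "sampling rate")
})

test_that("threshold crossing detects injected spikes on noise", {
  fs <- 20000
  withr::with_seed(3, {
    noise <- stats::rnorm(fs)                        # 1 s of unit noise
    inject <- seq(0.05, 0.95, by = 0.05) * fs
    for (i in inject) noise[i + 0:5] <- noise[i + 0:5] - 12
  })
  ev <- mua_detect(cbind(noise), fs, k = 5)[[1]]
  expect_equal(length(ev), length(inject))
  expect_true(all(abs(ev - inject / fs) < 0.001))
  # silent channel yields no events
  expect_equal(length(mua_detect(cbind(rep(0, 1000)), fs)[[1]]), 0)
})
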