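test_that("fixed-rate ECG generation is exact and deterministic", {
  sim <- gen_ecg(ecg_sim_spec(duration = 60, hr = 60, hrv_sd = 0, seed = 1))
  expect_length(sim$truth$R, 60)
  expect_equal(unique(round(diff(sim$truth$R), 12)), 1.0)
  sim2 <- gen_ecg(ecg_sim_spec(duration = 60, hr = 60, hrv_sd = 0, seed = 1))
  expect_identical(sim$track$values, sim2$track$values)
  expect_identical(sim$truth, sim2$truth)
  # different seed, jittered: different realization
  a <- gen_ecg(ecg_sim_spec(duration = 30, hrv_sd = 0.02, seed = 1))
  b <- gen_ecg(ecg_sim_spec(duration = 30, hrv_sd = 0.02, seed = 2))
  expect_false(identical(a$truth$R, b$truth$R))
})

test_that("realized RR intervals are centred on the requested rate", {
  spec <- ecg_sim_spec(duration = 300, hr = 75, hrv_sd = 0.02, seed = 3)
  sim <- gen_ecg(spec)
  rr <- diff(sim$truth$R)
  expect_lt(abs(mean(rr) - 60 / 75), 3 * 0.02 / sqrt(length(rr)) + 1e-3)
  expect_error(ecg_sim_spec(hr = 300), class = "beatkit_invalid_parameter")
  expect_error(ecg_sim_spec(qrs_width = 0.3), class = "beatkit_invalid_parameter")
  expect_error(ecg_sim_spec(fs = 50), class = "beatkit_invalid_parameter")
})

test_that("variable heart rate follows the breakpoint profile", {
  sim <- gen_ecg(ecg_sim_spec(duration = 120, hr = c(60, 120), hrv_sd = 0,
                              seed = 1))
  rr <- diff(sim$truth$R)
  early <- rr[1:10]; late <- tail(rr, 10)
  expect_gt(mean(early), 0.9)   # ~60 bpm at the start
  expect_lt(mean(late), 0.55)   # ~120 bpm at the end
})

test_that("PPG truth is ordered and consistent with a numeric derivative", {
  sim <- gen_ppg(ppg_sim_spec(duration = 30, hr = 75, seed = 5))
  tr <- sim$truth
  n <- length(tr$peak)
  expect_equal(length(tr$foot), n)
  expect_equal(length(tr$upstroke), n)
  expect_true(all(tr$foot < tr$upstroke & tr$upstroke < tr$peak))
  expect_true(all(tr$peak[seq_along(tr$dicrotic_notch)] < tr$dicrotic_notch))
  expect_true(all(tr$dicrotic_notch <= tr$secondary_peak))
  # analytic upstroke equals the argmax of the numerically differentiated
  # clean track, to within one sample
  d <- derive_track(sim$track, "derivative")
  fs <- sim$track$fs
  for (k in c(2, 10, 25)) {
    i0 <- round(tr$foot[k] * fs); i1 <- round(tr$peak[k] * fs)
    i_up <- (i0:i1)[which.max(d$values[i0:i1])]
    expect_lte(abs((i_up - 1) / fs - tr$upstroke[k]), 1 / fs)
  }
  # no notch requested -> no notch truth
  plain <- gen_ppg(ppg_sim_spec(duration = 20, notch_depth = 0, seed = 5))
  expect_null(plain$truth$dicrotic_notch)
  expect_null(plain$truth$secondary_peak)
})

test_that("noise injection is calibrated, additive and deterministic", {
  sim <- gen_ecg(ecg_sim_spec(duration = 60, seed = 6))
  clean <- sim$track
  same <- add_noise(clean, white_snr_db = NULL, wander_amp = 0, burst_rate = 0)
  expect_identical(same$values, clean$values)
  noisy <- add_noise(clean, white_snr_db = 20, seed = 9)
  realized <- 10 * log10(stats::var(clean$values) /
                           stats::var(noisy$values - clean$values))
  expect_lt(abs(realized - 20), 0.5)
  expect_identical(add_noise(clean, white_snr_db = 20, seed = 9)$values,
                   noisy$values)
  expect_false(identical(add_noise(clean, white_snr_db = 20, seed = 10)$values,
                         noisy$values))
  # wander and bursts change the signal but keep metadata
  messy <- add_noise(clean, wander_amp = 0.5, wander_hz = 0.3,
                     burst_rate = 4, burst_amp = 1, seed = 2)
  expect_equal(messy$fs, clean$fs)
  expect_gt(stats::var(messy$values - clean$values), 0)
  expect_error(add_noise(clean, wander_amp = 1, wander_hz = 2),
               class = "beatkit_invalid_parameter")
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_ecg(ecg_sim_spec(duration = 5, seed = 99)))
  invisible(gen_ppg(ppg_sim_spec(duration = 5, seed = 99)))
  expect_identical(.Random.seed, before)
})
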