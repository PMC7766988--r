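test_that("preprocessing differentiates and attenuates out-of-band tones", {
  fs <- 100
  const <- track(rep(2.5, 400), fs = fs)
  pp <- preprocess_ppg(const)
  expect_equal(pp$lpf$values, rep(2.5, 400), tolerance = 1e-6)
  expect_equal(max(abs(pp$dlpf$values)), 0, tolerance = 1e-4)

  t <- (0:1999) / fs
  sine <- track(sin(2 * pi * t), fs = fs)
  pp <- preprocess_ppg(sine)
  mid <- 500:1500
  # derivative of sin(2 pi t) is 2 pi cos(2 pi t): amplitude 2 pi, 90 deg lead
  expect_equal(max(pp$dlpf$values[mid]), 2 * pi, tolerance = 0.05)
  expect_equal(stats::cor(pp$dlpf$values[mid], cos(2 * pi * t[mid])), 1,
               tolerance = 1e-4)
  # a 25 Hz tone is far above the 10 Hz cutoff: attenuated > 10x
  mixed <- track(sin(2 * pi * t) + 0.5 * sin(2 * pi * 25 * t), fs = fs)
  lp <- preprocess_ppg(mixed)$lpf$values
  resid <- lp[mid] - sin(2 * pi * t[mid])
  expect_lt(max(abs(resid)), 0.5 / 10)
  expect_error(preprocess_ppg(track(rnorm(100), fs = 15)),
               class = "beatkit_invalid_parameter")
})

test_that("zero clamp rectifies exactly", {
  expect_equal(zero_clamp(c(-1, 2, -3)), c(0, 2, 0))
  expect_equal(zero_clamp(c(-5, -0.1)), c(0, 0))
  x <- c(0, 1, 2.5)
  expect_identical(zero_clamp(x), x)
})

test_that("upstroke finding hits the max-slope instant and scales freely", {
  expect_length(find_upstrokes(rep(0, 1000), 125), 0)
  sim <- gen_ppg(ppg_sim_spec(duration = 30, hr = 75, seed = 4))
  pp <- preprocess_ppg(sim$track)
  y <- zero_clamp(pp$dlpf$values)
  ups <- find_upstrokes(y, sim$track$fs)
  expect_equal(length(ups), length(sim$truth$upstroke))
  t_up <- (ups - 1) / sim$track$fs
  expect_lt(max(abs(t_up - sim$truth$upstroke)), 0.020)
  expect_identical(find_upstrokes(7.3 * y, sim$track$fs), ups)
})

test_that("foot and peak sit at the analytic derivative zero-crossings", {
  fs <- 1000
  t <- (0:2999) / fs
  x <- track(-cos(2 * pi * t), fs = fs)      # minima at 0,1,2; maxima at .5,...
  pp <- preprocess_ppg(x)
  up_idx <- which.min(abs(t - 1.25))         # known max-slope instant
  b <- locate_primary_fiducials(pp$lpf, pp$dlpf, up_idx)
  expect_true(b$valid)
  expect_equal(unname(b$foot["t"]), 1.0, tolerance = 1.5 / fs)
  expect_equal(unname(b$peak["t"]), 1.5, tolerance = 1.5 / fs)
  expect_equal(unname(b$upstroke["t"]), 1.25, tolerance = 1.5 / fs)
  expect_equal(unname(b$foot["a"]), -1, tolerance = 1e-3)
  expect_equal(unname(b$peak["a"]), 1, tolerance = 1e-3)

  # monotone rising tail: no downward crossing, beat rejected
  ramp <- track(seq(0, 1, length.out = 2000), fs = fs)
  ppr <- preprocess_ppg(ramp)
  br <- locate_primary_fiducials(ppr$lpf, ppr$dlpf, 1500)
  expect_false(br$valid)
})

test_that("secondary fiducials obey the search windows", {
  # notched pulse: notch and secondary peak recovered near truth
  sim <- gen_ppg(ppg_sim_spec(duration = 30, hr = 75, seed = 6))
  det <- detect_ppg_fiducials(sim$track)
  m <- match_events(det$series$dicrotic_notch$t, sim$truth$dicrotic_notch, 0.015)
  expect_equal(m$fn, 0)
  m <- match_events(det$series$secondary_peak$t, sim$truth$secondary_peak, 0.015)
  expect_equal(m$fn, 0)

  # plain single-Gaussian pulses: nothing secondary exists
  plain <- gen_ppg(ppg_sim_spec(duration = 30, hr = 75, notch_depth = 0, seed = 6))
  detp <- detect_ppg_fiducials(plain$track)
  expect_length(detp$series$dicrotic_notch$t, 0)
  expect_length(detp$series$secondary_peak$t, 0)
  expect_null(plain$truth$dicrotic_notch)

  # notch pushed beyond the time window: reported as absent
  tight <- ppg_params(dn_time_window = 0.3, sp_time_window = 0.3)
  dett <- detect_ppg_fiducials(sim$track, params = tight)
  expect_length(dett$series$dicrotic_notch$t, 0)
  expect_length(dett$series$secondary_peak$t, 0)
  expect_equal(length(dett$series$peak$t), length(det$series$peak$t))
})

test_that("per-beat features follow from the fiducials", {
  beats <- list(
    list(foot = c(t = 1.0, a = 0.0), upstroke = c(t = 1.1, a = 1.0),
         peak = c(t = 1.3, a = 2.0),
         dicrotic_notch = c(t = 1.5, a = 0.8)),
    list(foot = c(t = 1.8, a = 0.0), upstroke = c(t = 1.9, a = 1.0),
         peak = c(t = 2.1, a = 2.0),
         dicrotic_notch = c(t = NA_real_, a = NA_real_)))
  f <- beat_features(beats)
  expect_equal(f$rise_time, c(0.3, 0.3))
  expect_equal(f$foot_peak_amplitude, c(2, 2))
  expect_equal(f$decay_time, c(0.5, NA))        # last beat has no next foot
  expect_equal(f$rise_decay_ratio[1], 0.6)
  expect_equal(f$dn_relative_amplitude, c(0.4, NA))
})

test_that("full pipeline closes on clean synthetic PPG and stays ordered", {
  sim <- gen_ppg(ppg_sim_spec(duration = 60, hr = 60, seed = 2))
  det <- detect_ppg_fiducials(sim$track)
  s <- det$series
  expect_lte(abs(length(s$peak$t) - length(sim$truth$peak)), 1)
  for (nm in c("foot", "upstroke", "peak"))
    expect_equal(f1_score(match_events(s[[nm]]$t, sim$truth[[nm]], 0.05)), 1.0)
  # per-beat ordering and equal primary counts
  expect_equal(length(s$foot$t), length(s$peak$t))
  expect_equal(length(s$upstroke$t), length(s$peak$t))
  expect_true(all(s$foot$t < s$upstroke$t & s$upstroke$t < s$peak$t))
  expect_lte(length(s$dicrotic_notch$t), length(s$peak$t))
})

test_that("a strictly periodic beat train has equal rise times", {
  sim <- gen_ppg(ppg_sim_spec(duration = 40, hr = 60, hrv_sd = 0, seed = 2))
  s <- detect_ppg_fiducials(sim$track)$series
  rt <- s$peak$t - s$foot$t
  expect_lt(max(rt) - min(rt), 2 / sim$track$fs)
})

test_that("flat or empty signals give empty series", {
  flat <- track(rep(1, 1000), fs = 125)
  det <- detect_ppg_fiducials(flat)
  expect_true(all(vapply(det$series, function(s) length(s$t) == 0L, TRUE)))
})

test_that("timestamps ignore amplitude scale, DC offset and block phase", {
  sim <- gen_ppg(ppg_sim_spec(duration = 40, hr = 80, seed = 10))
  base <- detect_ppg_fiducials(sim$track)$series
  mod <- track(5 * sim$track$values - 2, fs = sim$track$fs)
  modded <- detect_ppg_fiducials(mod)$series
  for (nm in names(base))
    expect_equal(modded[[nm]]$t, base[[nm]]$t, tolerance = 1e-9)
  for (ph in c(0.15, 0.4)) {
    shifted <- detect_ppg_fiducials(sim$track, block_phase = ph)$series
    for (nm in names(base))
      expect_equal(shifted[[nm]]$t, base[[nm]]$t)
  }
})

test_that("upstroke timing is at least as robust to noise as peak timing", {
  # realistic PPG disturbance: in-band baseline drift plus white noise.
  # Drift tilts the waveform, moving the rounded extrema; the steep
  # systolic edge barely feels it, which is why the upstroke is the
  # preferred beat marker when millisecond precision matters.
  errs <- sapply(1:50, function(s) {
    sim <- gen_ppg(ppg_sim_spec(duration = 30, hr = 75, seed = s))
    noisy <- add_noise(sim$track, white_snr_db = 30, wander_amp = 0.3,
                       wander_hz = 0.4, seed = s + 900)
    det <- detect_ppg_fiducials(noisy)$series
    err_of <- function(nm) {
      m <- match_events(det[[nm]]$t, sim$truth[[nm]], 0.05)
      if (!m$tp) return(NA_real_)
      mean(abs(m$pairs[, "reference"] - m$pairs[, "detected"]))
    }
    c(up = err_of("upstroke"), peak = err_of("peak"))
  })
  expect_lte(mean(errs["up", ], na.rm = TRUE),
             mean(errs["peak", ], na.rm = TRUE))
})
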