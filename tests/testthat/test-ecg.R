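test_that("wavelet enhancement is linear and localizes a QRS template", {
  fs <- 250
  expect_equal(enhance_peaks(numeric(0), fs), numeric(0))
  expect_equal(enhance_peaks(rep(0, 500), fs), rep(0, 500))
  x <- qrs_template(500, fs, centre = 251)
  y <- enhance_peaks(x, fs)
  expect_true(all(y >= 0))
  expect_equal(length(y), 500)
  # argmax within +-20 ms of the template apex
  expect_lt(abs(which.max(y) - 251) / fs, 0.020)
  # homogeneity: scaling the input scales the output
  expect_equal(enhance_peaks(3.7 * x, fs), 3.7 * y, tolerance = 1e-12)
})

test_that("streaming block detection finds a centred beat exactly once", {
  fs <- 250
  r <- detect_rpeaks_block(rep(0, 125), fs)
  expect_length(r$candidates, 0)
  r <- detect_rpeaks_block(numeric(0), fs, r$state)
  expect_length(r$candidates, 0)

  x <- qrs_template(500, fs, centre = 251)
  st <- NULL
  cands <- integer()
  for (b in split(x, rep(1:4, each = 125))) {
    r <- detect_rpeaks_block(b, fs, st)
    st <- r$state
    cands <- c(cands, r$candidates)
  }
  r <- detect_rpeaks_block(numeric(0), fs, st)
  cands <- c(cands, r$candidates)
  expect_length(cands, 1)
  expect_lt(abs(cands - 251) / fs, 0.020)
})

test_that("block segmentation does not change the candidate set", {
  fs <- 250
  sim <- gen_ecg(ecg_sim_spec(duration = 30, hr = 80, seed = 9))
  x <- sim$track$values
  run <- function(cuts) {
    st <- NULL
    cands <- integer()
    lo <- 1L
    for (e in unique(c(cuts, length(x)))) {
      r <- detect_rpeaks_block(x[lo:e], fs, st)
      st <- r$state
      cands <- c(cands, r$candidates)
      lo <- e + 1L
    }
    r <- detect_rpeaks_block(numeric(0), fs, st)
    c(cands, r$candidates)
  }
  base <- run(seq(125, length(x), by = 125))
  # boundary placed exactly on the third beat's apex
  apex <- round(sim$truth$R[3] * fs)
  shifted <- run(sort(unique(c(apex, seq(apex + 125, length(x), by = 125)))))
  expect_equal(shifted, base)
})

test_that("quadratic refinement matches the vertex formula and parabolas", {
  expect_equal(refine_peak(c(1, 4, 1), 2, fs = 1), 1.0)
  expect_equal(refine_peak(c(1, 4, 3), 2, fs = 1), 1.25)
  expect_equal(refine_peak(c(3, 4, 1), 2, fs = 1), 0.75)
  # flat triple: degenerate denominator gives no shift
  expect_equal(refine_peak(c(2, 2, 2), 2, fs = 1), 1.0)
  # edges are returned unrefined
  expect_equal(refine_peak(c(4, 1, 0), 1, fs = 10), 0)
  expect_equal(refine_peak(c(0, 1, 4), 3, fs = 10), 0.2)
  expect_error(refine_peak(c(1, 0, 2), 2, fs = 1),
               class = "beatkit_invalid_parameter")
  # exact parabolas: vertex recovered to machine precision, any phase
  set.seed(21)
  for (rep in 1:50) {
    v0 <- runif(1, 4.2, 5.8)           # true vertex between samples
    a <- runif(1, 0.5, 3)
    y <- 10 - a * ((1:10) - v0)^2
    i <- which.max(y)
    t_hat <- refine_peak(y, i, fs = 1)
    expect_equal(t_hat, v0 - 1, tolerance = 1e-12)
    expect_lte(abs(t_hat - (i - 1)), 0.5)   # never leaves the sample cell
  }
})

test_that("refinement beats the sample grid on band-limited peaks", {
  fs <- 100
  set.seed(8)
  grid_err <- ref_err <- numeric(100)
  for (k in 1:100) {
    t0 <- 2 + runif(1) / fs            # apex at a random sub-sample phase
    t <- (0:399) / fs
    y <- exp(-((t - t0)^2) / (2 * 0.012^2))
    i <- which.max(y)
    grid_err[k] <- abs((i - 1) / fs - t0)
    ref_err[k] <- abs(refine_peak(y, i, fs) - t0)
  }
  expect_lt(mean(ref_err), mean(grid_err))
  expect_true(all(abs(ref_err - grid_err) <= 0.5 / fs + 1e-12))
})

test_that("whole-record detection closes the loop on clean synthetic ECG", {
  for (hr in c(50, 120)) {
    sim <- gen_ecg(ecg_sim_spec(duration = 60, hr = hr, seed = 42))
    det <- detect_rpeaks(sim$track)
    expect_lte(abs(length(det$t) - length(sim$truth$R)), 1)
    m <- match_events(det$t, sim$truth$R, 0.05)
    expect_equal(f1_score(m), 1.0)
    expect_true(all(diff(det$t) > 0))
  }
})

test_that("detections are invariant to amplitude scale", {
  sim <- gen_ecg(ecg_sim_spec(duration = 30, seed = 13))
  d1 <- detect_rpeaks(sim$track)$t
  half <- track(sim$track$values * 0.5, fs = sim$track$fs)
  expect_equal(detect_rpeaks(half)$t, d1)
  big <- track(sim$track$values * 40, fs = sim$track$fs)
  expect_equal(detect_rpeaks(big)$t, d1)
})

test_that("degenerate inputs are handled explicitly", {
  expect_error(detect_rpeaks(track(rnorm(100), fs = 50)),
               class = "beatkit_invalid_parameter")
  flat <- track(rep(0.7, 2500), fs = 250)
  expect_length(detect_rpeaks(flat)$t, 0)
})

test_that("noise degrades detection gradually, not catastrophically", {
  seeds <- 1:4
  mean_f1 <- sapply(c(30, 10, 5), function(snr) {
    mean(sapply(seeds, function(s) {
      sim <- gen_ecg(ecg_sim_spec(duration = 30, seed = s))
      noisy <- add_noise(sim$track, white_snr_db = snr, seed = s + 500)
      f1_score(match_events(detect_rpeaks(noisy)$t, sim$truth$R, 0.05))
    }))
  })
  expect_gte(mean_f1[1], 0.99)
  expect_true(all(diff(mean_f1) <= 1e-9))   # non-increasing with SNR
})
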