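test_that("track validates its invariants and maps samples to times", {
  tr <- track(c(1, 2, 3), fs = 10, offset = 0.5)
  expect_equal(track_times(tr), 0.5 + (0:2) / 10)
  expect_equal(track_duration(tr), 0.3)
  expect_error(track(1:3, fs = 0), class = "beatkit_invalid_parameter")
  expect_error(track(c(1, NA), fs = 1), class = "beatkit_invalid_parameter")
  expect_error(track(c(1, Inf), fs = 1), class = "beatkit_invalid_parameter")
})

test_that("derivative of constant and linear tracks is exact", {
  expect_equal(derive_track(track(rep(5, 4), fs = 1), "derivative")$values,
               rep(0, 4))
  expect_equal(derive_track(track(0:3, fs = 1), "derivative")$values,
               rep(1, 4))
  # scaled to units/second: same ramp at 100 Hz rises 100x faster
  expect_equal(derive_track(track(0:3, fs = 100), "derivative")$values,
               rep(100, 4))
})

test_that("lowpass passes in-band tones and validates its cutoff", {
  fs <- 100
  t <- (0:1999) / fs
  x <- track(sin(2 * pi * 1 * t), fs = fs)
  lp <- derive_track(x, "lowpass", cutoff_hz = 10)
  # a 1 Hz tone through a 10 Hz lowpass keeps its amplitude within 1 %
  mid <- 500:1500
  expect_lt(abs(max(lp$values[mid]) - 1), 0.01)
  expect_error(derive_track(x, "lowpass", cutoff_hz = 50),
               class = "beatkit_invalid_parameter")
  expect_error(derive_track(x, "lowpass", cutoff_hz = 60),
               class = "beatkit_invalid_parameter")
})

test_that("pinning snaps a click to the window extremum", {
  fs <- 100
  t <- (0:299) / fs
  tri <- track(1 - abs(t - 1), fs = fs)   # apex exactly at t = 1
  expect_equal(pin_to_extremum(tri, 0.92, 0.3, "peak"), 1.0)
  expect_equal(pin_to_extremum(tri, 1.08, 0.3, "valley"), 1.23)
  # monotone increasing stretch: the peak is the right window edge
  ramp <- track(t, fs = fs)
  expect_equal(pin_to_extremum(ramp, 1.0, 0.4, "peak"), 1.2)
  expect_equal(pin_to_extremum(ramp, 1.0, 0.4, "valley"), 0.8)
})

test_that("pinning equals an argmax oracle over the window samples", {
  set.seed(11)
  for (rep in 1:20) {
    tr <- track(rnorm(200), fs = 50)
    t0 <- runif(1, 0.5, 3.5)
    win <- runif(1, 0.1, 0.8)
    got <- pin_to_extremum(tr, t0, win, "peak")
    tt <- track_times(tr)
    idx <- which(tt >= t0 - win / 2 & tt <= t0 + win / 2)
    expect_equal(got, tt[idx[which.max(tr$values[idx])]])
    expect_gte(tr$values[which(tt == got)], max(tr$values[idx]))
    near <- pin_to_extremum(tr, t0, win, "nearest")
    expect_true(near %in% tt[idx[c(which.max(tr$values[idx]),
                                   which.min(tr$values[idx]))]])
  }
})

test_that("signal CSV reading applies fs, column and header settings", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1:500, ecg = sin(1:500)), f, row.names = FALSE)
  tr <- read_signal_csv(f, fs = 250, column = "ecg")
  expect_equal(length(tr$values), 500)
  expect_equal(track_duration(tr), 2)
  expect_equal(tr$name, "ecg")
  expect_error(read_signal_csv(f, fs = 250, column = "nope"),
               class = "beatkit_invalid_parameter")
  expect_error(read_signal_csv(f, fs = 250, column = 7),
               class = "beatkit_invalid_parameter")
})
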