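#' Specification for a synthetic ECG record
#'
#' Each beat is a sum of Gaussian waves (P, Q, R, S, T) placed relative to
#' the R apex; the Q and S waves are symmetric about R, so the analytic
#' apex of the compound waveform coincides with the R-Gaussian centre and
#' the generated ground truth is exact. Beat-to-beat (RR) intervals get
#' optional Gaussian jitter; heart rate may vary over the record.
#'
#' @param fs sampling rate, Hz (>= 100).
#' @param duration record length, seconds.
#' @param hr heart rate, bpm, in (20, 240]; a vector is interpreted as
#'   evenly spaced breakpoints over the record and interpolated linearly
#'   (variable heart rate).
#' @param qrs_width total QRS width, seconds, in (0.04, 0.2).
#' @param p_amp,t_amp,r_amp P/T/R wave amplitudes relative to `r_amp = 1`
#'   conventions (arbitrary units).
#' @param qt QT-like interval: T-wave centre delay after R, seconds.
#' @param hrv_sd standard deviation of Gaussian RR jitter, seconds.
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return a list of class `"ecg_sim_spec"`.
#' @export
ecg_sim_spec <- function(fs = 250, duration = 60, hr = 75, qrs_width = 0.08,
                         p_amp = 0.15, t_amp = 0.35, r_amp = 1, qt = 0.3,
                         hrv_sd = 0.01, seed = 1L) {
  if (fs < 100) stop_invalid("fs must be >= 100 Hz")
  if (any(hr <= 20 | hr > 240)) stop_invalid("hr must lie in (20, 240] bpm")
  if (qrs_width <= 0.04 || qrs_width >= 0.2)
    stop_invalid("qrs_width must lie in (0.04, 0.2) s")
  if (duration <= 0) stop_invalid("duration must be > 0")
  if (hrv_sd < 0) stop_invalid("hrv_sd must be >= 0")
  structure(list(fs = fs, duration = duration, hr = hr, qrs_width = qrs_width,
                 p_amp = p_amp, t_amp = t_amp, r_amp = r_amp, qt = qt,
                 hrv_sd = hrv_sd, seed = as.integer(seed)),
            class = "ecg_sim_spec")
}

# beat start times over [0, duration]: instantaneous rate is interpolated
# between hr breakpoints; jitter added per interval and clipped so order
# and a minimal gap are preserved
sim_beat_times <- function(duration, hr, hrv_sd, first = 0.4) {
  hr_at <- function(t) {
    if (length(hr) == 1L) return(rep(hr, length(t)))
    bp <- seq(0, duration, length.out = length(hr))
    approx(bp, hr, xout = pmin(pmax(t, 0), duration), rule = 2)$y
  }
  times <- numeric(0)
  t <- first
  while (t < duration) {
    times <- c(times, t)
    rr <- 60 / hr_at(t)
    if (hrv_sd > 0) {
      j <- rnorm(1, 0, hrv_sd)
      j <- max(-0.4 * rr, min(0.4 * rr, j))
      rr <- rr + j
    }
    t <- t + rr
  }
  times
}

gauss_wave <- function(t, centre, sigma, amp) {
  amp * exp(-((t - centre)^2) / (2 * sigma^2))
}

#' Generate a synthetic ECG with exact R-peak ground truth
#'
#' @param spec an [ecg_sim_spec()].
#' @return a list of class `"sim_output"`: `track` (a [track()]) and
#'   `truth`, a named list of strictly increasing fiducial timestamp
#'   vectors (here a single `"R"` entry).
#' @examples
#' sim <- gen_ecg(ecg_sim_spec(duration = 10, hr = 60, hrv_sd = 0, seed = 7))
#' length(sim$truth$R)   # 10 beats at exactly 1-s spacing
#' @export
gen_ecg <- function(spec) {
  stopifnot(inherits(spec, "ecg_sim_spec"))
  beats <- with_seed(spec$seed,
    sim_beat_times(spec$duration, spec$hr, spec$hrv_sd))
  # keep only beats whose apex is comfortably inside the sampled span
  beats <- beats[beats < spec$duration - 0.05]
  t <- (seq_len(round(spec$duration * spec$fs)) - 1) / spec$fs
  v <- numeric(length(t))
  s_r <- spec$qrs_width / 6           # R Gaussian width
  qs_off <- spec$qrs_width / 2.2      # symmetric Q/S offsets
  s_qs <- spec$qrs_width / 9
  for (b in beats) {
    keep <- t >= b - 0.45 & t <= b + 0.6
    tk <- t[keep]
    v[keep] <- v[keep] +
      gauss_wave(tk, b, s_r, spec$r_amp) +
      gauss_wave(tk, b - qs_off, s_qs, -0.18 * spec$r_amp) +
      gauss_wave(tk, b + qs_off, s_qs, -0.18 * spec$r_amp) +
      gauss_wave(tk, b - 0.22, 0.035, spec$p_amp) +
      gauss_wave(tk, b + spec$qt, 0.07, spec$t_amp)
  }
  structure(list(track = track(v, fs = spec$fs, name = "ecg", units = "mV"),
                 truth = list(R = beats)),
            class = "sim_output")
}

#' Specification for a synthetic PPG record
#'
#' Each pulse is a primary Gaussian (systolic rise to a rounded peak) plus
#' an optional delayed, wider secondary Gaussian; their superposition
#' creates a dicrotic notch and secondary peak. Ground truth (foot,
#' upstroke, peak, and when present notch and secondary peak) is computed
#' from the continuous analytic waveform on a fine grid, independent of
#' the output sampling rate.
#'
#' @param fs sampling rate, Hz (>= 25).
#' @param duration record length, seconds.
#' @param hr pulse rate, bpm (scalar or breakpoint vector as in
#'   [ecg_sim_spec()]).
#' @param hrv_sd Gaussian jitter on pulse-to-pulse intervals, seconds.
#' @param rise_fraction fraction of the nominal beat period from pulse
#'   onset region to the systolic peak, in (0.1, 0.5).
#' @param notch_delay delay of the secondary (diastolic) component after
#'   the systolic peak, seconds; `NULL` defaults to 35% of the nominal
#'   beat period.
#' @param notch_depth in \[0, 1): 0 disables the secondary component (no
#'   notch in the signal or the truth); larger values deepen the notch by
#'   spacing the two components further apart in amplitude terms.
#' @param second_peak_amp secondary component amplitude relative to the
#'   primary.
#' @param seed integer seed.
#' @return a list of class `"ppg_sim_spec"`.
#' @export
ppg_sim_spec <- function(fs = 125, duration = 60, hr = 75, hrv_sd = 0.01,
                         rise_fraction = 0.25, notch_delay = NULL,
                         notch_depth = 0.3, second_peak_amp = 0.35,
                         seed = 1L) {
  if (fs < 25) stop_invalid("fs must be >= 25 Hz")
  if (any(hr <= 20 | hr > 240)) stop_invalid("hr must lie in (20, 240] bpm")
  if (rise_fraction <= 0.1 || rise_fraction >= 0.5)
    stop_invalid("rise_fraction must lie in (0.1, 0.5)")
  if (notch_depth < 0 || notch_depth >= 1)
    stop_invalid("notch_depth must lie in [0, 1)")
  structure(list(fs = fs, duration = duration, hr = hr, hrv_sd = hrv_sd,
                 rise_fraction = rise_fraction, notch_delay = notch_delay,
                 notch_depth = notch_depth, second_peak_amp = second_peak_amp,
                 seed = as.integer(seed)),
            class = "ppg_sim_spec")
}

#' Generate a synthetic PPG with exact fiducial ground truth
#'
#' @param spec a [ppg_sim_spec()].
#' @return a list of class `"sim_output"`: `track` and `truth` with
#'   entries `foot`, `upstroke`, `peak` and, when `notch_depth > 0`,
#'   `dicrotic_notch` and `secondary_peak`. Truth is evaluated from the
#'   continuous pulse model on a 2 kHz grid with quadratic refinement, so
#'   it is accurate well below one output sample.
#' @export
gen_ppg <- function(spec) {
  stopifnot(inherits(spec, "ppg_sim_spec"))
  T0 <- 60 / mean(spec$hr)                 # nominal period fixes morphology
  rise <- spec$rise_fraction * T0
  s1 <- rise / 2.5
  delay <- if (is.null(spec$notch_delay)) 0.35 * T0 else spec$notch_delay
  amp2 <- if (spec$notch_depth > 0) spec$second_peak_amp else 0
  s2 <- 0.8 * s1
  has_notch <- amp2 > 0

  # first pulse placed so its onset trough falls clearly inside the record
  peaks0 <- with_seed(spec$seed,
    sim_beat_times(spec$duration, spec$hr, spec$hrv_sd,
                   first = rise + 0.35 * T0))
  # every rendered pulse (incl. its diastolic tail) lies fully inside the
  # record, so detector and truth agree on which beats exist
  peaks0 <- peaks0[peaks0 + delay + 4 * s2 + 0.1 < spec$duration]
  # a lead-in pulse before t = 0: the record then opens on a decay, which
  # gives the first in-record beat a well-defined foot (a genuine trough)
  phantom <- if (length(peaks0)) peaks0[1] - T0 else numeric()
  render <- c(phantom, peaks0)
  # continuous pulse model: superposition over all rendered beats
  model <- function(tt) {
    out <- numeric(length(tt))
    for (pk in render) {
      keep <- tt >= pk - 4 * s1 - T0 & tt <= pk + delay + 5 * s2
      if (!any(keep)) next
      out[keep] <- out[keep] + gauss_wave(tt[keep], pk, s1, 1) +
        (if (has_notch) gauss_wave(tt[keep], pk + delay, s2, amp2) else 0)
    }
    out
  }
  t <- (seq_len(round(spec$duration * spec$fs)) - 1) / spec$fs
  v <- model(t)

  # ground truth from the analytic model on a fine grid
  fine_fs <- 2000
  refine_grid <- function(g, y, i) {   # parabola vertex through 3 grid points
    if (i <= 1L || i >= length(y)) return(g[i])
    den <- y[i - 1] - 2 * y[i] + y[i + 1]
    d <- if (den == 0) 0 else 0.5 * (y[i - 1] - y[i + 1]) / den
    g[i] + max(-0.5, min(0.5, d)) / fine_fs
  }
  tr_foot <- numeric(); tr_up <- numeric(); tr_peak <- numeric()
  tr_dn <- numeric(); tr_sp <- numeric()
  for (i in seq_along(peaks0)) {
    pk <- peaks0[i]
    prev <- render[i]   # previous rendered pulse (phantom for the first)
    # search no earlier than the previous pulse's diastolic component, so
    # the minimum found is this beat's foot trough and not an older one
    g_lo <- max(pk - 0.9 * T0,
                prev + if (has_notch) delay + 1.5 * s2 else 2 * s1)
    g <- seq(g_lo, min(pk + delay + 3 * s2, spec$duration), 1 / fine_fs)
    y <- model(g)
    dy <- central_diff(y) * fine_fs
    in_rise <- g > pk - 3.5 * s1 & g < pk
    if (!any(in_rise)) next
    i_up <- which(in_rise)[which.max(dy[in_rise])]
    pre <- g < g[i_up]
    i_foot <- which(pre)[which.min(y[pre])]
    near_pk <- g > pk - 2 * s1 & g < pk + 2 * s1
    i_peak <- which(near_pk)[which.max(y[near_pk])]
    foot_t <- refine_grid(g, -y, i_foot)
    up_t <- refine_grid(g, dy, i_up)
    peak_t <- refine_grid(g, y, i_peak)
    if (foot_t < 0 || peak_t > spec$duration) next
    tr_foot <- c(tr_foot, foot_t); tr_up <- c(tr_up, up_t)
    tr_peak <- c(tr_peak, peak_t)
    if (has_notch) {
      mid <- g > g[i_peak] & g < pk + delay
      if (any(mid)) {
        i_dn <- which(mid)[which.min(y[mid])]
        post <- g > g[i_dn] & g < pk + delay + 2 * s2
        i_sp <- which(post)[which.max(y[post])]
        if (length(i_sp) && i_dn < i_sp && y[i_dn] < y[i_sp]) {
          tr_dn <- c(tr_dn, refine_grid(g, -y, i_dn))
          tr_sp <- c(tr_sp, refine_grid(g, y, i_sp))
        }
      }
    }
  }
  truth <- list(foot = tr_foot, upstroke = tr_up, peak = tr_peak)
  if (has_notch) {
    truth$dicrotic_notch <- tr_dn
    truth$secondary_peak <- tr_sp
  }
  structure(list(track = track(v, fs = spec$fs, name = "ppg", units = "a.u."),
                 truth = truth),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat("<sim_output>\n  ")
  print(x$track)
  for (nm in names(x$truth))
    cat(sprintf("  truth$%-15s %d events\n", nm, length(x$truth[[nm]])))
  invisible(x)
}

#' Add controlled noise to a track
#'
#' Adds, in this order: white Gaussian noise at a requested signal-to-noise
#' ratio, sinusoidal baseline wander, and random square-windowed
#' high-amplitude noise bursts (crude motion-artifact stand-ins of 0.5–2 s).
#' The input track is not modified.
#'
#' @param x a [track()].
#' @param white_snr_db SNR of the additive white noise in dB relative to
#'   the signal's variance, or `NULL` for none.
#' @param wander_amp baseline-wander amplitude (same units as the signal).
#' @param wander_hz baseline-wander frequency, Hz (< 1).
#' @param burst_rate expected bursts per minute.
#' @param burst_amp standard deviation of the in-burst noise.
#' @param seed integer seed; output is deterministic given it.
#' @return a new [track()] with the same metadata.
#' @export
add_noise <- function(x, white_snr_db = NULL, wander_amp = 0, wander_hz = 0.3,
                      burst_rate = 0, burst_amp = 0, seed = 1L) {
  stopifnot(is_track(x))
  if (wander_amp > 0 && wander_hz >= 1)
    stop_invalid("wander_hz must be < 1 Hz")
  n <- length(x$values)
  t <- track_times(x)
  v <- x$values
  with_seed(seed, {
    if (!is.null(white_snr_db)) {
      p_sig <- stats::var(x$values)
      sd_n <- sqrt(p_sig / 10^(white_snr_db / 10))
      v <- v + rnorm(n, 0, sd_n)
    }
    if (wander_amp > 0) {
      phase <- runif(1, 0, 2 * pi)
      v <- v + wander_amp * sin(2 * pi * wander_hz * t + phase)
    }
    if (burst_rate > 0 && burst_amp > 0) {
      n_burst <- rpois(1, burst_rate * track_duration(x) / 60)
      if (n_burst > 0) {
        for (k in seq_len(n_burst)) {
          b0 <- runif(1, 0, track_duration(x))
          dur <- runif(1, 0.5, 2)
          in_b <- t >= x$offset + b0 & t < x$offset + b0 + dur
          v[in_b] <- v[in_b] + rnorm(sum(in_b), 0, burst_amp)
        }
      }
    }
  })
  track(v, fs = x$fs, name = x$name, offset = x$offset, units = x$units)
}
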