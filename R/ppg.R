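#' PPG fiducial detector parameters
#'
#' The PPG detector is derivative-based: the signal is low-pass filtered
#' (zero-phase, so fiducial timestamps are not delayed), differentiated,
#' and the clamped derivative is scanned for upstrokes with the same
#' adaptive threshold used by the ECG detector. Foot and systolic peak are
#' the derivative zero-crossings bracketing each upstroke; shoulder,
#' dicrotic notch and secondary peak are searched in windows expressed as
#' fractions of the beat's own rise time and amplitude.
#'
#' @param lpf_cutoff low-pass cutoff, Hz (default 10, which keeps pulse
#'   morphology while removing high-frequency noise).
#' @param lpf_order Butterworth order of the (forward-backward) low-pass.
#' @param block_len threshold-update block length, seconds.
#' @param noise_alpha,qpd_attack_tc,qpd_decay_tc,w_n,w_s,threshold_scale
#'   adaptive-threshold parameters, as in [ecg_params()]. The default
#'   `threshold_scale` is higher than the ECG one so that the (smaller)
#'   derivative peak of the diastolic rise does not fire the upstroke
#'   detector.
#' @param refractory minimum time between upstrokes, seconds.
#' @param sp_time_window,dn_time_window how far after the systolic peak
#'   the secondary peak / dicrotic notch may lie, as a multiple of the
#'   beat's foot-to-peak rise time.
#' @param sp_amp_window,dn_amp_window how far below the systolic peak the
#'   secondary peak / dicrotic notch amplitude may lie, as a multiple of
#'   the beat's foot-to-peak amplitude.
#' @param min_fs lowest accepted sampling rate, Hz.
#' @return a list of class `"ppg_params"`.
#' @export
ppg_params <- function(lpf_cutoff = 10, lpf_order = 4, block_len = 0.5,
                       noise_alpha = 0.2, qpd_attack_tc = 0.01,
                       qpd_decay_tc = 1.5, w_n = 1, w_s = 1,
                       threshold_scale = 0.55, refractory = 0.25,
                       sp_time_window = 2.0, dn_time_window = 2.0,
                       sp_amp_window = 1.0, dn_amp_window = 1.0,
                       min_fs = 25) {
  if (lpf_cutoff <= 0) stop_invalid("lpf_cutoff must be > 0")
  wins <- c(sp_time_window, dn_time_window, sp_amp_window, dn_amp_window)
  if (any(wins <= 0 | wins > 5))
    stop_invalid("search-window fractions must lie in (0, 5]")
  if (refractory <= 0) stop_invalid("refractory must be > 0")
  structure(list(lpf_cutoff = lpf_cutoff, lpf_order = lpf_order,
                 block_len = block_len, noise_alpha = noise_alpha,
                 qpd_attack_tc = qpd_attack_tc, qpd_decay_tc = qpd_decay_tc,
                 w_n = w_n, w_s = w_s, threshold_scale = threshold_scale,
                 refractory = refractory, sp_time_window = sp_time_window,
                 dn_time_window = dn_time_window, sp_amp_window = sp_amp_window,
                 dn_amp_window = dn_amp_window, min_fs = min_fs),
            class = "ppg_params")
}

#' Preprocess a PPG track: low-pass and derivative
#'
#' @param x a [track()] with `fs >= params$min_fs`.
#' @param params a [ppg_params()] list; `lpf_cutoff` must be below the
#'   Nyquist frequency.
#' @return `list(lpf = <filtered track>, dlpf = <its time derivative,
#'   units/s>)`, both with the input's length, `fs` and `offset`.
#' @export
preprocess_ppg <- function(x, params = ppg_params()) {
  stopifnot(is_track(x))
  if (x$fs < params$min_fs)
    stop_invalid("sampling rate below the minimum ", params$min_fs, " Hz")
  if (params$lpf_cutoff >= x$fs / 2)
    stop_invalid("lpf_cutoff must be below the Nyquist frequency fs/2")
  lpf <- derive_track(x, "lowpass", cutoff_hz = params$lpf_cutoff,
                      order = params$lpf_order)
  dlpf <- derive_track(lpf, "derivative")
  list(lpf = lpf, dlpf = dlpf)
}

#' Clamp negative values to zero
#'
#' Rectifies the derivative before upstroke detection — an upstroke always
#' has positive polarity, so the negative (decay) half is discarded.
#'
#' @param x numeric vector.
#' @return `pmax(x, 0)`, same length.
#' @export
zero_clamp <- function(x) pmax(as.numeric(x), 0)

#' Find PPG upstrokes on the clamped derivative
#'
#' Local maxima of the rectified derivative exceeding the adaptive
#' threshold (noise level + quasi-peak detector, as in the ECG detector),
#' at least a refractory period apart. Processing is block-wise with state
#' carry-over; the result does not depend on the block segmentation.
#'
#' @param abs_dlpfs non-negative numeric vector (the zero-clamped
#'   derivative).
#' @param fs sampling rate, Hz.
#' @param params a [ppg_params()] list.
#' @param block_phase length of the first (shorter) block, seconds; see
#'   [detect_rpeaks()].
#' @return integer vector of 1-based sample indices of upstroke maxima.
#' @export
find_upstrokes <- function(abs_dlpfs, fs, params = ppg_params(),
                           block_phase = 0) {
  n <- length(abs_dlpfs)
  if (!n) return(integer())
  if (any(abs_dlpfs < 0)) stop_invalid("abs_dlpfs must be non-negative")
  bl <- max(1L, round(params$block_len * fs))
  ph <- if (block_phase > 0) min(max(1L, round(block_phase * fs)), n) else 0L
  ends <- sort(unique(c(seq(ph + bl, n, by = bl), if (ph > 0) ph, n)))
  starts <- c(1L, head(ends, -1L) + 1L)
  st <- ath_prime(ath_state_new(), abs_dlpfs[1:min(n, round(2 * fs))],
                  fs, params)
  cands <- integer()
  for (k in seq_along(starts)) {
    r <- ath_process(st, abs_dlpfs[starts[k]:ends[k]], fs, params)
    st <- r$state
    cands <- c(cands, r$candidates)
  }
  r <- ath_flush(st, params, fs)
  c(cands, r$candidates)
}

# linear-interpolated time of a zero crossing between samples i and i+1
zc_time <- function(v, i, fs, offset) {
  a <- v[i]; b <- v[i + 1L]
  frac <- if (a == b) 0 else a / (a - b)
  offset + (i - 1 + frac) / fs
}

# signal value at an arbitrary (sub-sample) time, linear interpolation
track_value_at <- function(x, t) {
  approx(track_times(x), x$values, xout = t, rule = 2)$y
}

#' Locate foot and systolic peak around one upstroke
#'
#' The foot is the last upward zero-crossing of the derivative
#' (`dlpf <= 0` to `> 0`) before the upstroke; the systolic peak is the
#' first downward crossing (`> 0` to `<= 0`) after it. Crossing times are
#' linearly interpolated between the bracketing samples, and amplitudes
#' read off the filtered signal at those times. A beat whose foot or peak
#' crossing does not exist before the record edge (or the next upstroke)
#' is rejected.
#'
#' @param lpf,dlpf the two tracks from [preprocess_ppg()].
#' @param upstroke_idx 1-based sample index of the upstroke (a local
#'   maximum of the clamped derivative).
#' @param next_upstroke_idx optional bound for the peak search.
#' @return `list(valid = TRUE, foot = c(t, a), upstroke = c(t, a),
#'   peak = c(t, a))`, or `list(valid = FALSE, reason = <text>)`.
#' @export
locate_primary_fiducials <- function(lpf, dlpf, upstroke_idx,
                                     next_upstroke_idx = NULL) {
  d <- dlpf$values
  n <- length(d)
  i <- as.integer(upstroke_idx)
  if (i < 1L || i > n) stop_invalid("upstroke_idx out of range")
  if (d[i] <= 0)
    return(list(valid = FALSE, reason = "derivative not positive at upstroke"))
  # foot: last i0 < i with d[i0] <= 0 < d[i0+1]
  before <- which(d[seq_len(i - 1L)] <= 0)
  if (!length(before))
    return(list(valid = FALSE, reason = "no upward zero-crossing before upstroke"))
  i0 <- max(before)
  # peak: first i1 >= i with d[i1] > 0 >= d[i1+1]
  hi <- if (is.null(next_upstroke_idx)) n else min(n, as.integer(next_upstroke_idx))
  after <- which(d[i:hi] <= 0)
  if (!length(after))
    return(list(valid = FALSE, reason = "no downward zero-crossing after upstroke"))
  i1 <- i + min(after) - 2L
  foot_t <- zc_time(d, i0, dlpf$fs, dlpf$offset)
  peak_t <- zc_time(d, i1, dlpf$fs, dlpf$offset)
  up_t <- refine_peak(zero_clamp(d), i, dlpf$fs, dlpf$offset)
  list(valid = TRUE,
       foot = c(t = foot_t, a = track_value_at(lpf, foot_t)),
       upstroke = c(t = up_t, a = track_value_at(lpf, up_t)),
       peak = c(t = peak_t, a = track_value_at(lpf, peak_t)))
}

#' Locate shoulder, dicrotic notch and secondary peak for one beat
#'
#' The shoulder is the first local minimum of the derivative strictly
#' between upstroke and systolic peak (absent when the derivative is
#' unimodal there). After the peak the derivative is negative; its next
#' upward zero-crossing is the dicrotic notch and the following downward
#' crossing the secondary peak. Both are accepted only inside the search
#' windows: at most `dn_time_window` (resp. `sp_time_window`) times the
#' beat's rise time after the peak, and within `dn_amp_window`
#' (`sp_amp_window`) times the foot-to-peak amplitude below the peak.
#' Anything not found is `NA`.
#'
#' @param lpf,dlpf tracks from [preprocess_ppg()].
#' @param beat a valid beat from [locate_primary_fiducials()].
#' @param params a [ppg_params()] list.
#' @param next_upstroke_idx optional search bound (next beat's upstroke).
#' @return `list(shoulder = c(t, a), dicrotic_notch = c(t, a),
#'   secondary_peak = c(t, a))`, each `c(NA, NA)` when absent.
#' @export
locate_secondary_fiducials <- function(lpf, dlpf, beat, params = ppg_params(),
                                       next_upstroke_idx = NULL) {
  stopifnot(isTRUE(beat$valid))
  d <- dlpf$values
  fs <- dlpf$fs; off <- dlpf$offset
  n <- length(d)
  nothing <- c(t = NA_real_, a = NA_real_)
  sh <- dn <- sp <- nothing
  idx_at <- function(t) as.integer(floor((unname(t) - off) * fs)) + 1L
  i_up <- idx_at(beat$upstroke["t"]) + 1L
  i_pk <- idx_at(beat$peak["t"])
  rise <- beat$peak["t"] - beat$foot["t"]
  amp <- beat$peak["a"] - beat$foot["a"]

  # excursions smaller than this are numerical ripple, not morphology
  eps <- 0.02 * max(d[seq(max(1L, i_up - 2L), max(i_up, i_pk))])

  # shoulder: first interior local minimum of d between upstroke and peak
  # with a genuine rebound (filters out sub-ripple wiggles)
  if (i_pk - i_up >= 3L) {
    seg <- d[i_up:i_pk]
    loc_min <- which(diff(sign(diff(seg))) > 0) + 1L
    for (m in loc_min) {
      if (max(seg[m:length(seg)]) - seg[m] >= eps) {
        j <- i_up + m - 1L
        sh_t <- off + (j - 1) / fs
        sh <- c(t = sh_t, a = track_value_at(lpf, sh_t))
        break
      }
    }
  }

  hi <- if (is.null(next_upstroke_idx)) n - 1L else
    min(n - 1L, as.integer(next_upstroke_idx))
  i1 <- i_pk + 1L
  while (i1 <= hi && d[i1] > 0) i1 <- i1 + 1L   # enter the negative lobe
  # dicrotic notch: next upward crossing (d <= 0 -> > 0) after the peak
  # whose positive lobe is real (reaches eps); secondary peak: the
  # downward crossing closing that lobe
  j <- i1
  while (j <= hi) {
    while (j <= hi && !(d[j] <= 0 && d[j + 1L] > 0)) j <- j + 1L
    if (j > hi) break
    k <- j + 1L
    while (k <= hi && !(d[k] > 0 && d[k + 1L] <= 0)) k <- k + 1L
    if (k > hi) {
      # lobe never closes before the next upstroke: that rise is the next
      # beat's systole, not a diastolic rebound of this one
      j <- hi + 1L
      break
    }
    lobe_top <- max(d[(j + 1L):min(k, n)])
    if (lobe_top >= eps) break
    j <- k                                       # ripple lobe: keep looking
  }
  if (j <= hi) {
    dn_t <- zc_time(d, j, fs, off)
    dn_a <- track_value_at(lpf, dn_t)
    dn_ok <- (dn_t - beat$peak["t"]) <= params$dn_time_window * rise &&
      (beat$peak["a"] - dn_a) <= params$dn_amp_window * amp &&
      dn_t > beat$peak["t"]
    if (dn_ok) {
      dn <- c(t = unname(dn_t), a = unname(dn_a))
      if (k <= hi) {
        sp_t <- zc_time(d, k, fs, off)
        sp_a <- track_value_at(lpf, sp_t)
        sp_ok <- (sp_t - beat$peak["t"]) <= params$sp_time_window * rise &&
          (beat$peak["a"] - sp_a) <= params$sp_amp_window * amp
        if (sp_ok) sp <- c(t = unname(sp_t), a = unname(sp_a))
      }
    }
  }
  list(shoulder = sh, dicrotic_notch = dn, secondary_peak = sp)
}

#' Per-beat timing and amplitude features
#'
#' @param beats list of beats: each a list with `foot`, `upstroke`,
#'   `peak` (named `c(t, a)` vectors) and optionally `dicrotic_notch`.
#' @return a data.frame with one row per beat: `rise_time` (foot to
#'   peak), `decay_time` (peak to next foot; `NA` for the last beat),
#'   `foot_peak_amplitude`, `rise_decay_ratio`, and
#'   `dn_relative_amplitude` (notch height above the foot as a fraction
#'   of the pulse amplitude; `NA` without a notch).
#' @export
beat_features <- function(beats) {
  n <- length(beats)
  nav <- rep(NA_real_, n)
  out <- data.frame(rise_time = nav, decay_time = nav,
                    foot_peak_amplitude = nav, rise_decay_ratio = nav,
                    dn_relative_amplitude = nav)
  for (i in seq_len(n)) {
    b <- beats[[i]]
    out$rise_time[i] <- b$peak["t"] - b$foot["t"]
    out$foot_peak_amplitude[i] <- b$peak["a"] - b$foot["a"]
    if (i < n)
      out$decay_time[i] <- beats[[i + 1L]]$foot["t"] - b$peak["t"]
    out$rise_decay_ratio[i] <- out$rise_time[i] / out$decay_time[i]
    dn <- b$dicrotic_notch
    if (!is.null(dn) && !is.na(dn["t"]))
      out$dn_relative_amplitude[i] <-
        (dn["a"] - b$foot["a"]) / out$foot_peak_amplitude[i]
  }
  out
}

#' Detect all PPG fiducials in a track
#'
#' Full pipeline: low-pass + differentiate ([preprocess_ppg()]), rectify,
#' find upstrokes ([find_upstrokes()]), then derive foot/peak per beat
#' ([locate_primary_fiducials()]; beats missing either crossing are
#' dropped) and the optional shoulder/notch/secondary peak
#' ([locate_secondary_fiducials()]). Timestamps are invariant to
#' amplitude scaling and DC offset of the input.
#'
#' @param x a [track()] holding the PPG.
#' @param params a [ppg_params()] list.
#' @param block_phase first-block length for the streaming upstroke
#'   detector, seconds; results should not depend on it.
#' @return named list of [fiducial_series()]: `foot`, `upstroke`, `peak`
#'   (equal lengths), `shoulder`, `dicrotic_notch`, `secondary_peak`
#'   (absent-per-beat fiducials are simply missing from their series),
#'   plus a `features` data.frame attribute-free companion from
#'   [beat_features()].
#' @examples
#' sim <- gen_ppg(ppg_sim_spec(duration = 20, hr = 70, seed = 1))
#' fids <- detect_ppg_fiducials(sim$track)
#' sapply(fids$series, length)
#' @export
detect_ppg_fiducials <- function(x, params = ppg_params(), block_phase = 0) {
  stopifnot(is_track(x))
  empty <- function(nm) fiducial_series(nm, min_distance = 0)
  names_all <- c("foot", "upstroke", "peak", "shoulder",
                 "dicrotic_notch", "secondary_peak")
  if (length(x$values) < 4 * params$lpf_order + 2 ||
      stats::sd(x$values) == 0) {
    series <- lapply(names_all, empty); names(series) <- names_all
    return(list(series = series, features = beat_features(list())))
  }
  pp <- preprocess_ppg(x, params)
  y <- zero_clamp(pp$dlpf$values)
  ups <- find_upstrokes(y, x$fs, params, block_phase = block_phase)
  beats <- list()
  for (k in seq_along(ups)) {
    nxt <- if (k < length(ups)) ups[k + 1L] else NULL
    b <- locate_primary_fiducials(pp$lpf, pp$dlpf, ups[k], nxt)
    if (!isTRUE(b$valid)) next
    sec <- locate_secondary_fiducials(pp$lpf, pp$dlpf, b, params, nxt)
    beats[[length(beats) + 1L]] <- c(b[c("foot", "upstroke", "peak")], sec)
  }
  collect <- function(nm) {
    t <- vapply(beats, function(b) unname(b[[nm]]["t"]), 0)
    a <- vapply(beats, function(b) unname(b[[nm]]["a"]), 0)
    keep <- !is.na(t)
    # enforce strict ordering defensively (degenerate beats could tie)
    t <- t[keep]; a <- a[keep]
    if (length(t) > 1L) {
      ord_ok <- c(TRUE, diff(t) > 0)
      t <- t[ord_ok]; a <- a[ord_ok]
    }
    fiducial_series(nm, t = t, amplitude = a, min_distance = 0)
  }
  series <- lapply(names_all, collect)
  names(series) <- names_all
  list(series = series, features = beat_features(beats))
}
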