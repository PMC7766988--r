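#' ECG R-peak detector parameters
#'
#' The detector enhances the QRS complex with a single-scale continuous
#' wavelet transform (Mexican-hat kernel tuned to the 10–25 Hz QRS band),
#' takes the modulus, and compares it block by block against the adaptive
#' threshold of [update_threshold()]. Detected maxima are refined to
#' sub-sample precision on the raw ECG by quadratic interpolation.
#'
#' @param block_len processing block length, seconds (default 0.5).
#' @param wavelet_scale wavelet width parameter \eqn{\sigma}, seconds. The
#'   Mexican-hat peak frequency is \eqn{1/(\sqrt{2}\pi\sigma)}, so the
#'   default 0.015 s centres the response near 15 Hz; the kernel length in
#'   samples scales with `fs` automatically.
#' @param noise_alpha exponential-moving-average coefficient for the
#'   per-block standard deviation that forms the noise level, in (0, 1].
#' @param qpd_attack_tc,qpd_decay_tc quasi-peak-detector attack and decay
#'   time constants, seconds (fast attack, slow decay:
#'   `qpd_attack_tc <= qpd_decay_tc`).
#' @param w_n,w_s noise- and signal-level weights in the threshold sum.
#' @param threshold_scale overall scale `c` of the threshold
#'   `c * (w_n * noise + w_s * qpd)`; balances catching early/premature
#'   beats against mistaking tall T-waves for beats.
#' @param refractory minimum time between detected beats, seconds.
#'   0.25 s corresponds to a 240 bpm physiological ceiling.
#' @param refine_window half-width, seconds, of the raw-ECG search window
#'   around an enhanced-domain candidate inside which the R apex is
#'   located and refined.
#' @param min_fs lowest accepted sampling rate, Hz (no internal
#'   resampling is performed).
#' @return a list of class `"ecg_params"`.
#' @export
ecg_params <- function(block_len = 0.5, wavelet_scale = 0.015,
                       noise_alpha = 0.2, qpd_attack_tc = 0.01,
                       qpd_decay_tc = 1.5, w_n = 1, w_s = 1,
                       threshold_scale = 0.35, refractory = 0.25,
                       refine_window = 0.04, min_fs = 100) {
  if (block_len <= 0) stop_invalid("block_len must be > 0")
  if (wavelet_scale <= 0) stop_invalid("wavelet_scale must be > 0")
  if (noise_alpha <= 0 || noise_alpha > 1) stop_invalid("noise_alpha in (0,1]")
  if (qpd_attack_tc <= 0 || qpd_decay_tc < qpd_attack_tc)
    stop_invalid("need 0 < qpd_attack_tc <= qpd_decay_tc")
  if (w_n <= 0 || w_s <= 0 || threshold_scale <= 0)
    stop_invalid("weights and threshold_scale must be > 0")
  if (refractory <= 0) stop_invalid("refractory must be > 0")
  structure(list(block_len = block_len, wavelet_scale = wavelet_scale,
                 noise_alpha = noise_alpha, qpd_attack_tc = qpd_attack_tc,
                 qpd_decay_tc = qpd_decay_tc, w_n = w_n, w_s = w_s,
                 threshold_scale = threshold_scale, refractory = refractory,
                 refine_window = refine_window, min_fs = min_fs),
            class = "ecg_params")
}

# Mexican-hat (Ricker) kernel sampled at fs, width sigma seconds,
# normalised to unit L2 norm. Length 2L+1 with L = ceil(5 sigma fs).
ricker_kernel <- function(fs, sigma) {
  L <- ceiling(5 * sigma * fs)
  t <- (-L:L) / fs
  w <- (1 - (t / sigma)^2) * exp(-(t / sigma)^2 / 2)
  w <- w - mean(w)          # exact zero mean: DC input maps to Y = 0
  w / sqrt(sum(w^2))
}

# even ("mirror") reflection padding, robust to short inputs
reflect_pad <- function(v, n_pad, side = c("left", "right")) {
  side <- match.arg(side)
  n <- length(v)
  if (n == 1L) return(rep(v, n_pad))
  idx <- if (side == "left") {
    1L + abs(seq(-n_pad, -1L)) %% (2L * (n - 1L))
  } else {
    1L + abs(seq(n, n + n_pad - 1L)) %% (2L * (n - 1L))
  }
  idx <- ifelse(idx > n, 2L * n - idx, idx)
  v[idx]
}

#' Enhance R-peaks of an ECG block
#'
#' Computes the modulus of the single-scale continuous wavelet transform of
#' the block: `Y = |x * psi|`, where `psi` is a Mexican-hat kernel tuned to
#' the QRS band. Record ends are handled by mirror padding. The output has
#' the same length as the input and is non-negative; it is the signal the
#' adaptive threshold operates on.
#'
#' @param block numeric vector of raw ECG samples (a block or a whole
#'   record).
#' @param fs sampling rate, Hz.
#' @param params an [ecg_params()] list.
#' @return numeric vector `Y`, same length as `block`, `Y >= 0`.
#' @export
enhance_peaks <- function(block, fs, params = ecg_params()) {
  if (!length(block)) return(numeric())
  w <- ricker_kernel(fs, params$wavelet_scale)
  L <- (length(w) - 1L) / 2L
  padded <- c(reflect_pad(block, L, "left"), block, reflect_pad(block, L, "right"))
  y <- stats::filter(padded, w, sides = 2)
  y <- abs(as.numeric(y[(L + 1L):(L + length(block))]))
  # cancellation dust (a DC block maps to ~1e-17, not 0) must not become
  # "structure" for the adaptive threshold
  y[y < 1e-12 * max(abs(block))] <- 0
  y
}

# -- streaming detection -----------------------------------------------------

new_ecg_state <- function(fs, params) {
  structure(list(fs = fs, kernel = ricker_kernel(fs, params$wavelet_scale),
                 raw = numeric(), y_done = 0L, ath = ath_state_new(),
                 last_peak_time = NA_real_),
            class = "ecg_detector_state")
}

#' @export
print.ecg_detector_state <- function(x, ...) {
  cat(sprintf(paste0("<ecg_detector_state> %d samples seen, noise level %.4g,",
                     " QPD level %.4g, threshold %.4g\n"),
              length(x$raw), x$ath$noise_level, x$ath$qpd_level, x$ath$threshold))
  invisible(x)
}

# compute Y for global 1-based indices a..b (requires raw up to b+L, or flush)
ecg_y_chunk <- function(state, a, b, flush = FALSE) {
  if (b < a) return(numeric())
  w <- state$kernel
  L <- (length(w) - 1L) / 2L
  raw <- state$raw
  left <- reflect_pad(raw, L, "left")
  padded <- if (flush) c(left, raw, reflect_pad(raw, L, "right")) else c(left, raw)
  # padded index of raw[i] is i + L; slice so the kernel support is complete
  slice <- padded[a:(b + 2L * L)]
  y <- stats::filter(slice, w, sides = 2)
  y <- abs(as.numeric(y[(L + 1L):(L + b - a + 1L)]))
  y[y < 1e-12 * max(abs(raw))] <- 0
  y
}

#' Process one raw ECG block of the streaming R-peak detector
#'
#' Blocks are consumed sequentially; a state object carries everything
#' needed across block boundaries (enhancement lag, running noise and
#' signal levels, a candidate still inside its refractory window), so
#' beats split between blocks are detected exactly once and the final
#' candidate set does not depend on where the block boundaries fall.
#' Passing an empty block flushes the detector and emits held candidates.
#'
#' @param block numeric vector of raw ECG samples; `numeric(0)` to flush.
#' @param fs sampling rate, Hz.
#' @param state state from the previous call, or `NULL` to start a record.
#' @param params an [ecg_params()] list.
#' @return `list(candidates = <1-based raw sample indices of confirmed
#'   R-peak candidates>, state = <updated state>)`.
#' @seealso [detect_rpeaks()] for the whole-record wrapper.
#' @export
detect_rpeaks_block <- function(block, fs, state = NULL, params = ecg_params()) {
  if (is.null(state)) state <- new_ecg_state(fs, params)
  stopifnot(inherits(state, "ecg_detector_state"))
  w <- state$kernel
  L <- (length(w) - 1L) / 2L
  flush <- length(block) == 0L
  state$raw <- c(state$raw, as.numeric(block))
  n <- length(state$raw)
  if (n == 0L) return(list(candidates = integer(), state = state))
  hi <- if (flush) n else n - L
  cands <- integer()
  if (hi >= state$y_done + 1L) {
    y <- ecg_y_chunk(state, state$y_done + 1L, hi, flush = flush)
    r <- ath_process(state$ath, y, fs, params)
    state$ath <- r$state
    state$y_done <- hi
    cands <- r$candidates
  }
  if (flush) {
    r <- ath_flush(state$ath, params, fs)
    state$ath <- r$state
    cands <- c(cands, r$candidates)
  }
  if (length(cands)) state$last_peak_time <- (max(cands) - 1L) / fs
  list(candidates = cands, state = state)
}

#' Refine a peak location to sub-sample precision
#'
#' Fits a second-order polynomial through a detected maximum and its two
#' neighbouring samples and returns the time of the fitted vertex:
#' `t = offset + (idx - 1 + delta) / fs` with
#' `delta = 0.5 (y- - y+) / (y- - 2 y0 + y+)`, clamped to
#' \[-0.5, 0.5\] samples. A flat triple (zero denominator) yields
#' `delta = 0`; an index at the array edge is returned unrefined.
#'
#' @param values numeric vector (raw signal).
#' @param idx 1-based index of a local maximum
#'   (`values[idx] >= values[idx +/- 1]`).
#' @param fs sampling rate, Hz.
#' @param offset time of the first sample, seconds.
#' @return refined timestamp, seconds.
#' @examples
#' refine_peak(c(1, 4, 3), 2, fs = 1)  # 0.25 s past the grid sample
#' @export
refine_peak <- function(values, idx, fs, offset = 0) {
  n <- length(values)
  if (idx <= 1L || idx >= n) return(offset + (idx - 1) / fs)
  ym <- values[idx - 1L]; y0 <- values[idx]; yp <- values[idx + 1L]
  if (y0 < ym || y0 < yp)
    stop_invalid("values[idx] is not a local maximum")
  den <- ym - 2 * y0 + yp
  delta <- if (den == 0) 0 else 0.5 * (ym - yp) / den
  delta <- max(-0.5, min(0.5, delta))
  offset + (idx - 1 + delta) / fs
}

# value of the fitted parabola at its vertex
refine_peak_value <- function(values, idx) {
  n <- length(values)
  if (idx <= 1L || idx >= n) return(values[idx])
  ym <- values[idx - 1L]; y0 <- values[idx]; yp <- values[idx + 1L]
  den <- ym - 2 * y0 + yp
  if (den == 0) return(y0)
  delta <- max(-0.5, min(0.5, 0.5 * (ym - yp) / den))
  y0 - 0.25 * (ym - yp) * delta
}

#' Detect R-peaks in an ECG track
#'
#' Full detector: the record is processed in blocks of
#' `params$block_len` seconds through wavelet enhancement and the adaptive
#' threshold ([detect_rpeaks_block()]); each confirmed candidate is then
#' located on the raw ECG (largest deviation within
#' `params$refine_window` of the candidate) and refined to sub-sample
#' precision with [refine_peak()]. Detection is invariant to positive
#' amplitude scaling of the input.
#'
#' @param x a [track()] holding the ECG; `x$fs` must be at least
#'   `params$min_fs`.
#' @param params an [ecg_params()] list.
#' @param block_phase length of the first (shorter) block, seconds, in
#'   `[0, block_len)`; shifts all block boundaries. Exposed to make the
#'   block-segmentation invariance directly testable; results should not
#'   depend on it.
#' @return a [fiducial_series()] named `"R"` with one event per detected
#'   beat (timestamp and fitted amplitude).
#' @examples
#' sim <- gen_ecg(ecg_sim_spec(duration = 20, hr = 70, seed = 1))
#' r <- detect_rpeaks(sim$track)
#' r
#' @export
detect_rpeaks <- function(x, params = ecg_params(), block_phase = 0) {
  stopifnot(is_track(x))
  if (x$fs < params$min_fs)
    stop_invalid("sampling rate ", x$fs, " Hz below the minimum ",
                 params$min_fs, " Hz (resample first)")
  if (!length(x$values))
    return(fiducial_series("R", min_distance = 0))
  bl <- max(1L, round(params$block_len * x$fs))
  n <- length(x$values)
  ph <- if (block_phase > 0) min(max(1L, round(block_phase * x$fs)), n) else 0L
  ends <- sort(unique(c(seq(ph + bl, n, by = bl), if (ph > 0) ph, n)))
  starts <- c(1L, head(ends, -1L) + 1L)
  # warm-up: prime the noise/QPD levels on the opening seconds so the
  # threshold is meaningful from the first sample (levels only; no
  # candidates are emitted and the stream then restarts at sample 1)
  st <- new_ecg_state(x$fs, params)
  st$ath <- ath_prime(st$ath,
                      enhance_peaks(x$values[1:min(n, round(2 * x$fs))],
                                    x$fs, params),
                      x$fs, params)
  cands <- integer()
  for (k in seq_along(starts)) {
    r <- detect_rpeaks_block(x$values[starts[k]:ends[k]], x$fs, st, params)
    st <- r$state
    cands <- c(cands, r$candidates)
  }
  r <- detect_rpeaks_block(numeric(), x$fs, st, params)
  cands <- c(cands, r$candidates)
  if (!length(cands))
    return(fiducial_series("R", min_distance = 0))

  # locate the apex on the raw ECG and refine it
  hw <- max(1L, round(params$refine_window * x$fs))
  t_ref <- numeric(length(cands)); a_ref <- numeric(length(cands))
  med <- stats::median(x$values)   # record-level baseline; sign-robust apex pick
  for (j in seq_along(cands)) {
    i <- cands[j]
    lo <- max(1L, i - hw); hi2 <- min(n, i + hw)
    seg <- x$values[lo:hi2]
    k <- which.max(abs(seg - med))
    sgn <- if (seg[k] >= med) 1 else -1
    idx <- lo + k - 1L
    s <- sgn * x$values
    # the window argmax can sit on the window edge of a slope: climb to
    # the nearest genuine local maximum before fitting the parabola
    while (idx > 1L && s[idx - 1L] > s[idx]) idx <- idx - 1L
    while (idx < n && s[idx + 1L] > s[idx]) idx <- idx + 1L
    t_ref[j] <- refine_peak(s, idx, x$fs, x$offset)
    a_ref[j] <- sgn * refine_peak_value(s, idx)
  }
  o <- order(t_ref)
  t_ref <- t_ref[o]; a_ref <- a_ref[o]
  # refinement (<= 0.5 sample) plus apex relocation can nudge neighbours;
  # keep the larger of any pair that collapsed inside the refractory gap
  keep <- rep(TRUE, length(t_ref))
  last <- 1L
  min_gap <- max(0, params$refractory - 2 * hw / x$fs - 2 / x$fs)
  if (length(t_ref) > 1L) {
    for (j in 2L:length(t_ref)) {
      if (t_ref[j] - t_ref[last] < max(min_gap, 1 / x$fs)) {
        if (abs(a_ref[j]) > abs(a_ref[last])) { keep[last] <- FALSE; last <- j }
        else keep[j] <- FALSE
      } else last <- j
    }
  }
  fiducial_series("R", t = t_ref[keep], amplitude = a_ref[keep],
                  min_distance = 0)
}
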