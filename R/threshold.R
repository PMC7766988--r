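# Adaptive detection threshold shared by the ECG and PPG detectors.
#
# The enhanced, non-negative signal Y is consumed in short blocks. Each
# block updates two running levels:
#   * noise level  — exponential moving average of the per-block standard
#     deviation of Y (keeps the threshold above the noise floor);
#   * signal level — a quasi-peak detector (QPD): a first-order IIR envelope
#     follower with a fast attack when the input exceeds the current level
#     and a slow decay otherwise, so it rides down from the last beat's
#     amplitude towards the next one.
# The block threshold is c * (w_n * noise + w_s * qpd). Candidates are local
# maxima of Y strictly above the threshold; candidates closer than the
# refractory period compete and the larger survives. A candidate close to
# the end of the processed data is held in the state and only emitted once
# the refractory window has elapsed (or at flush), so results do not depend
# on where block boundaries fall.

ath_state_new <- function() {
  list(noise_level = NA_real_, qpd_level = 0,
       prev_val = -Inf, prev2_val = -Inf, prev_idx = NA_integer_,
       pending_idx = NA_integer_, pending_val = NA_real_,
       threshold = 0, n_seen = 0L)
}

ath_coeff <- function(tc, fs) 1 - exp(-1 / (fs * tc))

# Process one chunk of the enhanced signal.
#   y    : non-negative numeric chunk
#   fs   : sampling rate, Hz
#   p    : list with noise_alpha, qpd_attack_tc, qpd_decay_tc, w_n, w_s,
#          threshold_scale, refractory (seconds)
# Returns list(candidates = 0-based global sample indices, state = updated).
ath_process <- function(state, y, fs, p) {
  n <- length(y)
  if (n == 0L) return(list(candidates = integer(), state = state))
  if (any(y < 0)) stop_invalid("enhanced signal must be non-negative")

  # running levels, updated from the whole chunk before scanning it
  sd_b <- if (n > 1L) stats::sd(y) else 0
  state$noise_level <- if (is.na(state$noise_level)) sd_b else
    (1 - p$noise_alpha) * state$noise_level + p$noise_alpha * sd_b
  att <- ath_coeff(p$qpd_attack_tc, fs)
  dec <- ath_coeff(p$qpd_decay_tc, fs)
  q <- state$qpd_level
  for (i in seq_len(n)) {
    a <- if (y[i] > q) att else dec
    q <- q + a * (y[i] - q)
  }
  state$qpd_level <- q
  thr <- p$threshold_scale * (p$w_n * state$noise_level + p$w_s * state$qpd_level)
  state$threshold <- thr

  refr <- max(1L, round(p$refractory * fs))
  cands <- integer()
  idx0 <- state$n_seen                      # y[i] is stream sample idx0 + i (1-based)
  pv <- state$prev_val; p2 <- state$prev2_val; pidx <- state$prev_idx
  pend_i <- state$pending_idx; pend_v <- state$pending_val
  for (i in seq_len(n)) {
    cur <- y[i]
    # was the previous sample a local maximum above threshold?
    if (!is.na(pidx) && pv > thr && pv >= p2 && pv > cur) {
      if (!is.na(pend_i) && (pidx - pend_i) < refr) {
        if (pv > pend_v) { pend_i <- pidx; pend_v <- pv }
      } else {
        if (!is.na(pend_i)) cands <- c(cands, pend_i)
        pend_i <- pidx; pend_v <- pv
      }
    }
    p2 <- pv; pv <- cur; pidx <- idx0 + i
  }
  # emit the held candidate once it is refractory-safe w.r.t. the data end
  if (!is.na(pend_i) && (pidx - pend_i) >= refr) {
    cands <- c(cands, pend_i); pend_i <- NA_integer_; pend_v <- NA_real_
  }
  state$prev_val <- pv; state$prev2_val <- p2; state$prev_idx <- pidx
  state$pending_idx <- pend_i; state$pending_val <- pend_v
  state$n_seen <- state$n_seen + n
  list(candidates = cands, state = state)
}

# Finish a record: resolve the final sample and any held candidate.
ath_flush <- function(state, p, fs) {
  cands <- integer()
  pend_i <- state$pending_idx; pend_v <- state$pending_val
  refr <- max(1L, round(p$refractory * fs))
  # the last sample can be a (boundary) local maximum
  if (!is.na(state$prev_idx) && state$prev_val > state$threshold &&
      state$prev_val >= state$prev2_val) {
    if (!is.na(pend_i) && (state$prev_idx - pend_i) < refr) {
      if (state$prev_val > pend_v) { pend_i <- state$prev_idx; pend_v <- state$prev_val }
    } else {
      if (!is.na(pend_i)) cands <- c(cands, pend_i)
      pend_i <- state$prev_idx
    }
  }
  if (!is.na(pend_i)) cands <- c(cands, pend_i)
  state$pending_idx <- NA_integer_; state$pending_val <- NA_real_
  list(candidates = cands, state = state)
}

# Prime a fresh state's levels from a warm-up stretch of enhanced signal,
# then rewind the stream position so detection restarts at sample 1.
ath_prime <- function(state, y_warm, fs, p) {
  if (length(y_warm)) {
    state <- ath_process(state, y_warm, fs, p)$state
    state$n_seen <- 0L
    state$prev_val <- -Inf; state$prev2_val <- -Inf
    state$prev_idx <- NA_integer_
    state$pending_idx <- NA_integer_; state$pending_val <- NA_real_
  }
  state
}

#' Update the adaptive detection threshold with one enhanced block
#'
#' One step of the threshold recursion used inside both detectors, exposed
#' for inspection and testing: the block's standard deviation feeds an
#' exponential moving average (the noise level), a quasi-peak detector —
#' a first-order IIR with fast attack and slow decay — tracks the signal
#' level, and the threshold is their weighted, scaled sum
#' `c * (w_n * noise + w_s * qpd)`.
#'
#' @param state detector state as returned by this function (or `NULL` for
#'   a fresh state).
#' @param y_block non-negative numeric block of the enhanced signal.
#' @param fs sampling rate, Hz.
#' @param params an [ecg_params()] or [ppg_params()] list (only the
#'   threshold-related fields are used).
#' @return `list(threshold = <numeric>, state = <updated state>)`.
#' @examples
#' p <- ecg_params()
#' s <- NULL
#' for (k in 1:40) {
#'   up <- update_threshold(s, rep(1, 125), fs = 250, params = p)
#'   s <- up$state
#' }
#' up$threshold  # converges to c * w_s * 1 (block sd is zero)
#' @export
update_threshold <- function(state, y_block, fs, params) {
  if (is.null(state)) state <- ath_state_new()
  r <- ath_process(state, y_block, fs, params)
  list(threshold = r$state$threshold, state = r$state)
}
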