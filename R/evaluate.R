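#' Match detected against reference events at a tolerance
#'
#' One-to-one, in-order greedy matching of two sorted timestamp sequences:
#' a detection and a reference are paired when they lie within `tau`
#' seconds of each other, each event is used at most once, and ties go to
#' the earlier detection. For this interval-compatibility structure the
#' greedy sweep attains the maximum possible number of pairs (verified
#' against an exhaustive bipartite-matching oracle in the test suite).
#'
#' @param detected numeric vector of detected timestamps, sorted ascending.
#' @param reference numeric vector of reference timestamps, sorted
#'   ascending.
#' @param tau matching tolerance, seconds (> 0); a pair is allowed when
#'   `|ref - det| <= tau`.
#' @return an object of class `"match_result"`: list with `tp`, `fp`, `fn`
#'   counts, `tau`, and `pairs` (two-column matrix of reference/detected
#'   timestamps).
#' @examples
#' match_events(c(1.00, 1.02), c(1.00), tau = 0.05)  # tp 1, fp 1, fn 0
#' @export
match_events <- function(detected, reference, tau) {
  if (!is.finite(tau) || tau <= 0) stop_invalid("tau must be > 0")
  detected <- as.numeric(detected); reference <- as.numeric(reference)
  if (is.unsorted(detected, strictly = FALSE) ||
      is.unsorted(reference, strictly = FALSE))
    stop_invalid("detected and reference must be sorted ascending")
  i <- 1L; j <- 1L
  nd <- length(detected); nr <- length(reference)
  pr <- numeric(); pd <- numeric()
  while (i <= nd && j <= nr) {
    d <- detected[i]; r <- reference[j]
    if (d < r - tau) {
      i <- i + 1L                      # unmatched detection (FP)
    } else if (r < d - tau) {
      j <- j + 1L                      # unmatched reference (FN)
    } else {
      pr <- c(pr, r); pd <- c(pd, d)   # within tolerance: pair them
      i <- i + 1L; j <- j + 1L
    }
  }
  tp <- length(pr)
  structure(list(tp = tp, fp = nd - tp, fn = nr - tp, tau = tau,
                 pairs = cbind(reference = pr, detected = pd)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> tau = %g s: TP %d, FP %d, FN %d",
              x$tau, x$tp, x$fp, x$fn))
  if (x$tp + x$fp + x$fn > 0)
    cat(sprintf(" | F1 %.4f", f1_score(x)))
  if (x$tp > 0)
    cat(sprintf(", error rate %.4f", error_rate(x)))
  cat("\n")
  invisible(x)
}

#' F1 score of a match result
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`, the harmonic mean of sensitivity and
#' positive predictive value — the standard summary when true negatives
#' are undefined, as for beat detection.
#'
#' @param m a [match_result()][match_events()], or a list with `tp`, `fp`,
#'   `fn` counts.
#' @return F1 as a fraction in \[0, 1\].
#' @export
f1_score <- function(m) {
  if (m$tp + m$fp + m$fn == 0)
    stop_invalid("F1 undefined: no events on either side")
  2 * m$tp / (2 * m$tp + m$fp + m$fn)
}

#' Detection error rate of a match result
#'
#' The ratio of false detections to true positives. By default both error
#' kinds are counted: `(FP + FN) / TP`; `fp_only = TRUE` gives `FP / TP`.
#'
#' @param m a [match_result()][match_events()] or compatible list.
#' @param fp_only count only false positives.
#' @return error rate as a fraction (may exceed 1).
#' @export
error_rate <- function(m, fp_only = FALSE) {
  if (m$tp == 0) stop_invalid("error rate undefined: no true positives")
  (m$fp + if (fp_only) 0 else m$fn) / m$tp
}

#' Evaluate detections at several tolerances
#'
#' @param detected,reference sorted timestamp vectors, seconds.
#' @param taus tolerances in seconds; the defaults 0.050 and 0.125 s are
#'   the two conventions used for beat detectors (about half a normal QRS
#'   width, and half the beat period at the 240 bpm physiological
#'   ceiling).
#' @return a data.frame with one row per tolerance: `tau`, `tp`, `fp`,
#'   `fn`, `f1`, `error_rate` (the latter two `NA` where undefined). `f1`
#'   is non-decreasing in `tau`.
#' @export
evaluate_at_tolerances <- function(detected, reference, taus = c(0.050, 0.125)) {
  if (!length(taus)) stop_invalid("taus must be non-empty")
  rows <- lapply(taus, function(tau) {
    m <- match_events(detected, reference, tau)
    data.frame(tau = tau, tp = m$tp, fp = m$fp, fn = m$fn,
               f1 = if (m$tp + m$fp + m$fn > 0) f1_score(m) else NA_real_,
               error_rate = if (m$tp > 0) error_rate(m) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Read a two-column fiducial CSV (name, timestamp)
#'
#' @param path CSV with columns `name` (or `fiducial`) and `t_seconds`
#'   (or `t`); header required.
#' @param name optional filter: keep only rows with this fiducial name.
#' @return numeric vector of timestamps, sorted ascending.
#' @export
read_fiducial_csv <- function(path, name = NULL) {
  df <- read.csv(path)
  ncol_t <- intersect(c("t_seconds", "t", "timestamp"), names(df))
  ncol_n <- intersect(c("name", "fiducial"), names(df))
  if (!length(ncol_t)) stop_invalid("no timestamp column in ", path)
  if (!is.null(name)) {
    if (!length(ncol_n)) stop_invalid("no name column in ", path)
    df <- df[df[[ncol_n[1]]] == name, , drop = FALSE]
  }
  sort(as.numeric(df[[ncol_t[1]]]))
}
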