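#' Create a fiducial series (instantaneous, zero-duration events)
#'
#' A fiducial series holds ordered timestamped events on one signal —
#' R-peaks, PPG feet, upstrokes and the like. Timestamps are real-valued
#' seconds (sub-sample positions are representable) and must be strictly
#' increasing with consecutive gaps of at least `min_distance`.
#'
#' @param name series name, e.g. `"R"`, `"foot"`.
#' @param t numeric vector of event timestamps, seconds, strictly increasing.
#' @param amplitude numeric vector of event amplitudes (same length as `t`).
#' @param sublabel optional character vector of per-event sub-labels
#'   (e.g. `"ectopic"`); `NA` where unused.
#' @param min_distance minimum allowed gap between consecutive events,
#'   seconds (>= 0). Insertions violating it are rejected.
#' @return An object of class `"fiducial_series"`.
#' @export
fiducial_series <- function(name, t = numeric(), amplitude = numeric(),
                            sublabel = NULL, min_distance = 0) {
  t <- as.numeric(t)
  amplitude <- as.numeric(amplitude)
  if (length(amplitude) == 0L && length(t) > 0L) amplitude <- rep(NA_real_, length(t))
  if (length(amplitude) != length(t))
    stop_invalid("t and amplitude lengths differ")
  if (is.null(sublabel)) sublabel <- rep(NA_character_, length(t))
  sublabel <- as.character(sublabel)
  if (length(sublabel) != length(t)) stop_invalid("sublabel length mismatch")
  if (min_distance < 0) stop_invalid("min_distance must be >= 0")
  if (length(t) > 1L) {
    d <- diff(t)
    if (any(d <= 0)) stop_invalid("timestamps must be strictly increasing")
    if (any(d < min_distance))
      stop_invalid("consecutive timestamps closer than min_distance")
  }
  structure(list(name = as.character(name), t = t, amplitude = amplitude,
                 sublabel = sublabel, min_distance = as.numeric(min_distance)),
            class = "fiducial_series")
}

#' Number of events in a fiducial series
#' @param x a [fiducial_series()].
#' @export
length.fiducial_series <- function(x) length(x$t)

#' @export
print.fiducial_series <- function(x, ...) {
  cat(sprintf("<fiducial_series '%s'> %d events", x$name, length(x$t)))
  if (length(x$t)) cat(sprintf(", t = [%.3f, %.3f] s", x$t[1], x$t[length(x$t)]))
  if (x$min_distance > 0) cat(sprintf(", min gap %.3g s", x$min_distance))
  cat("\n")
  invisible(x)
}

#' @export
summary.fiducial_series <- function(object, ...) {
  print(object)
  if (length(object$t) >= 2L) {
    ibi <- diff(object$t)
    cat(sprintf("  inter-event interval: mean %.3f s (rate %.1f /min), sd %.4f s\n",
                mean(ibi), 60 / mean(ibi), stats::sd(ibi)))
  }
  invisible(object)
}

#' @export
as.data.frame.fiducial_series <- function(x, ...) {
  data.frame(name = rep(x$name, length(x$t)), t = x$t,
             amplitude = x$amplitude, sublabel = x$sublabel,
             stringsAsFactors = FALSE)
}

#' Insert an event into a fiducial series
#'
#' The event is placed in time order. If any existing event lies within
#' `min_distance` of `t` the insertion is rejected and the series returned
#' unchanged; the outcome is reported in the `"accepted"` attribute of the
#' returned series (non-destructive default — no silent replacement).
#'
#' @param series a [fiducial_series()].
#' @param t event timestamp, seconds (finite).
#' @param amplitude event amplitude.
#' @param sublabel optional sub-label.
#' @param replace if `TRUE`, a conflicting existing event (within
#'   `min_distance`) is replaced by the new one instead of blocking it.
#' @return the updated series, with attribute `accepted` (logical).
#' @examples
#' s <- fiducial_series("R", min_distance = 0.2)
#' s <- insert_fiducial(s, 1.0, 0.5)
#' attr(insert_fiducial(s, 1.1, 0.4), "accepted")  # FALSE: too close
#' @export
insert_fiducial <- function(series, t, amplitude = NA_real_,
                            sublabel = NA_character_, replace = FALSE) {
  stopifnot(inherits(series, "fiducial_series"))
  if (!is.finite(t)) stop_invalid("t must be finite")
  conflict <- which(abs(series$t - t) < series$min_distance)
  if (length(conflict) && !replace) {
    attr(series, "accepted") <- FALSE
    return(series)
  }
  if (length(conflict)) {
    series$t <- series$t[-conflict]
    series$amplitude <- series$amplitude[-conflict]
    series$sublabel <- series$sublabel[-conflict]
  }
  if (any(series$t == t)) {  # exact duplicate with min_distance = 0
    attr(series, "accepted") <- FALSE
    return(series)
  }
  pos <- sum(series$t < t)
  series$t <- append(series$t, t, after = pos)
  series$amplitude <- append(series$amplitude, as.numeric(amplitude), after = pos)
  series$sublabel <- append(series$sublabel, as.character(sublabel), after = pos)
  # replacement may still not create a gap below min_distance with neighbours
  if (length(series$t) > 1L && any(diff(series$t) < series$min_distance)) {
    stop_invalid("replacement would violate min_distance with a neighbour")
  }
  attr(series, "accepted") <- TRUE
  series
}

#' Delete the event nearest to a timestamp
#'
#' @param series a [fiducial_series()].
#' @param t timestamp, seconds.
#' @param tolerance only delete if the nearest event is within this many
#'   seconds of `t`; `Inf` always deletes the nearest.
#' @return the updated series, with attribute `accepted` (logical).
#' @export
delete_fiducial <- function(series, t, tolerance = Inf) {
  stopifnot(inherits(series, "fiducial_series"))
  if (!length(series$t)) {
    attr(series, "accepted") <- FALSE
    return(series)
  }
  i <- which.min(abs(series$t - t))
  if (abs(series$t[i] - t) > tolerance) {
    attr(series, "accepted") <- FALSE
    return(series)
  }
  series$t <- series$t[-i]
  series$amplitude <- series$amplitude[-i]
  series$sublabel <- series$sublabel[-i]
  attr(series, "accepted") <- TRUE
  series
}

#' Inter-beat intervals of a fiducial series
#'
#' Interval `i` is `t[i+1] - t[i]`, reported at the later timestamp, the
#' convention that makes missed or spurious beats show up as spikes or dips
#' when the intervals are plotted over the signal.
#'
#' @param series a [fiducial_series()].
#' @return a data.frame with columns `t` (seconds, the later event of each
#'   pair) and `interval` (seconds); `n - 1` rows, empty for fewer than two
#'   events.
#' @examples
#' s <- fiducial_series("R", t = c(1.0, 2.0, 3.1))
#' interbeat_intervals(s)
#' @export
interbeat_intervals <- function(series) {
  stopifnot(inherits(series, "fiducial_series"))
  n <- length(series$t)
  if (n < 2L)
    return(data.frame(t = numeric(), interval = numeric()))
  data.frame(t = series$t[-1], interval = diff(series$t))
}
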