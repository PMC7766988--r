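#' Create a track (one uniformly sampled signal)
#'
#' A track is the basic signal container: an ordered vector of amplitudes
#' sampled at a fixed rate, starting at a time offset. The time of sample
#' `i` (0-based) is `offset + i / fs` seconds.
#'
#' @param values numeric vector of finite amplitudes.
#' @param fs sampling rate in Hz (> 0).
#' @param name track name.
#' @param offset start time of the first sample, seconds.
#' @param units amplitude unit label (free text, e.g. "mV").
#' @return An object of class `"track"`.
#' @examples
#' tr <- track(sin(2 * pi * (0:999) / 100), fs = 100, name = "demo")
#' tr
#' @export
track <- function(values, fs, name = "signal", offset = 0, units = "") {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_invalid("fs must be a single positive number")
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop_invalid("track values must be finite")
  structure(list(name = as.character(name), fs = as.numeric(fs),
                 offset = as.numeric(offset), values = values,
                 units = as.character(units)),
            class = "track")
}

is_track <- function(x) inherits(x, "track")

#' Sample times of a track
#'
#' @param x a [track()].
#' @return numeric vector of timestamps in seconds, one per sample.
#' @export
track_times <- function(x) {
  stopifnot(is_track(x))
  x$offset + (seq_along(x$values) - 1) / x$fs
}

#' Track duration in seconds
#' @param x a [track()].
#' @return length of the sampled span, `n / fs`, in seconds.
#' @export
track_duration <- function(x) {
  stopifnot(is_track(x))
  length(x$values) / x$fs
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track '%s'> %d samples @ %g Hz, t = [%.3f, %.3f] s%s\n",
              x$name, length(x$values), x$fs, x$offset,
              x$offset + max(length(x$values) - 1, 0) / x$fs,
              if (nzchar(x$units)) paste0(", units: ", x$units) else ""))
  invisible(x)
}

#' @export
summary.track <- function(object, ...) {
  v <- object$values
  cat(sprintf("<track '%s'>\n  fs      : %g Hz\n  samples : %d (%.2f s)\n",
              object$name, object$fs, length(v), track_duration(object)))
  cat(sprintf("  range   : [%.4g, %.4g]%s\n", min(v), max(v),
              if (nzchar(object$units)) paste0(" ", object$units) else ""))
  invisible(object)
}

#' Plot a track, optionally with fiducial markers
#'
#' @param x a [track()].
#' @param fiducials optional [fiducial_series()] or named list of them to
#'   overlay as points.
#' @param xlim optional time range (seconds).
#' @param ... passed to [graphics::plot()].
#' @export
plot.track <- function(x, fiducials = NULL, xlim = NULL, ...) {
  t <- track_times(x)
  keep <- if (is.null(xlim)) TRUE else t >= xlim[1] & t <= xlim[2]
  plot(t[keep], x$values[keep], type = "l", xlab = "time [s]",
       ylab = if (nzchar(x$units)) x$units else "amplitude",
       main = x$name, ...)
  if (!is.null(fiducials)) {
    if (inherits(fiducials, "fiducial_series")) fiducials <- list(fiducials)
    cols <- seq_along(fiducials) + 1
    for (i in seq_along(fiducials)) {
      f <- fiducials[[i]]
      points(f$t, f$amplitude, col = cols[i], pch = 19, cex = 0.7)
    }
    legend("topright", legend = vapply(fiducials, `[[`, "", "name"),
           col = cols, pch = 19, bty = "n")
  }
  invisible(x)
}

#' Derive a new track from an existing one
#'
#' Supports the two derivations used when annotating: the time derivative
#' (central differences, one-sided at the ends, scaled to units/second) and
#' a zero-phase Butterworth low-pass.
#'
#' @param x a [track()].
#' @param kind `"derivative"` or `"lowpass"`.
#' @param cutoff_hz low-pass cutoff in Hz; required for `kind = "lowpass"`,
#'   must be below the Nyquist frequency `fs/2`.
#' @param order Butterworth order for the low-pass (applied forward and
#'   backward, so the effective attenuation is doubled).
#' @return A new [track()] with the same `fs` and `offset`.
#' @examples
#' tr <- track(c(0, 1, 2, 3), fs = 1)
#' derive_track(tr, "derivative")$values  # 1 1 1 1
#' @export
derive_track <- function(x, kind = c("derivative", "lowpass"),
                         cutoff_hz = NULL, order = 4) {
  stopifnot(is_track(x))
  kind <- match.arg(kind)
  if (length(x$values) == 0L) stop_invalid("cannot derive from an empty track")
  if (kind == "derivative") {
    track(central_diff(x$values) * x$fs, fs = x$fs,
          name = paste0("d", x$name), offset = x$offset,
          units = if (nzchar(x$units)) paste0(x$units, "/s") else "1/s")
  } else {
    if (is.null(cutoff_hz) || !is.finite(cutoff_hz) || cutoff_hz <= 0)
      stop_invalid("lowpass requires a positive cutoff_hz")
    if (cutoff_hz >= x$fs / 2)
      stop_invalid("cutoff_hz must be below the Nyquist frequency fs/2")
    track(lowpass_zerophase(x$values, x$fs, cutoff_hz, order), fs = x$fs,
          name = sprintf("%s_lp%g", x$name, cutoff_hz), offset = x$offset,
          units = x$units)
  }
}

# central differences; forward/backward at the ends; returns same length
central_diff <- function(v) {
  n <- length(v)
  if (n == 1L) return(0)
  d <- numeric(n)
  d[1] <- v[2] - v[1]
  d[n] <- v[n] - v[n - 1]
  if (n > 2L) d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2
  d
}

# zero-phase Butterworth low-pass with reflective edge padding
lowpass_zerophase <- function(v, fs, cutoff_hz, order = 4) {
  n <- length(v)
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  # generous padding: filtfilt starts from zero state, so the pad must be
  # long enough for the step transient to die out before the data begin
  pad <- min(n - 1L, max(ceiling(fs), ceiling(fs / cutoff_hz) * 10L))
  if (pad > 0) {
    # odd reflection keeps the signal and its first derivative continuous
    left <- 2 * v[1] - v[seq(pad + 1L, 2L, -1L)]
    right <- 2 * v[n] - v[seq(n - 1L, n - pad, -1L)]
    out <- signal::filtfilt(bf, c(left, v, right))
    out[(pad + 1L):(pad + n)]
  } else {
    signal::filtfilt(bf, v)
  }
}

#' Pin a timestamp to the nearest signal extremum
#'
#' Moves an annotator-supplied timestamp to the local maximum (`"peak"`),
#' local minimum (`"valley"`), or whichever of the two is closer to the
#' click (`"nearest"`) within a window centred on `t`. The returned time is
#' that of the winning sample; no sub-sample refinement is applied here.
#'
#' @param x a [track()].
#' @param t clicked timestamp, seconds; must lie within the track span.
#' @param window full window width in seconds (> 0); clipped to the track.
#' @param mode `"peak"`, `"valley"` or `"nearest"`.
#' @return timestamp in seconds of the selected extremum sample.
#' @export
pin_to_extremum <- function(x, t, window, mode = c("peak", "valley", "nearest")) {
  stopifnot(is_track(x))
  mode <- match.arg(mode)
  if (!is.finite(t)) stop_invalid("t must be finite")
  if (!is.finite(window) || window <= 0) stop_invalid("window must be > 0")
  tt <- track_times(x)
  if (t < tt[1] || t > tt[length(tt)])
    stop_invalid("t lies outside the track span")
  lo <- max(1L, ceiling((t - window / 2 - x$offset) * x$fs) + 1L)
  hi <- min(length(x$values), floor((t + window / 2 - x$offset) * x$fs) + 1L)
  idx <- lo:hi
  i_max <- idx[which.max(x$values[idx])]
  i_min <- idx[which.min(x$values[idx])]
  i <- switch(mode,
    peak = i_max,
    valley = i_min,
    nearest = if (abs(tt[i_max] - t) <= abs(tt[i_min] - t)) i_max else i_min)
  tt[i]
}

#' Read a signal column from a delimited text file into a track
#'
#' @param path CSV/TSV file; the delimiter is inferred from the extension
#'   (".tsv" → tab, otherwise comma).
#' @param fs sampling rate declared for the file, Hz.
#' @param column column name or 1-based index holding the samples.
#' @param name track name; defaults to the column name.
#' @param offset start time in seconds.
#' @param units unit label.
#' @param header whether the file has a header row.
#' @return a [track()].
#' @export
read_signal_csv <- function(path, fs, column = 1L, name = NULL,
                            offset = 0, units = "", header = TRUE) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, header = header)
  if (is.character(column)) {
    if (!column %in% names(df))
      stop_invalid("column '", column, "' not found in ", path)
  } else if (column < 1L || column > ncol(df)) {
    stop_invalid("column index ", column, " out of range in ", path)
  }
  v <- df[[column]]
  if (is.null(name))
    name <- if (is.character(column)) column else names(df)[column]
  track(v, fs = fs, name = name, offset = offset, units = units)
}
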