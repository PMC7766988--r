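#' Create a partition set (named, variable-duration events)
#'
#' Partitions label segments of explicit interest — artefacts,
#' interventions, activities. Each has a name and a `[start, end)` span;
#' partitions within one set may not overlap, but touching endpoints are
#' allowed and names may repeat.
#'
#' @param name,start,end equal-length vectors describing initial partitions
#'   (may be empty).
#' @return An object of class `"partition_set"`.
#' @export
partition_set <- function(name = character(), start = numeric(), end = numeric()) {
  stopifnot(length(name) == length(start), length(start) == length(end))
  ps <- structure(list(name = as.character(name), start = as.numeric(start),
                       end = as.numeric(end)), class = "partition_set")
  if (length(start)) {
    if (any(start >= end)) stop_invalid("every partition needs start < end")
    o <- order(start)
    ps$name <- ps$name[o]; ps$start <- ps$start[o]; ps$end <- ps$end[o]
    if (length(start) > 1L && any(ps$start[-1] < ps$end[-length(end)]))
      stop_invalid("partitions overlap")
  }
  ps
}

#' @export
print.partition_set <- function(x, ...) {
  cat(sprintf("<partition_set> %d partition(s)\n", length(x$start)))
  if (length(x$start))
    for (i in seq_along(x$start))
      cat(sprintf("  %-12s [%.3f, %.3f) s\n", x$name[i], x$start[i], x$end[i]))
  invisible(x)
}

#' @export
as.data.frame.partition_set <- function(x, ...) {
  data.frame(name = x$name, start = x$start, end = x$end,
             stringsAsFactors = FALSE)
}

#' Add a partition to a set
#'
#' Inserted only if it does not overlap an existing partition (touching
#' endpoints are fine); otherwise the set is returned unchanged with
#' attribute `accepted = FALSE`.
#'
#' @param set a [partition_set()].
#' @param name partition name (free text, repeats allowed).
#' @param start,end span in seconds, `start < end`.
#' @return the updated set with attribute `accepted` (logical).
#' @export
add_partition <- function(set, name, start, end) {
  stopifnot(inherits(set, "partition_set"))
  if (!is.finite(start) || !is.finite(end) || start >= end)
    stop_invalid("start must be < end")
  overlap <- any(start < set$end & end > set$start)
  if (overlap) {
    attr(set, "accepted") <- FALSE
    return(set)
  }
  pos <- sum(set$start < start)
  set$name <- append(set$name, as.character(name), after = pos)
  set$start <- append(set$start, start, after = pos)
  set$end <- append(set$end, end, after = pos)
  attr(set, "accepted") <- TRUE
  set
}

#' Create an epoch grid (fixed-length labelled windows)
#'
#' Epoch `k` (0-based) covers the half-open window
#' `[k * epoch_length, (k+1) * epoch_length)` relative to the track start;
#' a trailing partial window is still labelable. Labels are drawn from a
#' fixed set (e.g. signal-quality codes) and may be left unset (`NA`).
#'
#' @param n_epochs number of windows.
#' @param epoch_length window length in seconds (> 0), default 10.
#' @param label_set allowed labels (character).
#' @param labels optional initial labels (`NA` = unset).
#' @return An object of class `"epoch_grid"`.
#' @export
epoch_grid <- function(n_epochs, epoch_length = 10,
                       label_set = c("Q0", "Q1", "Q2"), labels = NULL) {
  if (epoch_length <= 0) stop_invalid("epoch_length must be > 0")
  if (!length(label_set)) stop_invalid("label_set must be non-empty")
  if (is.null(labels)) labels <- rep(NA_character_, n_epochs)
  labels <- as.character(labels)
  if (length(labels) != n_epochs) stop_invalid("labels length != n_epochs")
  bad <- !is.na(labels) & !(labels %in% label_set)
  if (any(bad)) stop_invalid("labels outside label_set: ",
                             paste(unique(labels[bad]), collapse = ", "))
  structure(list(epoch_length = as.numeric(epoch_length),
                 label_set = as.character(label_set), labels = labels),
            class = "epoch_grid")
}

#' @export
print.epoch_grid <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("<epoch_grid> %d x %g s epochs, labels {%s}, %d assigned\n",
              n, x$epoch_length, paste(x$label_set, collapse = ", "),
              sum(!is.na(x$labels))))
  invisible(x)
}

#' Assign a label to one epoch
#'
#' @param grid an [epoch_grid()].
#' @param k 0-based epoch index.
#' @param label a member of the grid's label set, or `NA` to unset.
#' @return the updated grid.
#' @export
set_epoch_label <- function(grid, k, label) {
  stopifnot(inherits(grid, "epoch_grid"))
  if (k < 0 || k >= length(grid$labels)) stop_invalid("epoch index out of range")
  if (!is.na(label) && !(label %in% grid$label_set))
    stop_invalid("label '", label, "' not in label_set")
  grid$labels[k + 1L] <- as.character(label)
  grid
}

#' Epoch index covering a timestamp
#'
#' @param grid an [epoch_grid()].
#' @param t time in seconds relative to the track start.
#' @return 0-based epoch index (`NA` outside the grid).
#' @export
epoch_index <- function(grid, t) {
  stopifnot(inherits(grid, "epoch_grid"))
  k <- floor(t / grid$epoch_length)
  k[k < 0 | k >= length(grid$labels)] <- NA
  as.integer(k)
}

#' Segment a track into fixed-length epochs
#'
#' Builds an unlabelled epoch grid covering the whole track:
#' `ceiling(duration / epoch_length)` windows, the last possibly partial.
#'
#' @param x a [track()].
#' @param epoch_length window length in seconds, default 10 (the usual
#'   signal-quality annotation granularity).
#' @param label_set allowed labels.
#' @return an [epoch_grid()] with all labels unset.
#' @examples
#' tr <- track(numeric(65 * 100), fs = 100)
#' segment_epochs(tr)  # 7 epochs: six full + one 5-s remainder
#' @export
segment_epochs <- function(x, epoch_length = 10, label_set = c("Q0", "Q1", "Q2")) {
  stopifnot(is_track(x))
  if (epoch_length <= 0) stop_invalid("epoch_length must be > 0")
  n <- ceiling(track_duration(x) / epoch_length)
  epoch_grid(n, epoch_length = epoch_length, label_set = label_set)
}
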