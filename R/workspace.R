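#' Create an annotation workspace
#'
#' A workspace bundles everything belonging to one record: the signal
#' tracks, any number of fiducial series (each bound to a track), a
#' partition set, an epoch grid, and free-form metadata. It is the unit
#' that [save_workspace()] persists and [load_workspace()] restores for
#' re-editing.
#'
#' @param tracks named list of [track()] objects (names must match the
#'   tracks' own names).
#' @param fiducials named list of [fiducial_series()]; each element must
#'   carry a `"track"` attribute naming an existing track (set
#'   automatically by [ws_add_fiducials()], or pass `track_binding`).
#' @param partitions a [partition_set()].
#' @param epochs an [epoch_grid()] or `NULL`.
#' @param track_binding named character vector mapping fiducial-series
#'   name to track name (alternative to per-series attributes).
#' @param meta named list of scalar metadata (record id, creator, ...).
#' @return An object of class `"workspace"`.
#' @export
workspace <- function(tracks = list(), fiducials = list(),
                      partitions = partition_set(), epochs = NULL,
                      track_binding = NULL, meta = list()) {
  if (length(tracks)) {
    if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
      names(tracks) <- vapply(tracks, `[[`, "", "name")
    stopifnot(all(vapply(tracks, is_track, TRUE)))
  }
  if (length(fiducials)) {
    if (is.null(names(fiducials)) || any(!nzchar(names(fiducials))))
      names(fiducials) <- vapply(fiducials, `[[`, "", "name")
    stopifnot(all(vapply(fiducials, inherits, TRUE, "fiducial_series")))
    for (nm in names(fiducials)) {
      bind <- attr(fiducials[[nm]], "track")
      if (!is.null(track_binding) && nm %in% names(track_binding))
        bind <- track_binding[[nm]]
      if (is.null(bind)) bind <- if (length(tracks)) names(tracks)[1] else ""
      if (length(tracks) && !bind %in% names(tracks))
        stop_invalid("fiducial series '", nm, "' bound to unknown track '",
                     bind, "'")
      attr(fiducials[[nm]], "track") <- bind
    }
  }
  stopifnot(inherits(partitions, "partition_set"))
  if (!is.null(epochs)) stopifnot(inherits(epochs, "epoch_grid"))
  meta <- utils::modifyList(
    list(record_id = "", creator = "", created_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         tool_version = as.character(utils::packageVersion("beatkit"))),
    meta)
  structure(list(tracks = tracks, fiducials = fiducials,
                 partitions = partitions, epochs = epochs, meta = meta),
            class = "workspace")
}

#' Add a detector's fiducial output to a workspace
#'
#' @param ws a [workspace()].
#' @param series a [fiducial_series()] or a named list of them.
#' @param track name of the track the series belong to.
#' @return the updated workspace.
#' @export
ws_add_fiducials <- function(ws, series, track) {
  stopifnot(inherits(ws, "workspace"))
  if (inherits(series, "fiducial_series")) series <- list(series)
  for (s in series) {
    attr(s, "track") <- track
    ws$fiducials[[s$name]] <- s
  }
  workspace(ws$tracks, ws$fiducials, ws$partitions, ws$epochs, meta = ws$meta)
}

#' @export
print.workspace <- function(x, ...) {
  cat(sprintf("<workspace '%s'>\n", x$meta$record_id))
  cat(sprintf("  tracks     : %s\n",
              if (length(x$tracks)) paste(names(x$tracks), collapse = ", ") else "(none)"))
  cat(sprintf("  fiducials  : %s\n",
              if (length(x$fiducials))
                paste(sprintf("%s(%d)", names(x$fiducials),
                              vapply(x$fiducials, function(f) length(f$t), 0L)),
                      collapse = ", ") else "(none)"))
  cat(sprintf("  partitions : %d\n", length(x$partitions$start)))
  cat(sprintf("  epochs     : %s\n",
              if (is.null(x$epochs)) "(none)" else
                sprintf("%d x %g s", length(x$epochs$labels), x$epochs$epoch_length)))
  invisible(x)
}

WS_SCHEMA_VERSION <- "1.0"

h5_attr <- function(path, obj, name, value) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  oid <- rhdf5::H5Oopen(fid, obj)
  on.exit(rhdf5::H5Oclose(oid), add = TRUE, after = FALSE)
  rhdf5::h5writeAttribute(value, oid, name)
}

#' Save a workspace to an HDF5 file
#'
#' Layout (this package's documented schema, readable with any generic
#' HDF5 tool):
#' \preformatted{
#' /meta                 attrs: record_id, creator, created_at,
#'                              tool_version, schema_version
#' /tracks/<name>        dataset "values"; attrs fs, offset, units
#' /annotations/<name>   datasets "t", "amplitude", "sublabel";
#'                       attrs track, min_distance
#' /partitions           datasets "name", "start", "end"
#' /epochs               dataset "labels" ("" = unset);
#'                       attrs epoch_length, label_set
#' }
#' Floating-point data are stored as 64-bit doubles, so a load reproduces
#' every timestamp and amplitude exactly.
#'
#' @param ws a [workspace()].
#' @param path output file path (overwritten if present).
#' @return `invisible(path)`.
#' @export
save_workspace <- function(ws, path) {
  stopifnot(inherits(ws, "workspace"))
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    stop("cannot write workspace: directory not writable: ", dir)
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "meta")
  for (nm in names(ws$meta)) h5_attr(path, "meta", nm, as.character(ws$meta[[nm]]))
  h5_attr(path, "meta", "schema_version", WS_SCHEMA_VERSION)

  rhdf5::h5createGroup(path, "tracks")
  for (nm in names(ws$tracks)) {
    tr <- ws$tracks[[nm]]
    g <- paste0("tracks/", nm)
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(tr$values, path, paste0(g, "/values"))
    h5_attr(path, g, "fs", tr$fs)
    h5_attr(path, g, "offset", tr$offset)
    h5_attr(path, g, "units", tr$units)
  }

  rhdf5::h5createGroup(path, "annotations")
  for (nm in names(ws$fiducials)) {
    f <- ws$fiducials[[nm]]
    g <- paste0("annotations/", nm)
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(f$t, path, paste0(g, "/t"))
    rhdf5::h5write(f$amplitude, path, paste0(g, "/amplitude"))
    sub <- f$sublabel
    sub[is.na(sub)] <- ""
    rhdf5::h5write(sub, path, paste0(g, "/sublabel"))
    h5_attr(path, g, "track", attr(f, "track") %||% "")
    h5_attr(path, g, "min_distance", f$min_distance)
  }

  rhdf5::h5createGroup(path, "partitions")
  rhdf5::h5write(ws$partitions$name, path, "partitions/name")
  rhdf5::h5write(ws$partitions$start, path, "partitions/start")
  rhdf5::h5write(ws$partitions$end, path, "partitions/end")

  if (!is.null(ws$epochs)) {
    rhdf5::h5createGroup(path, "epochs")
    lab <- ws$epochs$labels
    lab[is.na(lab)] <- ""
    rhdf5::h5write(lab, path, "epochs/labels")
    h5_attr(path, "epochs", "epoch_length", ws$epochs$epoch_length)
    h5_attr(path, "epochs", "label_set", ws$epochs$label_set)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

h5_read_attrs <- function(path, obj) rhdf5::h5readAttributes(path, obj)

ws_schema_error <- function(what) {
  stop("workspace schema error: missing ", what, call. = FALSE)
}

#' Load a workspace from an HDF5 file
#'
#' Inverse of [save_workspace()]; rejects files written under a newer
#' major schema version.
#'
#' @param path HDF5 file produced by [save_workspace()].
#' @return a [workspace()].
#' @export
load_workspace <- function(path) {
  if (!file.exists(path)) stop("no such workspace file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  have <- function(g) g %in% paste0(sub("^/$", "", ls$group), "/", ls$name) |
    g %in% paste0(ls$group, "/", ls$name)
  top <- ls$name[ls$group == "/"]
  for (g in c("meta", "tracks", "annotations", "partitions"))
    if (!g %in% top) ws_schema_error(paste0("group /", g))
  meta <- h5_read_attrs(path, "meta")
  sv <- meta$schema_version %||% ws_schema_error("attribute schema_version")
  if (as.integer(strsplit(as.character(sv), "[.]")[[1]][1]) >
      as.integer(strsplit(WS_SCHEMA_VERSION, "[.]")[[1]][1]))
    stop("workspace written by a newer schema (", sv,
         "); this build reads up to ", WS_SCHEMA_VERSION, call. = FALSE)
  meta$schema_version <- NULL

  tracks <- list()
  for (nm in ls$name[ls$group == "/tracks" & ls$otype == "H5I_GROUP"]) {
    at <- h5_read_attrs(path, paste0("tracks/", nm))
    if (is.null(at$fs)) ws_schema_error(paste0("attribute fs on track ", nm))
    tracks[[nm]] <- track(as.numeric(rhdf5::h5read(path, paste0("tracks/", nm, "/values"))),
                          fs = as.numeric(at$fs), name = nm,
                          offset = as.numeric(at$offset %||% 0),
                          units = as.character(at$units %||% ""))
  }
  fids <- list()
  for (nm in ls$name[ls$group == "/annotations" & ls$otype == "H5I_GROUP"]) {
    g <- paste0("annotations/", nm)
    at <- h5_read_attrs(path, g)
    sub <- as.character(rhdf5::h5read(path, paste0(g, "/sublabel")))
    sub[sub == ""] <- NA_character_
    f <- fiducial_series(nm, t = as.numeric(rhdf5::h5read(path, paste0(g, "/t"))),
                         amplitude = as.numeric(rhdf5::h5read(path, paste0(g, "/amplitude"))),
                         sublabel = sub,
                         min_distance = as.numeric(at$min_distance %||% 0))
    attr(f, "track") <- as.character(at$track %||% "")
    fids[[nm]] <- f
  }
  parts <- partition_set(as.character(rhdf5::h5read(path, "partitions/name")),
                         as.numeric(rhdf5::h5read(path, "partitions/start")),
                         as.numeric(rhdf5::h5read(path, "partitions/end")))
  epochs <- NULL
  if ("epochs" %in% top) {
    at <- h5_read_attrs(path, "epochs")
    lab <- as.character(rhdf5::h5read(path, "epochs/labels"))
    lab[lab == ""] <- NA_character_
    epochs <- epoch_grid(length(lab),
                         epoch_length = as.numeric(at$epoch_length %||%
                                                     ws_schema_error("epochs/epoch_length")),
                         label_set = as.character(at$label_set),
                         labels = lab)
  }
  ws <- workspace(tracks, fids, parts, epochs, meta = lapply(meta, as.character))
  ws
}
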