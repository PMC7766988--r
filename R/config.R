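#' Load and validate a dataset configuration file
#'
#' The configuration is a declarative YAML file a data manager writes once
#' per dataset. It names the source of the records, how file columns map
#' to tracks, which detectors to run, and the annotation and epoch
#' settings offered to annotators. All fields except the source
#' specification have defaults; unknown keys trigger a warning (likely
#' typos), a missing source a hard error.
#'
#' Recognised top-level keys and their defaults:
#' \preformatted{
#' source:                        # MANDATORY
#'   dir: <path>                  # folder with record files
#'   filename_template: "*.csv"   # glob selecting records
#' output_dir: <source$dir>
#' tracks:                        # at least one
#'   - {name: ecg, column: 1, fs: <required>, units: ""}
#' detectors:
#'   ecg: {run: false, params: {}}    # params override ecg_params()
#'   ppg: {run: false, params: {}}
#' annotation:
#'   fiducial_names: ["R"]
#'   min_distance: 0.2
#'   pin_mode: "peak"                 # peak | valley | nearest
#'   pin_window: 0.1
#' epochs:
#'   length: 10
#'   labels: ["Q0", "Q1", "Q2"]
#' }
#'
#' @param path YAML configuration file.
#' @return a fully resolved list of class `"db_config"`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("source", "output_dir", "tracks", "detectors", "annotation",
             "epochs")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(raw$source) || is.null(raw$source$dir))
    stop("config error: 'source' (with 'dir') is mandatory and has no default",
         call. = FALSE)
  defaults <- list(
    source = list(dir = raw$source$dir, filename_template = "*.csv"),
    output_dir = raw$source$dir,
    tracks = list(),
    detectors = list(ecg = list(run = FALSE, params = list()),
                     ppg = list(run = FALSE, params = list())),
    annotation = list(fiducial_names = "R", min_distance = 0.2,
                      pin_mode = "peak", pin_window = 0.1),
    epochs = list(length = 10, labels = c("Q0", "Q1", "Q2")))
  cfg <- utils::modifyList(defaults, raw)
  # tracks is an unnamed sequence, which modifyList would not merge
  if (!is.null(raw$tracks)) cfg$tracks <- raw$tracks
  if (!length(cfg$tracks))
    stop("config error: at least one track mapping is required", call. = FALSE)
  for (i in seq_along(cfg$tracks)) {
    tr <- cfg$tracks[[i]]
    if (is.null(tr$fs)) stop("config error: track ", i, " has no fs", call. = FALSE)
    cfg$tracks[[i]] <- utils::modifyList(
      list(name = paste0("track", i), column = 1L, units = ""), tr)
  }
  if (!cfg$annotation$pin_mode %in% c("peak", "valley", "nearest"))
    stop("config error: pin_mode must be peak, valley or nearest", call. = FALSE)
  if (cfg$epochs$length <= 0 || !length(cfg$epochs$labels))
    stop("config error: epochs need positive length and a non-empty label set",
         call. = FALSE)
  structure(cfg, class = "db_config")
}

#' Load one record's tracks as described by a configuration
#'
#' @param cfg a [load_config()] result.
#' @param path the record file (CSV/TSV); columns are mapped per
#'   `cfg$tracks`. A track referencing an absent column is a hard error.
#' @return named list of [track()]s.
#' @export
load_record <- function(cfg, path) {
  stopifnot(inherits(cfg, "db_config"))
  out <- list()
  for (tr in cfg$tracks) {
    out[[tr$name]] <- read_signal_csv(path, fs = tr$fs, column = tr$column,
                                      name = tr$name, units = tr$units)
  }
  out
}
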