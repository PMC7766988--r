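# Readers for the waveform-database (WFDB/MIT) record format, so that
# public beat-annotated databases can be fed to the evaluation harness
# directly. Only the pieces needed for that are implemented: header files,
# signal formats 212 and 16, and binary annotation files. No writer is
# provided and none of the extended header syntax is interpreted.

WFDB_SYMBOLS <- c(
  "1" = "N", "2" = "L", "3" = "R", "4" = "a", "5" = "V", "6" = "F",
  "7" = "J", "8" = "A", "9" = "S", "10" = "E", "11" = "j", "12" = "/",
  "13" = "Q", "14" = "~", "16" = "|", "18" = "s", "19" = "T", "20" = "*",
  "21" = "D", "22" = "\"", "23" = "=", "24" = "p", "25" = "B", "26" = "^",
  "27" = "t", "28" = "+", "29" = "u", "30" = "?", "31" = "!", "32" = "[",
  "33" = "]", "34" = "e", "35" = "n", "36" = "@", "37" = "x", "38" = "f",
  "39" = "(", "40" = ")", "41" = "r")

# annotation codes carrying beat onsets (used by the default filter)
WFDB_BEAT_CODES <- c(1:13, 25, 34, 35, 38, 41)

#' Read a WFDB header (.hea) file
#'
#' @param path path to the `.hea` file.
#' @return list with `record`, `n_sig`, `fs`, `n_samp` and a data.frame
#'   `signals` (file, format, gain, baseline, units, description).
#' @export
read_wfdb_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n_sig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*", "", top[3])) else 250
  n_samp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig <- lapply(seq_len(n_sig), function(j) {
    f <- strsplit(trimws(lines[j + 1L]), "\\s+")[[1]]
    gain_spec <- if (length(f) >= 3) f[3] else "200"
    units <- sub("^[^/]*/?", "", gain_spec)
    gb <- sub("/.*", "", gain_spec)
    baseline <- if (grepl("\\(", gb)) as.numeric(sub(".*\\((-?[0-9]+)\\).*", "\\1", gb)) else NA
    gain <- as.numeric(sub("\\(.*", "", gb))
    if (gain == 0) gain <- 200
    adc_zero <- if (length(f) >= 5) as.numeric(f[5]) else 0
    data.frame(file = f[1], format = as.integer(sub("x.*|:.*|\\+.*", "", f[2])),
               gain = gain, baseline = if (is.na(baseline)) adc_zero else baseline,
               units = if (nzchar(units)) units else "mV",
               description = if (length(f) >= 9) paste(f[9:length(f)], collapse = " ")
                             else paste0("sig", j),
               stringsAsFactors = FALSE)
  })
  list(record = top[1], n_sig = n_sig, fs = fs, n_samp = n_samp,
       signals = do.call(rbind, sig))
}

# unpack format-212 bytes: two 12-bit two's-complement samples per 3 bytes
unpack_212 <- function(raw, n_samples) {
  b <- as.integer(raw)
  n_tri <- length(b) %/% 3L
  b1 <- b[seq(1L, by = 3L, length.out = n_tri)]
  b2 <- b[seq(2L, by = 3L, length.out = n_tri)]
  b3 <- b[seq(3L, by = 3L, length.out = n_tri)]
  s1 <- bitwAnd(b2, 15L) * 256L + b1
  s2 <- bitwAnd(bitwShiftR(b2, 4L), 15L) * 256L + b3
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  out <- as.vector(rbind(s1, s2))
  out[seq_len(min(n_samples, length(out)))]
}

#' Read a WFDB signal record into tracks
#'
#' Supports formats 212 (paired 12-bit samples) and 16 (little-endian
#' 16-bit). Amplitudes are converted to physical units via
#' `(adc - baseline) / gain`.
#'
#' @param header_path path to the `.hea` file; the signal file named in it
#'   is read from the same directory.
#' @return named list of [track()]s, one per signal.
#' @export
read_wfdb_record <- function(header_path) {
  h <- read_wfdb_header(header_path)
  dir <- dirname(header_path)
  tracks <- list()
  for (file in unique(h$signals$file)) {
    rows <- which(h$signals$file == file)
    fmt <- h$signals$format[rows[1]]
    ns <- length(rows)
    raw <- readBin(file.path(dir, file), "raw",
                   n = file.info(file.path(dir, file))$size)
    total <- if (is.na(h$n_samp)) NA_integer_ else h$n_samp * ns
    adc <- switch(as.character(fmt),
      "212" = unpack_212(raw, if (is.na(total)) (length(raw) %/% 3L) * 2L else total),
      "16" = {
        v <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                     endian = "little", signed = TRUE)
        if (!is.na(total)) v[seq_len(min(total, length(v)))] else v
      },
      stop("unsupported WFDB signal format: ", fmt))
    n_frames <- length(adc) %/% ns
    for (k in seq_along(rows)) {
      i <- rows[k]
      vals <- adc[seq(k, by = ns, length.out = n_frames)]
      phys <- (vals - h$signals$baseline[i]) / h$signals$gain[i]
      nm <- make.unique(h$signals$description)[i]
      tracks[[nm]] <- track(phys, fs = h$fs, name = nm,
                            units = h$signals$units[i])
    }
  }
  tracks
}

#' Read a binary WFDB annotation file
#'
#' Decodes the standard 2-byte annotation words (type in the high 6 bits,
#' sample interval in the low 10), including the SKIP long-interval,
#' NUM/SUB/CHN modifier and AUX string pseudo-annotations.
#'
#' @param path annotation file (e.g. `.atr`, `.qrs`).
#' @param fs sampling rate used to convert sample numbers to seconds.
#' @param beats_only keep only beat annotations (the usual choice when
#'   evaluating a beat detector against a reference); `FALSE` returns
#'   every annotation including rhythm/quality marks.
#' @return data.frame with columns `sample` (0-based), `time` (seconds),
#'   `code`, `symbol`, `aux`.
#' @export
read_wfdb_annotations <- function(path, fs, beats_only = TRUE) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  b <- as.integer(raw)
  i <- 1L
  t_cur <- 0
  sample <- integer(); code <- integer(); aux <- character()
  cur_aux <- NA_character_
  while (i + 1L <= length(b)) {
    lo <- b[i]; hi <- b[i + 1L]
    i <- i + 2L
    A <- bitwShiftR(hi, 2L)
    I <- bitwAnd(hi, 3L) * 256L + lo
    if (A == 0L && I == 0L) break                     # EOF
    if (A == 59L) {                                   # SKIP: 4-byte interval
      if (I == 0L) {
        hi16 <- b[i + 1L] * 256L + b[i]
        lo16 <- b[i + 3L] * 256L + b[i + 2L]
        t_cur <- t_cur + hi16 * 65536 + lo16
        i <- i + 4L
      } else t_cur <- t_cur + I
    } else if (A == 63L) {                            # AUX string
      len <- I
      cur_aux <- rawToChar(raw[seq(i, length.out = len)])
      i <- i + len + (len %% 2L)
      if (length(sample)) aux[length(sample)] <- cur_aux
    } else if (A %in% c(60L, 61L, 62L)) {             # NUM / SUB / CHN
      # modifier values are not retained; nothing to do
    } else {
      t_cur <- t_cur + I
      sample <- c(sample, t_cur)
      code <- c(code, A)
      aux <- c(aux, NA_character_)
    }
  }
  out <- data.frame(sample = sample, time = sample / fs, code = code,
                    symbol = unname(WFDB_SYMBOLS[as.character(code)]),
                    aux = aux, stringsAsFactors = FALSE)
  if (beats_only) out <- out[out$code %in% WFDB_BEAT_CODES, , drop = FALSE]
  rownames(out) <- NULL
  out
}
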