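# Independent oracles and fixture builders used across the suite.

# Exhaustive maximum bipartite matching (Kuhn's augmenting paths) between
# detections and references under |dt| <= tau. Independent of the greedy
# sweep in match_events().
bf_match_count <- function(det, ref, tau) {
  nd <- length(det); nr <- length(ref)
  if (!nd || !nr) return(0L)
  adj <- lapply(seq_len(nr), function(j) which(abs(det - ref[j]) <= tau))
  match_d <- integer(nd)
  count <- 0L
  for (j in seq_len(nr)) {
    seen <- logical(nd)
    aug <- function(jj) {
      for (i in adj[[jj]]) {
        if (!seen[i]) {
          seen[i] <<- TRUE
          if (match_d[i] == 0L || aug(match_d[i])) {
            match_d[i] <<- jj
            return(TRUE)
          }
        }
      }
      FALSE
    }
    if (aug(j)) count <- count + 1L
  }
  count
}

# a single clean QRS-like Gaussian deflection centred at sample `centre`
qrs_template <- function(n, fs, centre, width = 0.08, amp = 1) {
  t <- (seq_len(n) - 1) / fs
  amp * exp(-((t - (centre - 1) / fs)^2) / (2 * (width / 6)^2))
}

# a randomized but valid workspace for round-trip testing
random_workspace <- function(seed) {
  set.seed(seed)
  n_tracks <- sample(1:3, 1)
  tracks <- list()
  for (k in seq_len(n_tracks)) {
    nm <- paste0("sig", k)
    tracks[[nm]] <- track(rnorm(sample(20:300, 1)),
                          fs = sample(c(100, 128, 250, 500), 1),
                          name = nm, offset = runif(1, 0, 5),
                          units = sample(c("", "mV", "a.u."), 1))
  }
  fids <- list()
  for (k in seq_len(sample(0:3, 1))) {
    nm <- sample(c("R", "foot", "peak", "upstroke", "T"), 1)
    if (nm %in% names(fids)) next
    host <- tracks[[sample(names(tracks), 1)]]
    n_ev <- sample(0:20, 1)
    tt <- sort(host$offset + runif(n_ev, 0, track_duration(host)))
    tt <- tt[c(TRUE, diff(tt) > 1e-6)]
    f <- fiducial_series(nm, t = tt, amplitude = rnorm(length(tt)),
                         sublabel = ifelse(runif(length(tt)) < 0.2, "odd",
                                           NA_character_))
    attr(f, "track") <- host$name
    fids[[nm]] <- f
  }
  edges <- sort(runif(2 * sample(0:4, 1), 0, 60))
  parts <- partition_set()
  if (length(edges) >= 2) {
    for (k in seq(1, length(edges) - 1, by = 2)) {
      if (edges[k] < edges[k + 1])
        parts <- add_partition(parts, sample(c("artifact", "walk", "rest"), 1),
                               edges[k], edges[k + 1])
    }
  }
  epochs <- NULL
  if (runif(1) < 0.7) {
    n_ep <- sample(1:12, 1)
    labs <- sample(c(NA, "Q0", "Q1", "Q2"), n_ep, replace = TRUE)
    epochs <- epoch_grid(n_ep, epoch_length = sample(c(5, 10, 30), 1),
                         labels = labs)
  }
  workspace(tracks, fids, parts, epochs,
            meta = list(record_id = paste0("rec", seed), creator = "suite"))
}

# --- minimal WFDB writers (independent of the package's readers) -----------

# pack 12-bit two's-complement sample pairs into format-212 bytes
wfdb_write_212 <- function(samples, path) {
  if (length(samples) %% 2L) samples <- c(samples, 0L)
  u <- samples %% 4096L
  s1 <- u[seq(1, length(u), by = 2)]
  s2 <- u[seq(2, length(u), by = 2)]
  bytes <- as.raw(rbind(s1 %% 256L,
                        (s1 %/% 256L) + 16L * (s2 %/% 256L),
                        s2 %% 256L))
  writeBin(as.vector(bytes), path)
}

# encode annotations as standard 2-byte words; `use_skip` exercises the
# 4-byte long-interval escape, `aux` attaches an aux string to beat 1
wfdb_write_annotations <- function(samples, codes, path, use_skip = FALSE,
                                   aux = NULL) {
  stopifnot(length(samples) == length(codes))
  word <- function(code, interval) {
    c(interval %% 256L, bitwShiftL(code, 2L) + interval %/% 256L)
  }
  out <- integer()
  prev <- 0L
  for (k in seq_along(samples)) {
    iv <- samples[k] - prev
    prev <- samples[k]
    if (use_skip && k == 2L) {
      out <- c(out, word(59L, 0L),
               (iv %/% 65536L) %% 256L, (iv %/% 65536L) %/% 256L,
               iv %% 256L, (iv %% 65536L) %/% 256L,
               word(codes[k], 0L))
    } else {
      stopifnot(iv < 1024L)
      out <- c(out, word(codes[k], iv))
    }
    if (!is.null(aux) && k == 1L) {
      a <- utf8ToInt(aux)
      if (length(a) %% 2L) a <- c(a, 0L)
      out <- c(out, word(63L, length(utf8ToInt(aux))), a)
    }
  }
  out <- c(out, word(0L, 0L))
  writeBin(as.raw(out), path)
}
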