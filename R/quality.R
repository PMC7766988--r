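#' The five-code signal-quality / morphology label scheme
#'
#' Ten-second ECG epochs receive a two-fold judgement: a quality score
#' (`Q0` low — reliable heart-rate calculation impossible, `Q1`
#' acceptable — heart rate credible, `Q2` high — artifact-free, good for
#' heart-rate-variability work) and, when quality permits, a morphology
#' score (`M1`: P- and T-waves visible in nearly all complexes, `M0`
#' otherwise). The combinations map bijectively onto the flat codes
#' annotators actually assign:
#'
#' | code | quality | morphology |
#' |-----:|---------|------------|
#' | 0 | Q0 | — |
#' | 1 | Q1 | M0 |
#' | 2 | Q1 | M1 |
#' | 3 | Q2 | M0 |
#' | 4 | Q2 | M1 |
#'
#' @return `quality_codes()` returns the full mapping as a data.frame
#'   with columns `code`, `quality`, `morphology`.
#' @export
quality_codes <- function() {
  data.frame(code = 0:4,
             quality = c("Q0", "Q1", "Q1", "Q2", "Q2"),
             morphology = c(NA, "M0", "M1", "M0", "M1"),
             stringsAsFactors = FALSE)
}

#' @rdname quality_codes
#' @param quality `"Q0"`, `"Q1"` or `"Q2"`.
#' @param morphology `"M0"`, `"M1"`, or `NA`/missing (only valid with
#'   `Q0`, which takes no morphology score).
#' @export
encode_label <- function(quality, morphology = NA_character_) {
  tab <- quality_codes()
  if (!quality %in% c("Q0", "Q1", "Q2"))
    stop_invalid("quality must be Q0, Q1 or Q2")
  if (quality == "Q0") {
    if (!is.na(morphology))
      stop_invalid("Q0 takes no morphology score")
    return(0L)
  }
  if (is.na(morphology) || !morphology %in% c("M0", "M1"))
    stop_invalid("morphology must be M0 or M1 for ", quality)
  tab$code[tab$quality == quality & !is.na(tab$morphology) &
             tab$morphology == morphology]
}

#' @rdname quality_codes
#' @param code integer 0–4.
#' @export
decode_label <- function(code) {
  tab <- quality_codes()
  i <- match(code, tab$code)
  if (is.na(i)) stop_invalid("code must be an integer in 0..4")
  list(quality = tab$quality[i], morphology = tab$morphology[i])
}

#' Adjudicate multi-annotator epoch labels
#'
#' Three experts label each epoch independently. A unanimous panel is a
#' consensus. On any disagreement the epoch goes to a fourth reviewer; if
#' the four votes then contain a 3-to-1 majority, that label stands
#' (status `"fourth-review"`), otherwise the epoch is escalated to a
#' group discussion and carries no label (`"group-escalation"`).
#'
#' `majority_ok = TRUE` switches to a looser reading in which a 2-of-3
#' majority already counts as consensus and only three-way splits go to
#' the fourth reviewer.
#'
#' @param votes integer codes (0–4) of the first three annotators, in any
#'   order (the result is permutation-invariant in them).
#' @param fourth the fourth reviewer's vote, or `NULL` if not (yet)
#'   available.
#' @param majority_ok treat a 2-of-3 majority as consensus.
#' @return `list(label = <code or NA>, status = "consensus" |
#'   "fourth-review" | "group-escalation")`. With a pending fourth review
#'   (`fourth = NULL` and no consensus) the label is `NA` and the status
#'   `"fourth-review"`.
#' @examples
#' adjudicate(c(2, 2, 2))               # consensus
#' adjudicate(c(2, 2, 1), fourth = 2)   # 3-to-1 via fourth review
#' adjudicate(c(2, 2, 1), fourth = 1)   # split 2-2: group escalation
#' @export
adjudicate <- function(votes, fourth = NULL, majority_ok = FALSE) {
  votes <- as.integer(votes)
  if (length(votes) < 3L) stop_invalid("at least three votes are required")
  if (any(is.na(votes)) || any(!votes %in% 0:4))
    stop_invalid("votes must be codes 0..4")
  if (length(votes) > 3L) {
    if (!is.null(fourth)) stop_invalid("supply the fourth vote only once")
    fourth <- votes[4L]
    votes <- votes[1:3]
  }
  tab <- table(votes)
  if (length(tab) == 1L)
    return(list(label = as.integer(names(tab)), status = "consensus"))
  if (majority_ok && max(tab) >= 2L)
    return(list(label = as.integer(names(tab)[which.max(tab)]),
                status = "consensus"))
  if (is.null(fourth))
    return(list(label = NA_integer_, status = "fourth-review"))
  all4 <- table(c(votes, as.integer(fourth)))
  if (max(all4) >= 3L)
    return(list(label = as.integer(names(all4)[which.max(all4)]),
                status = "fourth-review"))
  list(label = NA_integer_, status = "group-escalation")
}

#' Merge per-epoch annotator votes into consensus labels
#'
#' @param votes a data.frame with columns `record`, `epoch`, `annotator`,
#'   `code`. For each (record, epoch) the votes of the first three
#'   annotators (by order of appearance) form the panel; a fourth, when
#'   present, is the reviewer.
#' @param majority_ok see [adjudicate()].
#' @return a data.frame with one row per (record, epoch): `label`
#'   (`NA` when escalated or pending) and `status`.
#' @export
merge_votes <- function(votes, majority_ok = FALSE) {
  stopifnot(all(c("record", "epoch", "annotator", "code") %in% names(votes)))
  key <- interaction(votes$record, votes$epoch, drop = TRUE)
  out <- lapply(split(votes, key), function(g) {
    v <- g$code
    res <- adjudicate(v[1:min(3L, length(v))],
                      fourth = if (length(v) >= 4L) v[4L] else NULL,
                      majority_ok = majority_ok)
    data.frame(record = g$record[1], epoch = g$epoch[1],
               label = res$label, status = res$status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$record, out$epoch), ]
}
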