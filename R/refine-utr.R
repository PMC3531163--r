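## Coverage-driven UTR extension: walk outward from an annotated transcript
## end until base-level coverage drops below threshold under the
## identical-coverage-run stopping rule.

## maximal run of identical depth containing position p (0-based), merged
## with the adjacent identical-depth run on each side; returns mean depth
.run_mean <- function(d, p) {
  n <- length(d)
  i <- p + 1L                       # 1-based index
  v <- d[i]
  lo <- i; while (lo > 1L && d[lo - 1L] == v) lo <- lo - 1L
  hi <- i; while (hi < n && d[hi + 1L] == v) hi <- hi + 1L
  # adjacent run on the left
  if (lo > 1L) {
    v2 <- d[lo - 1L]
    lo2 <- lo - 1L
    while (lo2 > 1L && d[lo2 - 1L] == v2) lo2 <- lo2 - 1L
    lo <- lo2
  }
  # adjacent run on the right
  if (hi < n) {
    v3 <- d[hi + 1L]
    hi2 <- hi + 1L
    while (hi2 < n && d[hi2 + 1L] == v3) hi2 <- hi2 + 1L
    hi <- hi2
  }
  mean(d[lo:hi])
}

## is position p (0-based) a stop under the two-clause rule?
.utr_stop <- function(depths, p, config) {
  vals <- vapply(depths, function(d) d[p + 1L], numeric(1))
  if (sum(vals < config$utr_depth_threshold) < config$utr_min_low_samples)
    return(FALSE)
  all(vapply(depths, .run_mean, numeric(1), p = p) <
        config$utr_depth_threshold)
}

#' Extend one UTR of a transcript from base coverage
#'
#' Walks outward from the annotated transcript end (strand-aware: the 3'
#' side of a plus-strand transcript walks right). A position is a stop iff
#' (i) its depth is below `utr_depth_threshold` in at least
#' `utr_min_low_samples` samples, and (ii) in every sample the mean depth
#' over the maximal identical-depth run containing the position, merged
#' with the adjacent identical-depth run on each side, is below the
#' threshold. The new end is the base before the first stop. The walk is
#' clamped at the nearest same-strand annotated transcript boundary and at
#' the chromosome end. An event is returned only when the extension reaches
#' `utr_min_extension` bases.
#'
#' @param tx a `transcript_model`.
#' @param coverage_tracks list of `coverage_track`s (all samples; tracks on
#'   the transcript's strand are used).
#' @param models the full `gene_model_set` (for the anti-fusion clamp).
#' @param config a `refinement_config`.
#' @param side `"5"` or `"3"`.
#' @return a one-row event data frame, or `NULL` when no extension
#'   qualifies.
#' @export
extend_utr <- function(tx, coverage_tracks, models, config, side = c("3", "5")) {
  side <- match.arg(side)
  tracks <- Filter(function(t) t$strand == tx$strand, coverage_tracks)
  if (length(tracks) < config$utr_min_low_samples)
    stop(sprintf("need >= %d strand-matched coverage samples, have %d",
                 config$utr_min_low_samples, length(tracks)))
  depths <- lapply(tracks, function(t) {
    d <- t$depth[[tx$chrom]]
    if (is.null(d)) stop("no coverage for chromosome ", tx$chrom)
    d
  })
  chrom_len <- length(depths[[1L]])
  span <- tx_span(tx)
  rightward <- (tx$strand == "+") == (side == "3")

  sp <- model_spans(models)
  sp <- sp[sp$chrom == tx$chrom & sp$strand == tx$strand &
             sp$transcript_id != tx$transcript_id, , drop = FALSE]

  if (rightward) {
    anchor <- span[["end"]]              # exclusive end, walk starts here
    nb <- sp$start[sp$start >= anchor]
    limit <- if (length(nb)) min(nb) else chrom_len   # exclusive bound
    p <- anchor
    while (p < limit && !.utr_stop(depths, p, config)) p <- p + 1L
    new_end <- p                          # exclusive
    extension <- new_end - anchor
    old <- c(span[["start"]], span[["end"]])
    new <- c(span[["start"]], new_end)
  } else {
    anchor <- span[["start"]]            # inclusive start, walk leftward
    nb <- sp$end[sp$end <= anchor]
    limit <- if (length(nb)) max(nb) else 0L          # inclusive bound
    p <- anchor - 1L
    while (p >= limit && !.utr_stop(depths, p, config)) p <- p - 1L
    new_start <- p + 1L
    extension <- anchor - new_start
    old <- c(span[["start"]], span[["end"]])
    new <- c(new_start, span[["end"]])
  }
  if (extension < config$utr_min_extension) return(NULL)
  type <- if (side == "3") "utr3" else "utr5"
  .event_row(type, tx$transcript_id, tx$chrom, tx$strand,
             old[1L], old[2L], new[1L], new[2L],
             support_reads = NA_integer_,
             support_samples = length(tracks),
             detail = sprintf("extension=%d", extension))
}

#' Apply UTR-extension events to a model set
#'
#' Each event moves only the outer coordinate of the terminal exon on the
#' extended side.
#'
#' @param models a `gene_model_set`.
#' @param events event data frame (types `utr5`/`utr3`).
#' @return revised `gene_model_set`.
#' @export
apply_utr_events <- function(models, events) {
  events <- events[events$event_type %in% c("utr5", "utr3"), , drop = FALSE]
  txs <- models$transcripts
  for (i in seq_len(nrow(events))) {
    tid <- events$transcript_id[i]
    tx <- txs[[tid]]
    if (is.null(tx)) stop("event references unknown transcript ", tid)
    ex <- tx$exons
    if (events$new_start[i] != events$old_start[i])
      ex[1L, 1L] <- events$new_start[i]
    if (events$new_end[i] != events$old_end[i])
      ex[nrow(ex), 2L] <- events$new_end[i]
    txs[[tid]] <- transcript_model(tx$transcript_id, tx$gene_id, tx$chrom,
                                   tx$strand, ex, cds = tx$cds,
                                   frame = tx$frame, attrs = tx$attrs)
  }
  gene_model_set(txs, provenance = "revised")
}
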