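## ORF impact of boundary revisions: frame-shift classification,
## frame-restoring companion pairs, and longest-ORF scans.

.stop_codons <- c("TAA", "TAG", "TGA")

#' Spliced sense-strand sequence of a transcript
#' @param tx a `transcript_model`.
#' @param genome a `genome_sequence`.
#' @return character scalar: exon sequences concatenated in transcription
#'   order (reverse-complemented for minus-strand transcripts).
#' @export
spliced_sequence <- function(tx, genome) {
  parts <- vapply(seq_len(nrow(tx$exons)), function(i)
    genome_subseq(genome, tx$chrom, tx$exons[i, 1L], tx$exons[i, 2L]),
    character(1))
  s <- paste(parts, collapse = "")
  if (tx$strand == "-") revcomp(s) else s
}

#' Classify the reading-frame effect of a boundary revision
#'
#' The exonic length delta of a junction event is the length gained by the
#' exons, i.e. old intron length minus new intron length. The event is a
#' frame-shift when it occurs between coding exons (both flanking exons
#' overlap the annotated CDS) and the delta is not a multiple of 3.
#'
#' @param tx the `transcript_model` the event was proposed against.
#' @param event one-row event data frame (type `junction`).
#' @return list: `transcript_id`, `event_id`, `coding_coding`,
#'   `exonic_length_delta`, `frameshift`.
#' @export
classify_frame_effect <- function(tx, event) {
  stopifnot(event$event_type == "junction")
  if (event$transcript_id != tx$transcript_id)
    stop("event/transcript mismatch")
  ex <- tx$exons
  j <- which(ex[-nrow(ex), 2L] == event$old_start &
               ex[-1L, 1L] == event$old_end)
  if (length(j) != 1L)
    stop("event does not match an annotated intron of ", tx$transcript_id)
  delta <- (event$old_end - event$old_start) -
    (event$new_end - event$new_start)
  coding <- FALSE
  if (!is.null(tx$cds)) {
    overlaps_cds <- function(exon)
      any(tx$cds[, 1L] < exon[2L] & tx$cds[, 2L] > exon[1L])
    coding <- overlaps_cds(ex[j, ]) && overlaps_cds(ex[j + 1L, ])
  }
  list(transcript_id = tx$transcript_id, event_id = event$event_id,
       coding_coding = coding,
       exonic_length_delta = as.integer(delta),
       frameshift = coding && (delta %% 3L != 0L))
}

#' Detect frame-restoring companion events
#'
#' For each frame-shifting event on a transcript, reports the other events
#' on the same transcript whose delta cancels it modulo 3 (summed deltas
#' congruent to 0). An empty companion set marks an unpaired frame-shift.
#'
#' @param reports list of frame-effect reports from
#'   [classify_frame_effect()], all for one transcript.
#' @return named list: for each frameshift event id, the character vector
#'   of companion event ids (possibly empty).
#' @export
find_companion_anomalies <- function(reports) {
  ids <- vapply(reports, `[[`, character(1), "event_id")
  deltas <- vapply(reports, `[[`, integer(1), "exonic_length_delta")
  fs <- vapply(reports, `[[`, logical(1), "frameshift")
  out <- list()
  for (i in which(fs)) {
    comp <- ids[setdiff(which((deltas[i] + deltas) %% 3L == 0L), i)]
    out[[ids[i]]] <- comp
  }
  out
}

#' Longest open reading frame of a transcript
#'
#' Scans the spliced sense-strand sequence in all three frames for the
#' longest ATG-to-stop ORF (length counted in codons, stop included). When
#' no ATG has an in-frame stop, the longest open ATG-to-end run is
#' reported with `intact = FALSE`; with no ATG at all the length is 0.
#'
#' @param tx a `transcript_model`.
#' @param genome a `genome_sequence`.
#' @return list: `transcript_id`, `start` (0-based offset in the spliced
#'   sequence), `length_codons`, `intact`.
#' @export
scan_orf <- function(tx, genome) {
  s <- spliced_sequence(tx, genome)
  res <- longest_orf(s)
  c(list(transcript_id = tx$transcript_id), res)
}

#' Longest ORF of a nucleotide string
#' @param s DNA string.
#' @return list: `start` (0-based), `length_codons`, `intact`.
#' @export
longest_orf <- function(s) {
  n <- nchar(s)
  best <- list(start = NA_integer_, length_codons = 0L, intact = FALSE)
  for (f in 0:2) {
    if (n - 2L < 1L + f) next
    starts <- seq.int(1L + f, n - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% .stop_codons)
    for (a in atg) {
      nxt <- stp[stp >= a]
      if (length(nxt)) {
        len <- nxt[1L] - a + 1L
        intact <- TRUE
      } else {
        len <- length(codons) - a + 1L
        intact <- FALSE
      }
      better <- len > best$length_codons ||
        (len == best$length_codons && intact && !best$intact)
      if (better)
        best <- list(start = starts[a] - 1L, length_codons = len,
                     intact = intact)
    }
  }
  best
}

#' Audit the ORF impact of all junction events
#'
#' @param models the `gene_model_set` the events were proposed against.
#' @param events event ledger.
#' @return data frame: transcript_id, event_id, coding_coding, delta,
#'   frameshift, companion_ids (comma-separated, empty when unpaired).
#' @export
orf_audit <- function(models, events) {
  jx <- events[events$event_type == "junction", , drop = FALSE]
  if (!nrow(jx))
    return(data.frame(transcript_id = character(0), event_id = character(0),
                      coding_coding = logical(0), delta = integer(0),
                      frameshift = logical(0), companion_ids = character(0)))
  rows <- list()
  for (tid in unique(jx$transcript_id)) {
    tx <- models$transcripts[[tid]]
    sub <- jx[jx$transcript_id == tid, , drop = FALSE]
    reports <- lapply(seq_len(nrow(sub)), function(i)
      classify_frame_effect(tx, sub[i, ]))
    comp <- find_companion_anomalies(reports)
    for (r in reports) {
      cids <- if (r$frameshift) paste(comp[[r$event_id]], collapse = ",")
        else ""
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = r$transcript_id, event_id = r$event_id,
        coding_coding = r$coding_coding, delta = r$exonic_length_delta,
        frameshift = r$frameshift, companion_ids = cids,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
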