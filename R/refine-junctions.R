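## Exon-intron boundary revision: replace an unsupported annotated intron
## with an evidence junction that satisfies all four rules.

.empty_events <- function() {
  data.frame(event_id = character(0), event_type = character(0),
             transcript_id = character(0), chrom = character(0),
             strand = character(0), old_start = integer(0),
             old_end = integer(0), new_start = integer(0),
             new_end = integer(0), support_reads = integer(0),
             support_samples = integer(0), detail = character(0),
             stringsAsFactors = FALSE)
}

.event_row <- function(event_type, transcript_id, chrom, strand,
                       old_start, old_end, new_start, new_end,
                       support_reads, support_samples, detail = "") {
  data.frame(event_id = NA_character_, event_type = event_type,
             transcript_id = transcript_id, chrom = chrom, strand = strand,
             old_start = as.integer(old_start), old_end = as.integer(old_end),
             new_start = as.integer(new_start), new_end = as.integer(new_end),
             support_reads = as.integer(support_reads),
             support_samples = as.integer(support_samples),
             detail = detail, stringsAsFactors = FALSE)
}

.number_events <- function(events, prefix = "E") {
  if (nrow(events))
    events$event_id <- sprintf("%s%04d", prefix, seq_len(nrow(events)))
  events
}

#' Propose exon-intron boundary revisions
#'
#' For each annotated intron with zero junction-read support, accept an
#' evidence junction as its replacement iff (a) its total reads reach
#' `min_junction_reads`; (b) its splice dinucleotides are canonical;
#' (c) it lies within the span from the leading exon's start to the
#' following exon's end; and (d) both revised flanking exon lengths fall
#' within `exon_len_ratio` of the annotated lengths. At most one event is
#' emitted per annotated intron: ties are broken by highest read support,
#' then smallest coordinate shift, then leftmost candidate.
#'
#' @param models a `gene_model_set`.
#' @param junctions a `junction_table`.
#' @param genome a `genome_sequence`.
#' @param config a `refinement_config`.
#' @return event data frame (one row per accepted revision).
#' @export
propose_junction_revisions <- function(models, junctions, genome, config) {
  events <- list()
  for (tx in models$transcripts) {
    intr <- introns_of(tx)
    if (!nrow(intr)) next
    for (i in seq_len(nrow(intr))) {
      old_s <- intr$start[i]; old_e <- intr$end[i]
      if (junction_support(junctions, tx$chrom, old_s, old_e,
                           tx$strand)[["reads"]] > 0L) next
      lead <- tx$exons[i, ]; foll <- tx$exons[i + 1L, ]
      cands <- junctions_in_region(junctions, tx$chrom, lead[["start"]],
                                   foll[["end"]], tx$strand)
      if (!nrow(cands)) next
      ok <- logical(nrow(cands))
      for (k in seq_len(nrow(cands))) {
        cs <- cands$start[k]; ce <- cands$end[k]
        if (cands$reads[k] < config$min_junction_reads) next
        if (cs < lead[["start"]] || ce > foll[["end"]]) next
        # revised flanking exons must be non-empty
        if (cs <= lead[["start"]] || ce >= foll[["end"]]) next
        r_lead <- (cs - lead[["start"]]) / (lead[["end"]] - lead[["start"]])
        r_foll <- (foll[["end"]] - ce) / (foll[["end"]] - foll[["start"]])
        if (r_lead < config$exon_len_ratio[1L] ||
            r_lead > config$exon_len_ratio[2L] ||
            r_foll < config$exon_len_ratio[1L] ||
            r_foll > config$exon_len_ratio[2L]) next
        if (ce - cs < 4L) next
        dn <- splice_dinucleotides(genome, tx$chrom, cs, ce, tx$strand)
        if (!.pair_ok(dn, config)) next
        ok[k] <- TRUE
      }
      cands <- cands[ok, , drop = FALSE]
      if (!nrow(cands)) next
      shift <- abs(cands$start - old_s) + abs(cands$end - old_e)
      best <- order(-cands$reads, shift, cands$start)[1L]
      events[[length(events) + 1L]] <- .event_row(
        "junction", tx$transcript_id, tx$chrom, tx$strand,
        old_s, old_e, cands$start[best], cands$end[best],
        cands$reads[best], cands$samples[best],
        detail = sprintf("intron_index=%d", i))
    }
  }
  if (!length(events)) return(.empty_events())
  .number_events(do.call(rbind, events))
}

#' Apply boundary-revision events to a model set
#'
#' Moves the flanking exon boundaries of each revised intron to the
#' candidate intron's ends. Exon counts are unchanged; CDS intervals are
#' re-clipped to the revised exons; untouched transcripts are returned
#' as-is.
#'
#' @param models a `gene_model_set`.
#' @param events event data frame from [propose_junction_revisions()].
#' @return revised `gene_model_set` (provenance `"revised"`).
#' @export
apply_junction_revisions <- function(models, events) {
  events <- events[events$event_type == "junction", , drop = FALSE]
  if (nrow(events) &&
      anyDuplicated(events[, c("transcript_id", "old_start", "old_end")]))
    stop("conflicting junction events on one annotated intron")
  txs <- models$transcripts
  for (i in seq_len(nrow(events))) {
    tid <- events$transcript_id[i]
    tx <- txs[[tid]]
    if (is.null(tx)) stop("event references unknown transcript ", tid)
    ex <- tx$exons
    j <- which(ex[-nrow(ex), 2L] == events$old_start[i] &
                 ex[-1L, 1L] == events$old_end[i])
    if (length(j) != 1L)
      stop("event does not match an annotated intron of ", tid)
    ex[j, 2L] <- events$new_start[i]
    ex[j + 1L, 1L] <- events$new_end[i]
    txs[[tid]] <- transcript_model(tx$transcript_id, tx$gene_id, tx$chrom,
                                   tx$strand, ex,
                                   cds = .clip_cds(tx$cds, ex),
                                   frame = tx$frame, attrs = tx$attrs)
  }
  gene_model_set(txs, provenance = "revised")
}

## intersect CDS intervals with a revised exon set, dropping empties
.clip_cds <- function(cds, exons) {
  if (is.null(cds)) return(NULL)
  out <- NULL
  for (i in seq_len(nrow(cds))) {
    for (j in seq_len(nrow(exons))) {
      s <- max(cds[i, 1L], exons[j, 1L])
      e <- min(cds[i, 2L], exons[j, 2L])
      if (s < e) out <- rbind(out, c(s, e))
    }
  }
  out
}
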