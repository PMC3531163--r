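#' Refine a gene model set against RNA-Seq evidence
#'
#' Runs the four revision procedures in fixed order — exon-intron boundary
#' revision, then 5' and 3' UTR extension, then recovery of missed exons,
#' then assembly of novel intergenic transcripts — each stage against the
#' progressively revised models. Returns the revised set together with a
#' ledger of every revision event. In the transcripts-affected total each
#' transcript is counted once however many revisions it received.
#'
#' @param models a `gene_model_set` (the putative annotation).
#' @param evidence list with components `coverage` (list of
#'   `coverage_track`s), `junctions` (a `junction_table`) and `genome` (a
#'   `genome_sequence`).
#' @param config a `refinement_config`.
#' @return an object of class `gm_refinement`: list with `models` (revised
#'   set, novel transcripts included and clustered into genes), `events`
#'   (the ledger), `clusters` (gene id per novel transcript) and `config`.
#' @export
refine <- function(models, evidence, config = refinement_config()) {
  stopifnot(is.list(evidence),
            all(c("coverage", "junctions", "genome") %in% names(evidence)))
  coverage <- evidence$coverage
  junctions <- evidence$junctions
  genome <- evidence$genome

  jx_events <- propose_junction_revisions(models, junctions, genome, config)
  current <- apply_junction_revisions(models, jx_events)

  utr_events <- .empty_events()
  for (side in c("5", "3")) {
    rows <- list()
    for (tx in current$transcripts) {
      ev <- extend_utr(tx, coverage, current, config, side = side)
      if (!is.null(ev)) rows[[length(rows) + 1L]] <- ev
    }
    if (length(rows)) {
      ev <- .number_events(do.call(rbind, rows),
                           prefix = if (side == "5") "U5_" else "U3_")
      current <- apply_utr_events(current, ev)
      utr_events <- rbind(utr_events, ev)
    }
  }

  islands <- rbind(call_coverage_islands(coverage, "+", config),
                   call_coverage_islands(coverage, "-", config))
  ne_events <- find_new_exons(current, islands, junctions, genome, config)
  current <- apply_new_exon_events(current, ne_events)

  nt <- assemble_new_transcripts(islands, junctions, current, genome, config)
  clusters <- cluster_new_transcripts(nt$transcripts)
  txs <- current$transcripts
  for (tid in names(nt$transcripts)) {
    t <- nt$transcripts[[tid]]
    t$gene_id <- unname(clusters[[tid]])
    txs[[tid]] <- t
  }
  revised <- gene_model_set(txs, provenance = "revised")

  events <- rbind(jx_events, utr_events, ne_events, nt$events)
  structure(list(models = revised, events = events, clusters = clusters,
                 config = config),
            class = "gm_refinement")
}

#' @export
print.gm_refinement <- function(x, ...) {
  ev <- x$events
  cat("<gm_refinement>\n")
  cat(sprintf("  %d revision event(s) across %d transcript(s)\n",
              nrow(ev), length(affected_transcripts(ev))))
  for (ty in c("junction", "utr5", "utr3", "new_exon", "new_transcript"))
    cat(sprintf("  %-15s %d\n", ty, sum(ev$event_type == ty)))
  invisible(x)
}

#' @export
summary.gm_refinement <- function(object, ...) {
  ev <- object$events
  cats <- c("junction", "utr5", "utr3", "new_exon")
  df <- data.frame(
    category = c(cats, "total"),
    events = c(vapply(cats, function(t) sum(ev$event_type == t), integer(1)),
               sum(ev$event_type %in% cats)),
    transcripts = c(vapply(cats, function(t)
      length(unique(ev$transcript_id[ev$event_type == t])), integer(1)),
      length(affected_transcripts(ev))),
    row.names = NULL)
  df$new_transcripts <- c(rep(NA_integer_, length(cats)),
                          sum(ev$event_type == "new_transcript"))
  df
}

#' Transcripts affected by revision events
#'
#' Counts each transcript once; novel transcripts are excluded (they do not
#' revise an annotated model).
#'
#' @param events event ledger.
#' @return character vector of affected annotated transcript ids.
#' @export
affected_transcripts <- function(events) {
  sel <- events$event_type %in% c("junction", "utr5", "utr3", "new_exon")
  unique(events$transcript_id[sel])
}

#' Write an event ledger as TSV
#' @param events event ledger.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an event ledger TSV
#' @param path events TSV written by [write_events_tsv()].
#' @return event data frame.
#' @export
read_events_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(event_id = "character",
                                   transcript_id = "character",
                                   detail = "character"))
}
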