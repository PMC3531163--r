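## Validation statistics for revisions: coverage category distributions,
## conservation profiles, splice-site motif matrices, poly(A)-signal
## profiles, end-distance histograms, and summary accounting.

#' Rounded percentage at one decimal
#'
#' The single rounding rule used by all summary accounting:
#' `round(100 * numerator / denominator, 1)`.
#'
#' @param numerator,denominator counts.
#' @return numeric percentage at one decimal.
#' @export
summary_percentage <- function(numerator, denominator) {
  round(100 * numerator / denominator, 1)
}

## ---- coverage categories around revised junctions -------------------------

#' Coverage distributions around revised exon-intron boundaries
#'
#' For each boundary-revision event, classifies every base of the window
#' from the leading exon's start to the following exon's end (old model)
#' into four categories: `exon` (exonic under both models), `intron`
#' (intronic under both), `revised_exon` (exonic only under the revised
#' model) and `revised_intron` (intronic only under the revised model).
#' Depths are pooled across samples and normalized by the window maximum.
#' The `revised_exon` vs `revised_intron` distributions are compared with a
#' two-sided Wilcoxon rank-sum test.
#'
#' @param old_models,new_models model sets before and after revision.
#' @param events event ledger (junction events are used).
#' @param coverage list of `coverage_track`s.
#' @return list: the four numeric vectors of normalized depths, `statistic`
#'   (rank-sum W), and `p_value` (`NA` when either disputed category is
#'   empty).
#' @export
boundary_coverage_categories <- function(old_models, new_models, events,
                                         coverage) {
  events <- events[events$event_type == "junction", , drop = FALSE]
  cats <- list(exon = numeric(0), intron = numeric(0),
               revised_exon = numeric(0), revised_intron = numeric(0))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    old_tx <- old_models$transcripts[[ev$transcript_id]]
    new_tx <- new_models$transcripts[[ev$transcript_id]]
    win <- .event_window(old_tx, ev)
    if (is.null(win)) next
    depth <- pooled_depth(coverage, ev$strand, ev$chrom, win[1L], win[2L])
    mx <- max(depth)
    if (mx == 0) next
    depth <- depth / mx
    pos <- win[1L]:(win[2L] - 1L)
    old_exonic <- .exonic_mask(old_tx, pos)
    new_exonic <- .exonic_mask(new_tx, pos)
    cats$exon <- c(cats$exon, depth[old_exonic & new_exonic])
    cats$intron <- c(cats$intron, depth[!old_exonic & !new_exonic])
    cats$revised_exon <- c(cats$revised_exon, depth[!old_exonic & new_exonic])
    cats$revised_intron <- c(cats$revised_intron,
                             depth[old_exonic & !new_exonic])
  }
  if (length(cats$revised_exon) && length(cats$revised_intron)) {
    wt <- stats::wilcox.test(cats$revised_exon, cats$revised_intron,
                             alternative = "two.sided", exact = FALSE,
                             correct = TRUE)
    cats$statistic <- unname(wt$statistic)
    cats$p_value <- wt$p.value
  } else {
    cats$statistic <- NA_real_
    cats$p_value <- NA_real_
  }
  cats
}

.event_window <- function(old_tx, ev) {
  ex <- old_tx$exons
  j <- which(ex[-nrow(ex), 2L] == ev$old_start & ex[-1L, 1L] == ev$old_end)
  if (length(j) != 1L) return(NULL)
  c(ex[j, 1L], ex[j + 1L, 2L])
}

.exonic_mask <- function(tx, pos) {
  m <- logical(length(pos))
  for (i in seq_len(nrow(tx$exons)))
    m <- m | (pos >= tx$exons[i, 1L] & pos < tx$exons[i, 2L])
  m
}

## ---- conservation profiles ------------------------------------------------

## transcription-sense genomic position for an offset at a junction side.
## donor: offset 0 = first intronic base (negative = exonic upstream).
## acceptor: offset 0 = first exonic base after the intron (negative =
## intronic).
.side_pos <- function(start, end, strand, side, offset) {
  if (side == "donor") {
    if (strand == "+") start + offset else end - 1L - offset
  } else {
    if (strand == "+") end + offset else start - 1L - offset
  }
}

#' Per-offset conservation score around splice junctions
#'
#' Mean score per transcription-sense offset in `[-half_window,
#' half_window)` anchored at donor and acceptor sites. Donor offsets below
#' zero are exonic; acceptor offsets below zero are intronic.
#'
#' @param models a `gene_model_set` (its distinct junctions are the
#'   anchors), or a junction-key data frame (chrom, start, end, strand).
#' @param score_track named list of per-chromosome numeric score vectors.
#' @param half_window window half-width in bases.
#' @return list with `donor` and `acceptor` profiles (data frames: offset,
#'   value) and `n_anchors`.
#' @export
conservation_junction_profile <- function(models, score_track,
                                          half_window = 50L) {
  keys <- if (inherits(models, "gene_model_set")) junction_keys(models)
    else models
  offsets <- seq.int(-half_window, half_window - 1L)
  prof <- list(donor = numeric(length(offsets)),
               acceptor = numeric(length(offsets)))
  counts <- list(donor = integer(length(offsets)),
                 acceptor = integer(length(offsets)))
  for (i in seq_len(nrow(keys))) {
    sc <- score_track[[keys$chrom[i]]]
    for (side in c("donor", "acceptor")) {
      pos <- .side_pos(keys$start[i], keys$end[i], keys$strand[i], side,
                       offsets)
      ok <- pos >= 0L & pos < length(sc)
      prof[[side]][ok] <- prof[[side]][ok] + sc[pos[ok] + 1L]
      counts[[side]][ok] <- counts[[side]][ok] + 1L
    }
  }
  mk <- function(side) data.frame(
    offset = offsets,
    value = ifelse(counts[[side]] > 0, prof[[side]] / counts[[side]],
                   NA_real_))
  list(donor = mk("donor"), acceptor = mk("acceptor"),
       n_anchors = nrow(keys))
}

## ---- splice-site position frequency matrices ------------------------------

#' Position frequency matrices flanking splice junctions
#'
#' Transcription-sense base frequencies per offset around donor and
#' acceptor sites, with per-column information content in bits. Donor
#' window default `[-3, +6)` (negative offsets exonic); acceptor window
#' default `[-13, +3)` (negative offsets intronic). Junctions too short for
#' the windows are skipped and counted.
#'
#' @param models a `gene_model_set` or a junction-key data frame.
#' @param genome a `genome_sequence`.
#' @param donor_window,acceptor_window integer vectors `c(lo, hi)`,
#'   half-open offset windows.
#' @return list with `donor` and `acceptor` elements, each a list holding
#'   `freq` (4 x width matrix, rows A,C,G,T; columns sum to 1), `ic`
#'   (bits per offset), `offsets` and `n`; plus `n_skipped`.
#' @export
splice_pfm <- function(models, genome, donor_window = c(-3L, 6L),
                       acceptor_window = c(-13L, 3L)) {
  keys <- if (inherits(models, "gene_model_set")) junction_keys(models)
    else models
  windows <- list(donor = seq.int(donor_window[1L], donor_window[2L] - 1L),
                  acceptor = seq.int(acceptor_window[1L],
                                     acceptor_window[2L] - 1L))
  bases <- c("A", "C", "G", "T")
  counts <- lapply(windows, function(w)
    matrix(0L, nrow = 4L, ncol = length(w),
           dimnames = list(bases, as.character(w))))
  n_used <- c(donor = 0L, acceptor = 0L)
  n_skipped <- 0L
  # intron must be long enough that windows never cross to the other side
  min_intron <- max(donor_window[2L], 0L) + max(-acceptor_window[1L], 0L)
  for (i in seq_len(nrow(keys))) {
    if (keys$end[i] - keys$start[i] < min_intron) {
      n_skipped <- n_skipped + 1L
      next
    }
    clen <- chrom_lengths(genome)[[keys$chrom[i]]]
    for (side in c("donor", "acceptor")) {
      pos <- .side_pos(keys$start[i], keys$end[i], keys$strand[i], side,
                       windows[[side]])
      if (any(pos < 0L | pos >= clen)) next
      seqs <- vapply(pos, function(p)
        genome_subseq(genome, keys$chrom[i], p, p + 1L), character(1))
      if (keys$strand[i] == "-") seqs <- chartr("ACGT", "TGCA", seqs)
      for (k in seq_along(seqs)) {
        b <- match(seqs[k], bases)
        if (!is.na(b)) counts[[side]][b, k] <- counts[[side]][b, k] + 1L
      }
      n_used[[side]] <- n_used[[side]] + 1L
    }
  }
  mk <- function(side) {
    cm <- counts[[side]]
    tot <- colSums(cm)
    freq <- sweep(cm, 2L, pmax(tot, 1L), "/")
    ic <- apply(freq, 2L, function(p) {
      p <- p[p > 0]
      if (!length(p)) return(0)
      2 + sum(p * log2(p))
    })
    ic[tot == 0] <- 0
    list(freq = freq, ic = ic, offsets = windows[[side]],
         n = unname(n_used[[side]]))
  }
  list(donor = mk("donor"), acceptor = mk("acceptor"),
       n_skipped = n_skipped)
}

## ---- poly(A)-signal positional profile ------------------------------------

## sense-strand hexamer starting at transcription-sense offset o from an
## anchor base (0-based genomic index of the anchor base itself)
.hexamer_at <- function(genome, chrom, anchor, strand, offset, k = 6L) {
  clen <- chrom_lengths(genome)[[chrom]]
  if (strand == "+") {
    s <- anchor + offset
    if (s < 0L || s + k > clen) return(NA_character_)
    genome_subseq(genome, chrom, s, s + k)
  } else {
    e <- anchor - offset + 1L
    if (e - k < 0L || e > clen) return(NA_character_)
    revcomp(genome_subseq(genome, chrom, e - k, e))
  }
}

#' Positional frequency of a hexamer near transcript 3' ends
#'
#' For each transcription-sense offset in the window, the fraction of
#' transcripts whose sense-strand hexamer starting at (3' end + offset)
#' equals `motif` (DNA sense, so the canonical poly(A) signal AAUAAA is
#' `"AATAAA"`). A negative control is computed identically anchored at the
#' 5' start.
#'
#' @param models a `gene_model_set`.
#' @param genome a `genome_sequence`.
#' @param motif DNA hexamer to count.
#' @param window integer `c(lo, hi)`, half-open offset window.
#' @return list with `profile` and `control` data frames (offset,
#'   frequency) and `n_anchors`.
#' @export
hexamer_end_profile <- function(models, genome, motif = "AATAAA",
                                window = c(-60L, 10L)) {
  offsets <- seq.int(window[1L], window[2L] - 1L)
  k <- nchar(motif)
  count <- function(anchor_of) {
    hits <- integer(length(offsets))
    n <- 0L
    for (tx in models$transcripts) {
      a <- anchor_of(tx)
      n <- n + 1L
      for (j in seq_along(offsets)) {
        h <- .hexamer_at(genome, tx$chrom, a, tx$strand, offsets[j], k)
        if (!is.na(h) && h == motif) hits[j] <- hits[j] + 1L
      }
    }
    data.frame(offset = offsets,
               frequency = if (n > 0) hits / n else rep(0, length(offsets)))
  }
  end3 <- function(tx) {
    sp <- tx_span(tx)
    if (tx$strand == "+") sp[["end"]] - 1L else sp[["start"]]
  }
  start5 <- function(tx) {
    sp <- tx_span(tx)
    if (tx$strand == "+") sp[["start"]] else sp[["end"]] - 1L
  }
  list(profile = count(end3), control = count(start5),
       n_anchors = length(models$transcripts))
}

## ---- end-distance histogram ------------------------------------------------

#' Histogram of peak-to-transcript-end distances
#'
#' Signed transcription-sense distance from each peak midpoint to the
#' nearest annotated transcript 5' end, binned; positive distances are
#' downstream of the 5' end. Peaks with no transcript end within the
#' window are dropped.
#'
#' @param peaks data frame with chrom, start, end (0-based half-open), as
#'   from [read_bed()].
#' @param models a `gene_model_set`.
#' @param window maximum absolute distance (bases).
#' @param bin bin width (bases).
#' @return list: `breaks`, `counts`, `n_peaks_used`.
#' @export
end_distance_profile <- function(peaks, models, window = 5000L, bin = 100L) {
  sp <- model_spans(models)
  tss <- ifelse(sp$strand == "+", sp$start, sp$end - 1L)
  dists <- numeric(0)
  for (i in seq_len(nrow(peaks))) {
    mid <- (peaks$start[i] + peaks$end[i]) %/% 2L
    sel <- sp$chrom == peaks$chrom[i]
    if (!any(sel)) next
    d_gen <- mid - tss[sel]
    d_sense <- ifelse(sp$strand[sel] == "+", d_gen, -d_gen)
    j <- which.min(abs(d_sense))
    if (abs(d_sense[j]) <= window) dists <- c(dists, d_sense[j])
  }
  breaks <- seq.int(-window, window, by = bin)
  counts <- if (length(dists))
    graphics::hist(dists, breaks = breaks, plot = FALSE,
                   right = FALSE)$counts
  else integer(length(breaks) - 1L)
  list(breaks = breaks, counts = counts, n_peaks_used = length(dists))
}

## ---- summary accounting ----------------------------------------------------

#' Summary accounting of a refinement run
#'
#' Produces the evidence-coverage table (exons, junctions and transcripts
#' that carry any read support, with percentages at one decimal) and the
#' revision table (events and deduplicated transcripts per category;
#' percentages over the total annotated transcripts; transcripts with two
#' or more revisions counted once in the total row).
#'
#' @param models the putative `gene_model_set`.
#' @param evidence evidence list (`coverage`, `junctions`), as for
#'   [refine()].
#' @param events event ledger from [refine()].
#' @return list with data frames `coverage_table` and `revision_table`,
#'   plus `n_new_transcripts`.
#' @export
summary_report <- function(models, evidence, events) {
  txs <- models$transcripts
  n_tx <- length(txs)
  exon_total <- 0L; exon_cov <- 0L
  jx_total <- 0L; jx_cov <- 0L
  tx_cov <- 0L
  for (tx in txs) {
    covered_any <- FALSE
    for (i in seq_len(nrow(tx$exons))) {
      exon_total <- exon_total + 1L
      d <- pooled_depth(evidence$coverage, tx$strand, tx$chrom,
                        tx$exons[i, 1L], tx$exons[i, 2L])
      if (any(d >= 1)) {
        exon_cov <- exon_cov + 1L
        covered_any <- TRUE
      }
    }
    intr <- introns_of(tx)
    for (i in seq_len(nrow(intr))) {
      jx_total <- jx_total + 1L
      if (junction_support(evidence$junctions, intr$chrom[i], intr$start[i],
                           intr$end[i], intr$strand[i])[["reads"]] >= 1L)
        jx_cov <- jx_cov + 1L
    }
    if (covered_any) tx_cov <- tx_cov + 1L
  }
  coverage_table <- data.frame(
    category = c("exons", "junctions", "transcripts"),
    total = c(exon_total, jx_total, n_tx),
    covered = c(exon_cov, jx_cov, tx_cov),
    percentage = c(summary_percentage(exon_cov, exon_total),
                   summary_percentage(jx_cov, jx_total),
                   summary_percentage(tx_cov, n_tx)))

  cats <- c("junction", "utr5", "utr3", "new_exon")
  ev <- events[events$event_type %in% cats, , drop = FALSE]
  n_events <- vapply(cats, function(t) sum(ev$event_type == t), integer(1))
  n_txs <- vapply(cats, function(t)
    length(unique(ev$transcript_id[ev$event_type == t])), integer(1))
  total_tx <- length(unique(ev$transcript_id))
  revision_table <- data.frame(
    category = c(cats, "total"),
    events = c(n_events, sum(n_events)),
    transcripts = c(n_txs, total_tx),
    percentage = summary_percentage(c(n_txs, total_tx), max(n_tx, 1L)))

  list(coverage_table = coverage_table, revision_table = revision_table,
       n_new_transcripts = sum(events$event_type == "new_transcript"))
}
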