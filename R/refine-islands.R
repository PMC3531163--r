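## Coverage islands, novel exon recovery and novel transcript assembly.

#' Call coverage islands on one strand
#'
#' An island is a maximal run of bases whose pooled depth (summed over all
#' samples of the strand) reaches `island_min_depth`, of length at least
#' `island_min_length`. Islands on one strand never overlap by
#' construction. This internal caller is the unit that stands in for an
#' external transcript assembler's "intact exon".
#'
#' @param coverage_tracks list of `coverage_track`s.
#' @param strand `"+"` or `"-"`.
#' @param config a `refinement_config`.
#' @return data frame: chrom, start, end, strand, pooled_mean_depth, plus a
#'   `sample_means` list-column of per-sample mean depths.
#' @export
call_coverage_islands <- function(coverage_tracks, strand, config) {
  tracks <- Filter(function(t) t$strand == strand, coverage_tracks)
  out <- list()
  if (!length(tracks)) return(.empty_islands())
  chroms <- names(tracks[[1L]]$depth)
  for (cn in chroms) {
    pooled <- Reduce(`+`, lapply(tracks, function(t) t$depth[[cn]]))
    r <- rle(pooled >= config$island_min_depth)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values & r$lengths >= config$island_min_length
    if (!any(keep)) next
    for (i in which(keep)) {
      s <- starts[i]; e <- ends[i]
      sm <- vapply(tracks, function(t) mean(t$depth[[cn]][(s + 1L):e]),
                   numeric(1))
      names(sm) <- vapply(tracks, `[[`, character(1), "sample_id")
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn, start = s, end = e, strand = strand,
        pooled_mean_depth = mean(pooled[(s + 1L):e]),
        sample_means = I(list(sm)), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.empty_islands())
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

.empty_islands <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), pooled_mean_depth = numeric(0),
             sample_means = I(list()))
}

## total bases of [s,e) covered by the union of exon intervals in `exons`
.exon_overlap_bases <- function(exons, chrom, s, e, strand = NA) {
  sel <- exons$chrom == chrom & exons$start < e & exons$end > s
  if (!is.na(strand)) sel <- sel & exons$strand == strand
  if (!any(sel)) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(
    start = pmax(exons$start[sel], s) + 1L,
    end = pmin(exons$end[sel], e)))
  sum(IRanges::width(ir))
}

## best supported canonical junction rows (helper for link search)
.linking_junctions <- function(junctions, genome, chrom, strand, config) {
  a <- junctions$agg
  sel <- a$chrom == chrom & a$strand == strand &
    a$reads >= config$min_junction_reads & (a$end - a$start) >= 4L
  a <- a[sel, , drop = FALSE]
  if (!nrow(a)) return(a)
  canon <- vapply(seq_len(nrow(a)), function(i)
    .pair_ok(splice_dinucleotides(genome, chrom, a$start[i], a$end[i],
                                  strand), config), logical(1))
  a[canon, , drop = FALSE]
}

#' Recover exons missed by the annotation
#'
#' An island becomes a new exon of transcript T iff it lies inside T's
#' span; a supported canonical junction links each island end to an
#' annotated exon boundary of T (the upstream link's intron starts at an
#' exon end of T and lands inside the island, the downstream link's intron
#' leaves the island and lands on an exon start of T); and the island's
#' overlap with all annotated exons is below `new_exon_max_overlap` of the
#' island's length. Exon boundaries are snapped to the linking junctions'
#' intron ends.
#'
#' @param models a `gene_model_set`.
#' @param islands island data frame from [call_coverage_islands()].
#' @param junctions a `junction_table`.
#' @param genome a `genome_sequence`.
#' @param config a `refinement_config`.
#' @return event data frame (type `new_exon`).
#' @export
find_new_exons <- function(models, islands, junctions, genome, config) {
  events <- list()
  all_exons <- model_exons(models)
  for (i in seq_len(nrow(islands))) {
    isl <- islands[i, ]
    cand_tids <- overlapping_transcripts(models, isl$chrom, isl$start,
                                         isl$end, isl$strand)
    links <- NULL
    for (tid in cand_tids) {
      tx <- models$transcripts[[tid]]
      span <- tx_span(tx)
      if (isl$start < span[["start"]] || isl$end > span[["end"]]) next
      jx <- .linking_junctions(junctions, genome, isl$chrom, isl$strand,
                               config)
      if (!nrow(jx)) next
      # upstream link: intron from an exon end of T into the island
      up <- jx[jx$start %in% tx$exons[, 2L] &
                 jx$end >= isl$start & jx$end < isl$end, , drop = FALSE]
      # downstream link: intron from the island onto an exon start of T
      dn <- jx[jx$end %in% tx$exons[, 1L] &
                 jx$start > isl$start & jx$start <= isl$end, , drop = FALSE]
      if (!nrow(up) || !nrow(dn)) next
      up <- up[order(-up$reads, up$end), , drop = FALSE][1L, ]
      dn <- dn[order(-dn$reads, -dn$start), , drop = FALSE][1L, ]
      if (up$end >= dn$start) next
      links <- list(tx = tx, up = up, dn = dn)
      break
    }
    if (is.null(links)) next
    ns <- links$up$end; ne <- links$dn$start
    len <- ne - ns
    ov <- .exon_overlap_bases(all_exons, isl$chrom, ns, ne)
    if (ov / len >= config$new_exon_max_overlap) next
    events[[length(events) + 1L]] <- .event_row(
      "new_exon", links$tx$transcript_id, isl$chrom, isl$strand,
      isl$start, isl$end, ns, ne,
      support_reads = min(links$up$reads, links$dn$reads),
      support_samples = min(links$up$samples, links$dn$samples),
      detail = sprintf("island=%d-%d;up=%d-%d;down=%d-%d", isl$start,
                       isl$end, links$up$start, links$up$end,
                       links$dn$start, links$dn$end))
  }
  if (!length(events)) return(.empty_events())
  .number_events(do.call(rbind, events), prefix = "X")
}

#' Apply new-exon events to a model set
#'
#' Inserts each recovered exon into its transcript, increasing the exon
#' count by one per event.
#'
#' @param models a `gene_model_set`.
#' @param events event data frame (type `new_exon`).
#' @return revised `gene_model_set`.
#' @export
apply_new_exon_events <- function(models, events) {
  events <- events[events$event_type == "new_exon", , drop = FALSE]
  txs <- models$transcripts
  for (i in seq_len(nrow(events))) {
    tid <- events$transcript_id[i]
    tx <- txs[[tid]]
    if (is.null(tx)) stop("event references unknown transcript ", tid)
    ex <- rbind(tx$exons, c(events$new_start[i], events$new_end[i]))
    txs[[tid]] <- transcript_model(tx$transcript_id, tx$gene_id, tx$chrom,
                                   tx$strand, ex, cds = tx$cds,
                                   frame = tx$frame, attrs = tx$attrs)
  }
  gene_model_set(txs, provenance = "revised")
}

#' Assemble novel intergenic transcripts from island chains
#'
#' Builds maximal chains of islands connected consecutively by supported
#' canonical junctions, keeps chains of at least
#' `min_new_transcript_exons` islands whose span overlaps no annotated
#' transcript span on either strand, and snaps exon boundaries to the
#' linking junctions.
#'
#' @param islands island data frame from [call_coverage_islands()].
#' @param junctions a `junction_table`.
#' @param models a `gene_model_set` (defines intergenic space).
#' @param genome a `genome_sequence`.
#' @param config a `refinement_config`.
#' @return list with `events` (type `new_transcript`, one per assembled
#'   transcript; `detail` carries the exon chain) and `transcripts` (a list
#'   of `transcript_model` objects with provisional ids).
#' @export
assemble_new_transcripts <- function(islands, junctions, models, genome,
                                     config) {
  sp <- model_spans(models)
  intergenic <- vapply(seq_len(nrow(islands)), function(i) {
    s <- islands[i, ]
    !any(sp$chrom == s$chrom & sp$start < s$end & sp$end > s$start)
  }, logical(1))
  isl <- islands[intergenic, , drop = FALSE]
  events <- list(); new_txs <- list(); counter <- 0L
  for (cn in unique(isl$chrom)) {
    for (st in unique(isl$strand[isl$chrom == cn])) {
      sub <- isl[isl$chrom == cn & isl$strand == st, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      if (!nrow(sub)) next
      jx <- .linking_junctions(junctions, genome, cn, st, config)
      n <- nrow(sub)
      # link[i]: best junction joining island i to island i+1, or NULL
      link <- vector("list", n)
      for (i in seq_len(n - 1L)) {
        cand <- jx[jx$start > sub$start[i] & jx$start <= sub$end[i] &
                     jx$end >= sub$start[i + 1L] & jx$end < sub$end[i + 1L], ,
                   drop = FALSE]
        if (nrow(cand))
          link[[i]] <- cand[order(-cand$reads, cand$start), ,
                            drop = FALSE][1L, ]
      }
      i <- 1L
      while (i <= n) {
        j <- i
        while (j < n && !is.null(link[[j]])) j <- j + 1L
        chain <- i:j
        if (length(chain) >= config$min_new_transcript_exons) {
          exons <- matrix(0L, nrow = length(chain), ncol = 2L)
          exons[1L, 1L] <- sub$start[chain[1L]]
          exons[length(chain), 2L] <- sub$end[chain[length(chain)]]
          for (k in seq_len(length(chain) - 1L)) {
            ln <- link[[chain[k]]]
            exons[k, 2L] <- ln$start
            exons[k + 1L, 1L] <- ln$end
          }
          span_ok <- !any(sp$chrom == cn & sp$start < exons[length(chain), 2L] &
                            sp$end > exons[1L, 1L])
          if (span_ok) {
            counter <- counter + 1L
            tid <- sprintf("NOVEL_%04d", counter)
            reads <- vapply(chain[-length(chain)],
                            function(k) link[[k]]$reads, numeric(1))
            samples <- vapply(chain[-length(chain)],
                              function(k) link[[k]]$samples, numeric(1))
            new_txs[[tid]] <- transcript_model(tid, tid, cn, st, exons)
            events[[length(events) + 1L]] <- .event_row(
              "new_transcript", tid, cn, st,
              NA_integer_, NA_integer_, exons[1L, 1L],
              exons[length(chain), 2L],
              support_reads = min(reads), support_samples = min(samples),
              detail = paste(sprintf("%d-%d", exons[, 1L], exons[, 2L]),
                             collapse = ","))
          }
        }
        i <- j + 1L
      }
    }
  }
  ev <- if (length(events)) {
    .number_events(do.call(rbind, events), prefix = "N")
  } else .empty_events()
  list(events = ev, transcripts = new_txs)
}

#' Cluster novel transcripts into genes
#'
#' Single-linkage clustering where two transcripts are linked when they
#' share a splice junction or overlap exonically by at least one base on
#' the same strand. Implemented as union-find over the linkage pairs;
#' cluster ids are deterministic (ordered by leftmost member).
#'
#' @param new_transcripts list of `transcript_model`s.
#' @return named character vector: gene (cluster) id per transcript id.
#' @export
cluster_new_transcripts <- function(new_transcripts) {
  n <- length(new_transcripts)
  if (!n) return(character(0))
  ids <- vapply(new_transcripts, `[[`, character(1), "transcript_id")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  jsets <- lapply(new_transcripts, function(t) {
    intr <- introns_of(t)
    if (!nrow(intr)) character(0)
    else .jx_key(intr$chrom, intr$start, intr$end, intr$strand)
  })
  for (i in seq_len(n - 1L)) {
    ti <- new_transcripts[[i]]
    for (j in (i + 1L):n) {
      tj <- new_transcripts[[j]]
      linked <- length(intersect(jsets[[i]], jsets[[j]])) > 0L
      if (!linked && ti$chrom == tj$chrom && ti$strand == tj$strand) {
        for (a in seq_len(nrow(ti$exons))) {
          if (any(tj$exons[, 1L] < ti$exons[a, 2L] &
                    tj$exons[, 2L] > ti$exons[a, 1L])) {
            linked <- TRUE; break
          }
        }
      }
      if (linked) union2(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  cluster_ids <- sprintf("NOVELG_%04d", match(roots, unique(roots)))
  stats::setNames(cluster_ids, ids)
}
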