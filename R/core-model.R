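#' gmrefine: RNA-Seq-guided refinement of gene models
#'
#' Tools to revise putative gene annotations against strand-specific RNA-Seq
#' evidence, audit the consequences for annotated open reading frames, and
#' evaluate the revisions with motif, coverage and conservation statistics.
#' All internal coordinates are 0-based half-open on the forward genomic
#' strand; GTF input/output converts to and from the 1-based closed GTF
#' convention, while BED and bedGraph are native 0-based half-open.
#'
#' @keywords internal
#' @aliases gmrefine-package
"_PACKAGE"

## ---- genome sequence ------------------------------------------------------

#' Construct a genome sequence object
#'
#' A genome is a named set of chromosome sequences over the alphabet
#' A, C, G, T, N (uppercased on construction). Base lookups are 0-based.
#'
#' @param sequences named character vector, one DNA string per chromosome.
#' @return an object of class `genome_sequence`.
#' @export
genome_sequence <- function(sequences) {
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == ""))
    stop("every chromosome sequence must be named")
  if (anyDuplicated(names(sequences)))
    stop("duplicated chromosome names")
  sequences <- vapply(sequences, toupper, character(1))
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("non-ACGTN characters in sequence of ", names(sequences)[bad][1])
  structure(list(seq = sequences, lengths = nchar(sequences)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("<genome_sequence> ", length(x$seq), " chromosome(s), ",
      format(sum(x$lengths), big.mark = ","), " bases\n", sep = "")
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome a `genome_sequence`.
#' @return named integer vector of chromosome lengths.
#' @export
chrom_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_sequence"))
  genome$lengths
}

#' Extract a forward-strand subsequence
#'
#' @param genome a `genome_sequence`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @return character scalar (forward strand).
#' @export
genome_subseq <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "genome_sequence"))
  if (!chrom %in% names(genome$seq)) stop("unknown chromosome: ", chrom)
  len <- genome$lengths[[chrom]]
  if (start < 0 || end > len || start >= end)
    stop(sprintf("interval [%d,%d) out of bounds for %s (length %d)",
                 start, end, chrom, len))
  substr(genome$seq[[chrom]], start + 1L, end)
}

#' Reverse-complement a DNA string
#' @param s character scalar over A,C,G,T,N.
#' @return the reverse complement, same case.
#' @export
revcomp <- function(s) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         vapply(s, function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

## ---- transcript model -----------------------------------------------------

#' Construct a transcript model
#'
#' A stranded, exon-structured transcript, the unit being refined. Exons are
#' given as a two-column matrix of 0-based half-open intervals on one
#' chromosome; they are sorted on construction and must be pairwise
#' non-overlapping with at least one intronic base between consecutive exons.
#' An optional CDS is a set of sub-intervals of the exons, with the frame
#' offset of the first coding base (0, 1 or 2 in transcription sense).
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column numeric matrix (start, end), 0-based half-open.
#' @param cds optional two-column matrix of CDS intervals, each contained in
#'   an exon.
#' @param frame frame offset of the first coding base (default 0).
#' @param attrs opaque GTF attribute text carried through I/O (optional).
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds = NULL, frame = 0L, attrs = "") {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stop("transcript needs at least one exon")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 1L] >= exons[, 2L]))
    stop("empty or inverted exon in transcript ", transcript_id)
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] <= exons[-nrow(exons), 2L]))
    stop("overlapping or abutting exons in transcript ", transcript_id)
  if (!is.null(cds)) {
    cds <- matrix(as.integer(cds), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
    cds <- cds[order(cds[, 1L]), , drop = FALSE]
    if (any(cds[, 1L] >= cds[, 2L])) stop("empty CDS interval")
    for (i in seq_len(nrow(cds))) {
      inside <- any(exons[, 1L] <= cds[i, 1L] & cds[i, 2L] <= exons[, 2L])
      if (!inside)
        stop("CDS interval not contained in an exon of ", transcript_id)
    }
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons, cds = cds,
                 frame = as.integer(frame), attrs = attrs),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s:%d-%d(%s) %d exon(s)%s\n",
              x$transcript_id, x$gene_id, x$chrom, x$exons[1L, 1L],
              x$exons[nrow(x$exons), 2L], x$strand, nrow(x$exons),
              if (is.null(x$cds)) "" else sprintf(", CDS %d segment(s)",
                                                 nrow(x$cds))))
  invisible(x)
}

#' Genomic span of a transcript
#' @param tx a `transcript_model`.
#' @return integer vector `c(start, end)`, 0-based half-open.
#' @export
tx_span <- function(tx) {
  c(start = unname(tx$exons[1L, 1L]),
    end = unname(tx$exons[nrow(tx$exons), 2L]))
}

#' Introns of a transcript
#'
#' One row per gap between consecutive exons, in genomic order. For an
#' n-exon transcript this yields n - 1 splice-site keys.
#'
#' @param tx a `transcript_model`.
#' @return data frame with columns chrom, start, end (0-based half-open
#'   intron coordinates) and strand; zero rows for single-exon transcripts.
#' @export
introns_of <- function(tx) {
  n <- nrow(tx$exons)
  if (n < 2L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  data.frame(chrom = tx$chrom,
             start = tx$exons[-n, 2L],
             end = tx$exons[-1L, 1L],
             strand = tx$strand,
             stringsAsFactors = FALSE)
}

## ---- gene model set -------------------------------------------------------

#' Construct a gene model set
#'
#' A collection of transcripts indexed by id, with an interval index for
#' overlap queries.
#'
#' @param transcripts list of `transcript_model` objects.
#' @param provenance `"putative"` or `"revised"`.
#' @return an object of class `gene_model_set`.
#' @export
gene_model_set <- function(transcripts, provenance = "putative") {
  stopifnot(is.list(transcripts))
  ids <- vapply(transcripts, function(t) t$transcript_id, character(1))
  if (anyDuplicated(ids)) stop("duplicated transcript ids: ",
                               paste(unique(ids[duplicated(ids)]),
                                     collapse = ", "))
  names(transcripts) <- ids
  structure(list(transcripts = transcripts, provenance = provenance),
            class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("<gene_model_set> %d transcript(s), provenance: %s\n",
              length(x$transcripts), x$provenance))
  invisible(x)
}

#' @export
length.gene_model_set <- function(x) length(x$transcripts)

#' Span table of a gene model set
#' @param models a `gene_model_set`.
#' @return data frame: transcript_id, gene_id, chrom, start, end, strand.
#' @export
model_spans <- function(models) {
  txs <- models$transcripts
  data.frame(
    transcript_id = vapply(txs, `[[`, character(1), "transcript_id"),
    gene_id = vapply(txs, `[[`, character(1), "gene_id"),
    chrom = vapply(txs, `[[`, character(1), "chrom"),
    start = vapply(txs, function(t) t$exons[1L, 1L], integer(1)),
    end = vapply(txs, function(t) t$exons[nrow(t$exons), 2L], integer(1)),
    strand = vapply(txs, `[[`, character(1), "strand"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Transcripts whose span overlaps a query interval
#'
#' Uses an IRanges overlap index; strand `NA` matches both strands.
#'
#' @param models a `gene_model_set`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open query interval.
#' @param strand `"+"`, `"-"` or `NA` for either.
#' @return character vector of transcript ids (sorted).
#' @export
overlapping_transcripts <- function(models, chrom, start, end, strand = NA) {
  sp <- model_spans(models)
  sp <- sp[sp$chrom == chrom, , drop = FALSE]
  if (!is.na(strand)) sp <- sp[sp$strand == strand, , drop = FALSE]
  if (nrow(sp) == 0L) return(character(0))
  # 0-based half-open -> 1-based closed for IRanges
  subject <- IRanges::IRanges(start = sp$start + 1L, end = sp$end)
  query <- IRanges::IRanges(start = start + 1L, end = end)
  hits <- IRanges::findOverlaps(query, subject)
  sort(sp$transcript_id[S4Vectors::subjectHits(hits)])
}

#' All annotated exons of a model set
#' @param models a `gene_model_set`.
#' @return data frame: transcript_id, chrom, start, end, strand (one row per
#'   exon, 0-based half-open).
#' @export
model_exons <- function(models) {
  rows <- lapply(models$transcripts, function(t)
    data.frame(transcript_id = t$transcript_id, chrom = t$chrom,
               start = t$exons[, 1L], end = t$exons[, 2L], strand = t$strand,
               stringsAsFactors = FALSE))
  if (!length(rows))
    return(data.frame(transcript_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Unique splice-junction keys of a model set
#'
#' @param models a `gene_model_set`.
#' @return data frame: chrom, start, end, strand — one row per distinct
#'   intron (0-based half-open).
#' @export
junction_keys <- function(models) {
  rows <- lapply(models$transcripts, introns_of)
  if (!length(rows))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  unique(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
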