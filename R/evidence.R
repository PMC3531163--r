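## Expression evidence: per-sample strand-specific base coverage, junction
## read counts, and splice dinucleotide interrogation.

#' Construct a coverage track
#'
#' Per-sample, per-strand base-level read depth, stored densely per
#' chromosome. Positions absent from the source bedGraph are depth 0.
#'
#' @param sample_id sample identifier.
#' @param strand `"+"` or `"-"` (library strand of the track).
#' @param depth named list of non-negative numeric vectors, one per
#'   chromosome.
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(sample_id, strand, depth) {
  stopifnot(strand %in% c("+", "-"), is.list(depth))
  if (any(vapply(depth, function(d) any(d < 0), logical(1))))
    stop("negative depth in coverage track")
  structure(list(sample_id = sample_id, strand = strand, depth = depth),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> sample %s strand %s, %d chromosome(s)\n",
              x$sample_id, x$strand, length(x$depth)))
  invisible(x)
}

#' Load a bedGraph file as a coverage track
#' @param path bedGraph file.
#' @param sample_id sample identifier.
#' @param strand `"+"` or `"-"`.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return a `coverage_track`.
#' @export
load_bedgraph <- function(path, sample_id, strand, chrom_lengths) {
  coverage_track(sample_id, strand, read_bedgraph(path, chrom_lengths))
}

#' Depth over a window of a coverage track
#' @param track a `coverage_track`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open window.
#' @return numeric vector of per-base depths, length `end - start`.
#' @export
depth_window <- function(track, chrom, start, end) {
  d <- track$depth[[chrom]]
  if (is.null(d)) stop("no coverage for chromosome ", chrom)
  if (start < 0 || end > length(d) || start >= end)
    stop("window out of bounds")
  d[(start + 1L):end]
}

#' Pooled depth over a window, summed across tracks of one strand
#' @param tracks list of `coverage_track`s.
#' @param strand strand to pool.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open window.
#' @return numeric vector of pooled per-base depths.
#' @export
pooled_depth <- function(tracks, strand, chrom, start, end) {
  sel <- Filter(function(t) t$strand == strand, tracks)
  if (!length(sel)) return(numeric(end - start))
  Reduce(`+`, lapply(sel, depth_window, chrom, start, end))
}

## ---- junction table -------------------------------------------------------

.jx_key <- function(chrom, start, end, strand)
  paste(chrom, start, end, strand, sep = ":")

#' Construct a splice-junction evidence table
#'
#' Records are (junction key, sample, read count >= 1); the (key, sample)
#' pair must be unique. An aggregate index (total reads and number of
#' samples with reads per key) is precomputed for queries.
#'
#' @param records data frame with columns chrom, start, end, strand, sample,
#'   reads (0-based half-open intron coordinates).
#' @return an object of class `junction_table`.
#' @export
junction_table <- function(records) {
  need <- c("chrom", "start", "end", "strand", "sample", "reads")
  stopifnot(all(need %in% names(records)))
  if (nrow(records) && any(records$reads < 1L))
    stop("junction read counts must be >= 1")
  key <- .jx_key(records$chrom, records$start, records$end, records$strand)
  if (anyDuplicated(paste(key, records$sample)))
    stop("duplicate (junction, sample) record")
  if (nrow(records)) {
    totals <- rowsum(records$reads, key)
    nsamp <- rowsum(rep(1L, nrow(records)), key)
    first <- !duplicated(key)
    agg <- data.frame(chrom = records$chrom[first],
                      start = records$start[first],
                      end = records$end[first],
                      strand = records$strand[first],
                      key = key[first], stringsAsFactors = FALSE)
    agg$reads <- totals[agg$key, 1L]
    agg$samples <- nsamp[agg$key, 1L]
  } else {
    agg <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      key = character(0), reads = integer(0),
                      samples = integer(0))
  }
  structure(list(records = records, agg = agg), class = "junction_table")
}

#' @export
print.junction_table <- function(x, ...) {
  cat(sprintf("<junction_table> %d record(s), %d distinct junction(s)\n",
              nrow(x$records), nrow(x$agg)))
  invisible(x)
}

#' Total read support for one junction
#'
#' @param junctions a `junction_table`.
#' @param chrom,start,end,strand the junction key (0-based half-open intron).
#' @return integer vector `c(reads, samples)`: total reads summed over
#'   samples and the number of samples with at least one read; `c(0, 0)` for
#'   an absent key.
#' @export
junction_support <- function(junctions, chrom, start, end, strand) {
  i <- match(.jx_key(chrom, start, end, strand), junctions$agg$key)
  if (is.na(i)) return(c(reads = 0L, samples = 0L))
  c(reads = junctions$agg$reads[i], samples = junctions$agg$samples[i])
}

#' Junctions intersecting a genomic region
#'
#' @param junctions a `junction_table`.
#' @param chrom chromosome.
#' @param start,end 0-based half-open region.
#' @param strand `"+"`, `"-"` or `NA` for either.
#' @return aggregate data frame (chrom, start, end, strand, reads, samples)
#'   of junctions whose intron intersects the region.
#' @export
junctions_in_region <- function(junctions, chrom, start, end, strand = NA) {
  a <- junctions$agg
  sel <- a$chrom == chrom & a$start < end & a$end > start
  if (!is.na(strand)) sel <- sel & a$strand == strand
  a[sel, c("chrom", "start", "end", "strand", "reads", "samples"),
    drop = FALSE]
}

## ---- splice dinucleotides -------------------------------------------------

.canonical_pairs <- c("GT-AG", "GC-AG", "AT-AC")

#' Donor and acceptor dinucleotides of an intron
#'
#' Reports both 2-mers in transcription sense: on the minus strand the
#' donor is the reverse complement of the intron's 3' genomic end and the
#' acceptor the reverse complement of its 5' genomic end.
#'
#' @param genome a `genome_sequence`.
#' @param chrom,start,end,strand the intron (0-based half-open, length >= 4).
#' @return list with `donor`, `acceptor` (2-character strings) and
#'   `canonical` (TRUE iff the pair is GT-AG, GC-AG or AT-AC).
#' @export
splice_dinucleotides <- function(genome, chrom, start, end, strand) {
  if (end - start < 4L) stop("intron shorter than 4 bases")
  left <- genome_subseq(genome, chrom, start, start + 2L)
  right <- genome_subseq(genome, chrom, end - 2L, end)
  if (strand == "+") {
    donor <- left; acceptor <- right
  } else {
    donor <- revcomp(right); acceptor <- revcomp(left)
  }
  list(donor = donor, acceptor = acceptor,
       canonical = paste(donor, acceptor, sep = "-") %in% .canonical_pairs)
}
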