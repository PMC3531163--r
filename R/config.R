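#' Refinement configuration
#'
#' Every numeric threshold used by the refinement procedures. Defaults are
#' the evidence criteria of the strict rule set: a revised splice model needs
#' at least two junction-spanning reads while the previous model has none;
#' splice dinucleotides must be canonical (GT-AG, GC-AG or AT-AC); revised
#' flanking exons must be 80-120% of the annotated exon length; UTR extension
#' walks stop where depth drops below 15 in at least two samples (with the
#' identical-coverage-run average also below 15 in every sample) and
#' extensions shorter than 100 bases are discarded; novel exons must overlap
#' annotated exons by less than 30% of their length; a novel transcript needs
#' at least two exons connected by supported junctions. The coverage-island
#' caller that stands in for an external assembler uses `island_min_depth`
#' (pooled depth) and `island_min_length`.
#'
#' @param min_junction_reads minimum total junction-spanning reads.
#' @param allowed_pairs canonical splice dinucleotide pairs.
#' @param exon_len_ratio closed interval for revised/annotated exon length.
#' @param utr_depth_threshold depth below which a base counts as low.
#' @param utr_min_low_samples number of low samples required to stop.
#' @param utr_min_extension minimum extension length (bases) to report.
#' @param island_min_depth minimum pooled depth inside a coverage island.
#' @param island_min_length minimum island length (bases).
#' @param new_exon_max_overlap maximum annotated-exon overlap, as a fraction
#'   of the new exon length (exclusive bound).
#' @param min_new_transcript_exons minimum exons in a novel transcript.
#' @return an object of class `refinement_config`.
#' @export
refinement_config <- function(min_junction_reads = 2L,
                              allowed_pairs = c("GT-AG", "GC-AG", "AT-AC"),
                              exon_len_ratio = c(0.80, 1.20),
                              utr_depth_threshold = 15,
                              utr_min_low_samples = 2L,
                              utr_min_extension = 100L,
                              island_min_depth = 5,
                              island_min_length = 50L,
                              new_exon_max_overlap = 0.30,
                              min_new_transcript_exons = 2L) {
  stopifnot(min_junction_reads >= 1L, utr_min_low_samples >= 1L,
            utr_min_extension >= 1L, island_min_length >= 1L,
            min_new_transcript_exons >= 1L,
            length(exon_len_ratio) == 2L,
            exon_len_ratio[1L] <= 1, exon_len_ratio[2L] >= 1,
            new_exon_max_overlap > 0, new_exon_max_overlap <= 1)
  structure(list(min_junction_reads = as.integer(min_junction_reads),
                 allowed_pairs = allowed_pairs,
                 exon_len_ratio = as.numeric(exon_len_ratio),
                 utr_depth_threshold = utr_depth_threshold,
                 utr_min_low_samples = as.integer(utr_min_low_samples),
                 utr_min_extension = as.integer(utr_min_extension),
                 island_min_depth = island_min_depth,
                 island_min_length = as.integer(island_min_length),
                 new_exon_max_overlap = new_exon_max_overlap,
                 min_new_transcript_exons = as.integer(min_new_transcript_exons)),
            class = "refinement_config")
}

#' @export
print.refinement_config <- function(x, ...) {
  cat("<refinement_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-26s %s\n", nm, paste(format(v), collapse = " ")))
  }
  invisible(x)
}

.pair_ok <- function(dinuc, config)
  paste(dinuc$donor, dinuc$acceptor, sep = "-") %in% config$allowed_pairs
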