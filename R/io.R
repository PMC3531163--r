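## File readers and writers: FASTA, GTF (Ensembl dialect), BED6, bedGraph,
## junction TSV. All writers are deterministic byte-for-byte given the same
## inputs. GTF is 1-based closed on disk, everything else 0-based half-open.

#' Read a genome FASTA file
#' @param path FASTA file.
#' @return a `genome_sequence`.
#' @export
read_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(dss)
  # Ensembl-style headers may carry descriptions: keep first token
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_sequence(seqs)
}

#' Write a genome FASTA file
#' @param genome a `genome_sequence`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(dss, path, width = 70L)
  invisible(path)
}

## ---- GTF ------------------------------------------------------------------

.gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(paste0(key, ' "[^"]*"'), attrs))
  if (length(m) == 0L) return(NA_character_)
  sub(paste0(key, ' "([^"]*)"'), "\\1", m)
}

#' Read gene models from a GTF file
#'
#' Ingests Ensembl-style exon (and optional CDS) records. Coordinates are
#' converted from GTF 1-based closed to the internal 0-based half-open
#' convention; exons are grouped per transcript and sorted. Only `gene_id`
#' and `transcript_id` are interpreted; the remaining attribute text is kept
#' opaque and re-emitted by [write_gtf()]. A stated CDS frame for the first
#' coding base is honoured; if absent, frame 0 is assumed.
#'
#' @param path GTF file.
#' @param provenance provenance label for the returned set.
#' @return a `gene_model_set`.
#' @export
read_gtf <- function(path, provenance = "putative") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  ex <- list(); cds <- list(); meta <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop("malformed GTF line ", i, ": expected 9 tab-separated fields")
    feature <- f[3L]
    if (!feature %in% c("exon", "CDS")) next
    start <- suppressWarnings(as.integer(f[4L]))
    end <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start) || is.na(end) || start > end)
      stop("malformed GTF line ", i, ": bad coordinates")
    if (!f[7L] %in% c("+", "-"))
      stop("malformed GTF line ", i, ": bad strand")
    tid <- .gtf_attr(f[9L], "transcript_id")
    gid <- .gtf_attr(f[9L], "gene_id")
    if (is.na(tid) || is.na(gid))
      stop("malformed GTF line ", i, ": missing gene_id/transcript_id")
    rec <- c(start - 1L, end)  # 1-based closed -> 0-based half-open
    if (feature == "exon") {
      ex[[tid]] <- rbind(ex[[tid]], rec)
    } else {
      frame <- suppressWarnings(as.integer(f[8L]))
      cds[[tid]] <- rbind(cds[[tid]], c(rec, if (is.na(frame)) -1L else frame))
    }
    if (is.null(meta[[tid]])) {
      extra <- gsub('\\s*(gene_id|transcript_id) "[^"]*";?', "", f[9L])
      extra <- trimws(extra)
      meta[[tid]] <- list(gene_id = gid, chrom = f[1L], strand = f[7L],
                          attrs = extra)
    }
  }
  txs <- vector("list", length(ex))
  for (k in seq_along(ex)) {
    tid <- names(ex)[k]
    m <- meta[[tid]]
    cm <- cds[[tid]]
    frame <- 0L
    cdsm <- NULL
    if (!is.null(cm)) {
      cm <- cm[order(cm[, 1L]), , drop = FALSE]
      # frame of the first coding base in transcription sense
      fr_row <- if (m$strand == "+") 1L else nrow(cm)
      # GTF frame column is a phase (bases to skip to the next codon start);
      # internally we store the codon offset of the first coding base
      if (cm[fr_row, 3L] >= 0L) frame <- (3L - cm[fr_row, 3L]) %% 3L
      cdsm <- cm[, 1:2, drop = FALSE]
    }
    txs[[k]] <- tryCatch(
      transcript_model(tid, m$gene_id, m$chrom, m$strand,
                       ex[[tid]], cds = cdsm, frame = frame,
                       attrs = m$attrs),
      error = function(e) stop("rejecting transcript ", tid, ": ",
                               conditionMessage(e), call. = FALSE))
  }
  gene_model_set(txs, provenance = provenance)
}

#' Write gene models to a GTF file
#'
#' Transcripts are emitted in (chrom, span start, transcript_id) order; exon
#' lines of each transcript are in ascending genomic order regardless of
#' strand. `read_gtf(write_gtf(x))` is the identity on the data model.
#'
#' @param models a `gene_model_set`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gtf <- function(models, path) {
  sp <- model_spans(models)
  ord <- order(sp$chrom, sp$start, sp$transcript_id)
  out <- character(0)
  for (tid in sp$transcript_id[ord]) {
    tx <- models$transcripts[[tid]]
    base_attr <- sprintf('gene_id "%s"; transcript_id "%s";',
                         tx$gene_id, tx$transcript_id)
    attr_txt <- if (nzchar(tx$attrs)) paste(base_attr, tx$attrs) else base_attr
    for (i in seq_len(nrow(tx$exons)))
      out <- c(out, paste(tx$chrom, "gmrefine", "exon",
                          tx$exons[i, 1L] + 1L, tx$exons[i, 2L], ".",
                          tx$strand, ".", attr_txt, sep = "\t"))
    if (!is.null(tx$cds)) {
      frames <- .cds_frames(tx)
      for (i in seq_len(nrow(tx$cds)))
        out <- c(out, paste(tx$chrom, "gmrefine", "CDS",
                            tx$cds[i, 1L] + 1L, tx$cds[i, 2L], ".",
                            tx$strand, frames[i], attr_txt, sep = "\t"))
    }
  }
  writeLines(out, path)
  invisible(path)
}

## per-row GTF frame column from the first-coding-base frame offset
.cds_frames <- function(tx) {
  n <- nrow(tx$cds)
  lens <- tx$cds[, 2L] - tx$cds[, 1L]
  ord <- if (tx$strand == "+") seq_len(n) else rev(seq_len(n))
  # GTF frame is the count of bases to skip before the first full codon
  fr2 <- integer(n); acc <- tx$frame
  for (i in ord) {
    fr2[i] <- (3L - acc %% 3L) %% 3L
    acc <- acc + lens[i]
  }
  fr2
}

## ---- bedGraph -------------------------------------------------------------

#' Read a bedGraph file into per-chromosome dense vectors
#'
#' Positions not covered by any interval get value 0. Overlapping intervals
#' are an error.
#'
#' @param path bedGraph file (track lines ignored).
#' @param chrom_lengths named integer vector of chromosome lengths; every
#'   chromosome named here gets a dense vector.
#' @return named list of numeric vectors, one per chromosome.
#' @export
read_bedgraph <- function(path, chrom_lengths) {
  out <- lapply(chrom_lengths, function(n) numeric(n))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track") & !startsWith(lines, "#") &
                   nzchar(lines)]
  if (length(lines)) {
    f <- strsplit(lines, "\t", fixed = TRUE)
    chrom <- vapply(f, `[[`, character(1), 1L)
    start <- as.integer(vapply(f, `[[`, character(1), 2L))
    end <- as.integer(vapply(f, `[[`, character(1), 3L))
    val <- as.numeric(vapply(f, `[[`, character(1), 4L))
    for (cn in unique(chrom)) {
      sel <- chrom == cn
      if (!cn %in% names(out)) stop("undeclared chromosome in bedGraph: ", cn)
      o <- order(start[sel])
      s <- start[sel][o]; e <- end[sel][o]; v <- val[sel][o]
      if (length(s) > 1L && any(s[-1L] < e[-length(e)])) {
        i <- which(s[-1L] < e[-length(e)])[1L]
        stop(sprintf("overlapping bedGraph intervals on %s near %d", cn, s[i + 1L]))
      }
      if (e[length(e)] > chrom_lengths[[cn]])
        stop("bedGraph interval beyond chromosome end on ", cn)
      for (i in seq_along(s)) out[[cn]][(s[i] + 1L):e[i]] <- v[i]
    }
  }
  out
}

#' Write per-chromosome dense vectors as bedGraph
#'
#' Zero-valued runs are omitted; output is sorted by chromosome then start.
#'
#' @param values named list of numeric vectors.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bedgraph <- function(values, path) {
  out <- character(0)
  for (cn in sort(names(values))) {
    r <- rle(values[[cn]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      out <- c(out, paste(cn, starts[keep], ends[keep],
                          format(r$values[keep], trim = TRUE,
                                 scientific = FALSE), sep = "\t"))
  }
  writeLines(out, path)
  invisible(path)
}

## ---- BED ------------------------------------------------------------------

#' Read a BED file (3-6 columns)
#' @param path BED file.
#' @return data frame: chrom, start, end, and when present name, score,
#'   strand (0-based half-open).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track") & !startsWith(lines, "#") &
                   nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- min(lengths(f))
  df <- data.frame(chrom = vapply(f, `[[`, character(1), 1L),
                   start = as.integer(vapply(f, `[[`, character(1), 2L)),
                   end = as.integer(vapply(f, `[[`, character(1), 3L)),
                   stringsAsFactors = FALSE)
  if (ncol >= 4L) df$name <- vapply(f, `[[`, character(1), 4L)
  if (ncol >= 5L) df$score <- as.numeric(vapply(f, `[[`, character(1), 5L))
  if (ncol >= 6L) df$strand <- vapply(f, `[[`, character(1), 6L)
  df
}

## ---- junction TSV ---------------------------------------------------------

#' Read a splice-junction evidence table
#'
#' Tab-separated with a header line and columns chrom, intron_start,
#' intron_end, strand, sample, read_count. Intron coordinates are 0-based
#' half-open; read counts must be >= 1.
#'
#' @param path TSV file.
#' @return a `junction_table`.
#' @export
read_junction_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "intron_start", "intron_end", "strand", "sample",
            "read_count")
  if (!all(need %in% names(df)))
    stop("junction TSV must have columns: ", paste(need, collapse = ", "))
  junction_table(data.frame(chrom = df$chrom,
                            start = as.integer(df$intron_start),
                            end = as.integer(df$intron_end),
                            strand = df$strand, sample = df$sample,
                            reads = as.integer(df$read_count),
                            stringsAsFactors = FALSE))
}

#' Write a splice-junction evidence table
#' @param junctions a `junction_table`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_junction_tsv <- function(junctions, path) {
  df <- junctions$records
  df <- df[order(df$chrom, df$start, df$end, df$strand, df$sample), ]
  out <- data.frame(chrom = df$chrom, intron_start = df$start,
                    intron_end = df$end, strand = df$strand,
                    sample = df$sample, read_count = df$reads)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
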