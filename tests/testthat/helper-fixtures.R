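# Fixture builders and independent brute-force oracles used across tests.

# genome with a fixed sequence on one chromosome
toy_genome <- function(seq, chrom = "chr1") {
  genome_sequence(stats::setNames(seq, chrom))
}

# random genome of length n (uppercase ACGT)
random_genome <- function(n, chrom = "chr1", seed = 1) {
  set.seed(seed)
  toy_genome(paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""),
             chrom)
}

toy_tx <- function(id, exons, strand = "+", chrom = "chr1", gene = NULL,
                   cds = NULL, attrs = "") {
  transcript_model(id, gene %||% paste0("g_", id), chrom, strand,
                   matrix(as.integer(exons), ncol = 2, byrow = TRUE),
                   cds = if (is.null(cds)) NULL
                   else matrix(as.integer(cds), ncol = 2, byrow = TRUE),
                   attrs = attrs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coverage track with constant depth over given intervals, 0 elsewhere
toy_track <- function(sample_id, strand, chrom_len, intervals = NULL,
                      chrom = "chr1") {
  d <- numeric(chrom_len)
  if (!is.null(intervals))
    for (i in seq_len(nrow(intervals)))
      d[(intervals[i, 1] + 1):intervals[i, 2]] <- intervals[i, 3]
  coverage_track(sample_id, strand, stats::setNames(list(d), chrom))
}

toy_junctions <- function(...) {
  # each argument: c(start, end, reads) or list(chrom, start, end, strand,
  # sample, reads); default chrom chr1, strand +, one sample per call
  args <- list(...)
  rows <- lapply(seq_along(args), function(i) {
    a <- args[[i]]
    data.frame(chrom = "chr1", start = a[[1]], end = a[[2]], strand = "+",
               sample = paste0("s", i), reads = a[[3]],
               stringsAsFactors = FALSE)
  })
  junction_table(do.call(rbind, rows))
}

# write a genome with planted canonical splice sites for a transcript set
plant_splice_sites <- function(genome, models, donor = "GT") {
  chars <- strsplit(genome$seq, "", fixed = TRUE)
  for (tx in models$transcripts) {
    intr <- introns_of(tx)
    for (i in seq_len(nrow(intr))) {
      s <- intr$start[i]; e <- intr$end[i]
      if (tx$strand == "+") {
        chars[[tx$chrom]][(s + 1):(s + 2)] <- strsplit(donor, "")[[1]]
        chars[[tx$chrom]][(e - 1):e] <- c("A", "G")
      } else {
        chars[[tx$chrom]][(e - 1):e] <- strsplit(revcomp(donor), "")[[1]]
        chars[[tx$chrom]][(s + 1):(s + 2)] <- c("C", "T")
      }
    }
  }
  genome_sequence(vapply(chars, paste, character(1), collapse = ""))
}

## ---- independent oracles ---------------------------------------------------

# junction support by linear scan over the raw records
oracle_junction_support <- function(records, chrom, start, end, strand) {
  sel <- records$chrom == chrom & records$start == start &
    records$end == end & records$strand == strand
  c(reads = sum(records$reads[sel]), samples = sum(sel))
}

# coverage islands by per-base brute force on the pooled vector
oracle_islands <- function(pooled, min_depth, min_len) {
  ok <- pooled >= min_depth
  out <- NULL
  i <- 1
  n <- length(ok)
  while (i <= n) {
    if (ok[i]) {
      j <- i
      while (j < n && ok[j + 1]) j <- j + 1
      # 1-based run i..j is 0-based half-open [i-1, j)
      if (j - i + 1 >= min_len) out <- rbind(out, c(i - 1, j))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# longest ORF by naive nested loops over all frames and start positions
oracle_longest_orf <- function(s) {
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- list(start = NA_integer_, length_codons = 0L, intact = FALSE)
  for (f in 0:2) {
    p <- 1 + f
    while (p + 2 <= n) {
      if (substr(s, p, p + 2) == "ATG") {
        q <- p
        found <- FALSE
        len <- 0
        while (q + 2 <= n) {
          len <- len + 1
          if (substr(s, q, q + 2) %in% stops) { found <- TRUE; break }
          q <- q + 3
        }
        better <- len > best$length_codons ||
          (len == best$length_codons && found && !best$intact)
        if (better)
          best <- list(start = p - 1L, length_codons = as.integer(len),
                       intact = found)
      }
      p <- p + 3
    }
  }
  best
}

# two-sample rank-sum statistic by all-pairs counting
oracle_ranksum_W <- function(x, y) {
  w <- 0
  for (xi in x) w <- w + sum(xi > y) + 0.5 * sum(xi == y)
  w
}

# base frequencies at given transcription-sense offsets by per-anchor tally
oracle_pfm <- function(genome, keys, side, offsets) {
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0, 4, length(offsets), dimnames = list(bases, offsets))
  for (i in seq_len(nrow(keys))) {
    for (k in seq_along(offsets)) {
      o <- offsets[k]
      if (side == "donor") {
        pos <- if (keys$strand[i] == "+") keys$start[i] + o
        else keys$end[i] - 1 - o
      } else {
        pos <- if (keys$strand[i] == "+") keys$end[i] + o
        else keys$start[i] - 1 - o
      }
      b <- genome_subseq(genome, keys$chrom[i], pos, pos + 1)
      if (keys$strand[i] == "-") b <- chartr("ACGT", "TGCA", b)
      counts[b, k] <- counts[b, k] + 1
    }
  }
  sweep(counts, 2, pmax(colSums(counts), 1), "/")
}

## ---- shared simulated benchmark (computed once per test run) ---------------

.sim_cache <- new.env(parent = emptyenv())

sim_fixture <- function() {
  if (is.null(.sim_cache$ds)) {
    cfg <- sim_config(seed = 42)
    ds <- simulate_dataset(cfg)
    res <- refine(ds$models, ds$evidence)
    .sim_cache$cfg <- cfg
    .sim_cache$ds <- ds
    .sim_cache$res <- res
  }
  list(cfg = .sim_cache$cfg, ds = .sim_cache$ds, res = .sim_cache$res)
}
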