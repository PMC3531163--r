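## Deterministic synthetic fixtures: genome + true gene models with planted
## splice sites, poly(A) signals, ORFs and a conservation track; corrupted
## annotations with a plant ledger; and matching coverage/junction evidence.
## Everything is a pure function of (config, seed).

#' Simulation configuration
#'
#' Defines the synthetic study conditions: genome geometry, gene structure
#' ranges, sequencing depth regime, and how many errors of each category
#' are planted. Defaults give a compact benchmark (two 400-kb chromosomes,
#' 50 genes, 3 samples) whose exonic depth comfortably exceeds the UTR
#' threshold and whose junction reads always satisfy the two-read rule for
#' supported junctions.
#'
#' @param seed integer seed; all generator randomness flows from it.
#' @param n_chroms,chrom_length genome geometry.
#' @param n_genes number of genes (one transcript each).
#' @param exons_per_gene integer range `c(lo, hi)`.
#' @param exon_length,intron_length,intergenic_gap base-length ranges.
#' @param terminal_exon_length range for first/last exons (kept long so UTR
#'   truncations of at least 100 bases remain recoverable).
#' @param n_samples coverage samples per strand.
#' @param exonic_depth mean per-sample depth on true exonic bases.
#' @param intronic_noise mean per-sample depth off exons (0 emulates clean
#'   strand-specific libraries).
#' @param junction_reads per-sample read-count range for true junctions.
#' @param gc_donor_fraction fraction of introns using GC-AG (rest GT-AG).
#' @param polya_offset_range transcription-sense offset range (negative,
#'   relative to the 3'-terminal base) for the planted AATAAA hexamer.
#' @param n_junction_plants,n_utr5_plants,n_utr3_plants,n_new_exon_plants,n_new_transcript_plants
#'   satisfiable planted errors per category.
#' @param frameshift_pair_fraction fraction of junction plants planted as
#'   frame-restoring pairs (two shifts on one transcript whose exonic
#'   deltas cancel modulo 3).
#' @param plant_decoys also plant one below-threshold decoy per rule.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 400000L,
                       n_genes = 50L,
                       exons_per_gene = c(3L, 6L),
                       exon_length = c(90L, 250L),
                       intron_length = c(70L, 300L),
                       intergenic_gap = c(600L, 1500L),
                       terminal_exon_length = c(250L, 400L),
                       n_samples = 3L,
                       exonic_depth = 30,
                       intronic_noise = 0,
                       junction_reads = c(1L, 4L),
                       gc_donor_fraction = 0.05,
                       polya_offset_range = c(-40L, -15L),
                       n_junction_plants = 6L,
                       n_utr5_plants = 5L,
                       n_utr3_plants = 5L,
                       n_new_exon_plants = 5L,
                       n_new_transcript_plants = 5L,
                       frameshift_pair_fraction = 1 / 3,
                       plant_decoys = TRUE) {
  stopifnot(n_chroms >= 1L, chrom_length >= 10000L, n_genes >= 1L,
            exons_per_gene[1L] >= 2L, n_samples >= 2L,
            exonic_depth > 15 + 5,  # margin above the UTR threshold
            exon_length[1L] >= 60L, intron_length[1L] >= 40L)
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-26s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}

.runif_int <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(seq.int(range[1L], range[2L]), n, replace = TRUE)
}

## overwrite genome characters (char vector per chrom) at 0-based pos
.write_seq <- function(chars, pos0, s) {
  chars[(pos0 + 1L):(pos0 + nchar(s))] <- strsplit(s, "", fixed = TRUE)[[1]]
  chars
}

#' Simulate a genome, true gene models and a conservation track
#'
#' Generates a random genome and lays out non-overlapping genes with
#' canonical splice sites planted at every intron (GT-AG, with a configured
#' fraction of GC-AG donors; minus-strand sites are written in reverse
#' complement), an AATAAA poly(A) signal at a random transcription-sense
#' offset upstream of each 3' end, and an intact ORF spanning the annotated
#' CDS (in-frame internal stop codons are rewritten). The conservation
#' track is high on exons and low elsewhere, with mild noise. Deterministic
#' given the config seed.
#'
#' @param config a `sim_config`.
#' @return list: `genome` (a `genome_sequence`), `models` (true
#'   `gene_model_set`), `conservation` (named list of per-chromosome score
#'   vectors).
#' @export
simulate_genome_and_models <- function(config) {
  set.seed(config$seed)
  chrom_names <- sprintf("chr%d", seq_len(config$n_chroms))
  chars <- lapply(seq_len(config$n_chroms), function(i)
    sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE))
  names(chars) <- chrom_names

  txs <- list()
  cursor <- stats::setNames(rep(1000L, config$n_chroms), chrom_names)
  gi <- 0L
  while (gi < config$n_genes) {
    gi <- gi + 1L
    cn <- chrom_names[(gi - 1L) %% config$n_chroms + 1L]
    strand <- sample(c("+", "-"), 1L)
    n_ex <- .runif_int(1L, config$exons_per_gene)
    # genes reserved for structural decoys get special shapes
    lens <- .runif_int(n_ex, config$exon_length)
    lens[1L] <- .runif_int(1L, config$terminal_exon_length)
    lens[n_ex] <- .runif_int(1L, config$terminal_exon_length)
    ilens <- .runif_int(n_ex - 1L, config$intron_length)
    gap <- .runif_int(1L, config$intergenic_gap)
    start <- cursor[[cn]] + gap
    ex <- matrix(0L, nrow = n_ex, ncol = 2L)
    p <- start
    for (k in seq_len(n_ex)) {
      ex[k, ] <- c(p, p + lens[k])
      p <- p + lens[k] + if (k < n_ex) ilens[k] else 0L
    }
    if (p + 1000L > config$chrom_length)
      stop("chromosome capacity exceeded; reduce n_genes or lengthen chroms")
    cursor[[cn]] <- p
    tid <- sprintf("T%04d", gi)
    # CDS: leave a 30-base 5' UTR and a 60-base 3' UTR (transcription sense)
    u5 <- 30L; u3 <- 60L
    if (strand == "+") {
      cds_lo <- ex[1L, 1L] + u5; cds_hi <- ex[n_ex, 2L] - u3
    } else {
      cds_lo <- ex[1L, 1L] + u3; cds_hi <- ex[n_ex, 2L] - u5
    }
    cds <- NULL
    for (k in seq_len(n_ex)) {
      s <- max(ex[k, 1L], cds_lo); e <- min(ex[k, 2L], cds_hi)
      if (s < e) cds <- rbind(cds, c(s, e))
    }
    txs[[tid]] <- transcript_model(tid, sprintf("G%04d", gi), cn, strand,
                                   ex, cds = cds, frame = 0L)
  }
  models <- gene_model_set(txs, provenance = "truth")

  # plant splice sites, poly(A) signals and ORFs
  for (tx in models$transcripts) {
    intr <- introns_of(tx)
    for (i in seq_len(nrow(intr))) {
      donor <- if (stats::runif(1) < config$gc_donor_fraction) "GC" else "GT"
      if (tx$strand == "+") {
        chars[[tx$chrom]] <- .write_seq(chars[[tx$chrom]], intr$start[i],
                                        donor)
        chars[[tx$chrom]] <- .write_seq(chars[[tx$chrom]], intr$end[i] - 2L,
                                        "AG")
      } else {
        chars[[tx$chrom]] <- .write_seq(chars[[tx$chrom]], intr$end[i] - 2L,
                                        revcomp(donor))
        chars[[tx$chrom]] <- .write_seq(chars[[tx$chrom]], intr$start[i],
                                        "CT")
      }
    }
    # AATAAA at a transcription-sense offset in polya_offset_range
    off <- .runif_int(1L, config$polya_offset_range)
    sp <- tx_span(tx)
    if (tx$strand == "+") {
      a <- sp[["end"]] - 1L
      chars[[tx$chrom]] <- .write_seq(chars[[tx$chrom]], a + off, "AATAAA")
    } else {
      a <- sp[["start"]]
      chars[[tx$chrom]] <- .write_seq(chars[[tx$chrom]], a - off - 5L,
                                      "TTTATT")
    }
  }
  chars <- .plant_orfs(models, chars)
  genome <- genome_sequence(vapply(chars, paste, character(1),
                                   collapse = ""))

  conservation <- lapply(chrom_names, function(cn)
    pmin(pmax(stats::rnorm(config$chrom_length, 0.1, 0.03), 0), 1))
  names(conservation) <- chrom_names
  for (tx in models$transcripts)
    for (k in seq_len(nrow(tx$exons))) {
      idx <- (tx$exons[k, 1L] + 1L):tx$exons[k, 2L]
      conservation[[tx$chrom]][idx] <-
        pmin(pmax(stats::rnorm(length(idx), 0.9, 0.03), 0), 1)
    }

  list(genome = genome, models = models, conservation = conservation)
}

## rewrite each CDS so the spliced coding sequence is ATG ... stop with no
## internal in-frame stop codon
.plant_orfs <- function(models, chars) {
  for (tx in models$transcripts) {
    if (is.null(tx$cds)) next
    # genomic positions of CDS bases in transcription order
    pos <- unlist(lapply(seq_len(nrow(tx$cds)), function(i)
      tx$cds[i, 1L]:(tx$cds[i, 2L] - 1L)))
    if (tx$strand == "-") pos <- rev(pos)
    n <- length(pos)
    if (n < 9L) next
    n_cod <- n %/% 3L
    put <- function(p, base) {
      b <- if (tx$strand == "-") chartr("ACGT", "TGCA", base) else base
      chars[[tx$chrom]][p + 1L] <<- b
    }
    get_codon <- function(ci) {
      idx <- pos[(3L * (ci - 1L) + 1L):(3L * ci)]
      b <- chars[[tx$chrom]][idx + 1L]
      s <- paste(b, collapse = "")
      if (tx$strand == "-") chartr("ACGT", "TGCA", s) else s
    }
    # start codon
    for (k in 1:3) put(pos[k], substr("ATG", k, k))
    # clear internal stops
    for (ci in 2:(n_cod - 1L)) {
      if (get_codon(ci) %in% .stop_codons) {
        idx <- pos[3L * (ci - 1L) + 1L]
        put(idx, "C")
      }
    }
    # terminal stop codon
    for (k in 1:3)
      put(pos[3L * (n_cod - 1L) + k], substr("TAA", k, k))
  }
  chars
}

## ---- corruption -----------------------------------------------------------

#' Corrupt a true annotation, recording a plant ledger
#'
#' Injects, per the configured counts: exon-intron boundary shifts (4-30
#' bases, chosen so the true exon lengths stay within the 80-120% band of
#' the corrupted ones and the corrupted splice site is non-canonical),
#' 5'/3' UTR truncations of at least the minimum reportable extension,
#' internal exon deletions, and whole-transcript deletions (novel
#' transcript plants). A configured fraction of boundary shifts are planted
#' as frame-restoring pairs on one transcript. With `plant_decoys`, one
#' below-threshold decoy per rule is added and flagged unsatisfiable.
#'
#' @param true_models the true `gene_model_set`.
#' @param config a `sim_config`.
#' @param genome the simulated `genome_sequence` (used to keep corrupted
#'   splice sites non-canonical).
#' @param refine_config the `refinement_config` whose thresholds the plants
#'   must satisfy (defaults used otherwise).
#' @return list: `models` (corrupted `gene_model_set`) and `ledger` (data
#'   frame: plant_id, category, rule, transcript_id, chrom, strand,
#'   true_start, true_end, corrupt_start, corrupt_end, delta, satisfiable).
#' @export
corrupt_annotation <- function(true_models, config, genome,
                               refine_config = refinement_config()) {
  set.seed(config$seed + 1L)
  txs <- true_models$transcripts
  ledger <- list()
  add <- function(category, rule, tid, chrom, strand, ts, te, cs, ce,
                  delta, satisfiable) {
    ledger[[length(ledger) + 1L]] <<- data.frame(
      plant_id = sprintf("P%03d", length(ledger) + 1L),
      category = category, rule = rule, transcript_id = tid,
      chrom = chrom, strand = strand,
      true_start = as.integer(ts), true_end = as.integer(te),
      corrupt_start = as.integer(cs), corrupt_end = as.integer(ce),
      delta = as.integer(delta), satisfiable = satisfiable,
      stringsAsFactors = FALSE)
  }

  # eligibility: multi-intron genes for junction plants etc.
  ids <- names(txs)
  n_exons <- vapply(txs, function(t) nrow(t$exons), integer(1))
  pool <- ids[order(ids)]
  take <- function(n, need_exons = 2L) {
    cand <- pool[n_exons[pool] >= need_exons]
    if (length(cand) < n) stop("not enough genes to host requested plants")
    sel <- cand[seq_len(n)]
    pool <<- setdiff(pool, sel)
    sel
  }

  ## -- junction boundary shifts ------------------------------------------
  n_pairs <- floor(config$n_junction_plants *
                     config$frameshift_pair_fraction / 2)
  n_single <- config$n_junction_plants - 2L * n_pairs

  shift_boundary <- function(tx, intron_idx, d_target) {
    # corrupt the donor side by delta bases of exon length change:
    # delta > 0 means the corrupted intron is longer (exon truncated)
    ex <- tx$exons
    old_s <- ex[intron_idx, 2L]; old_e <- ex[intron_idx + 1L, 1L]
    lead_len <- ex[intron_idx, 2L] - ex[intron_idx, 1L]
    cand <- d_target
    for (d in cand) {
      cs <- old_s - d            # corrupted intron start
      if (cs <= ex[intron_idx, 1L] + 4L) next
      if (cs >= old_e - 4L) next
      # 80-120% rule must hold for recovery: true/corrupt ratio
      r <- lead_len / (lead_len - d)
      if (r < refine_config$exon_len_ratio[1L] + 0.01 ||
          r > refine_config$exon_len_ratio[2L] - 0.01) next
      # require the corrupted intron's dinucleotides to be non-canonical
      dn2 <- splice_dinucleotides(genome, tx$chrom, cs, old_e, tx$strand)
      if (.pair_ok(dn2, refine_config)) next
      return(list(cs = cs, d = d))
    }
    NULL
  }

  plant_shift <- function(tid, intron_idx, deltas_wanted, rule,
                          satisfiable = TRUE) {
    tx <- txs[[tid]]
    res <- shift_boundary(tx, intron_idx, deltas_wanted)
    if (is.null(res)) return(FALSE)
    ex <- tx$exons
    old_s <- ex[intron_idx, 2L]; old_e <- ex[intron_idx + 1L, 1L]
    ex[intron_idx, 2L] <- res$cs
    txs[[tid]] <<- transcript_model(tx$transcript_id, tx$gene_id, tx$chrom,
                                    tx$strand, ex,
                                    cds = .clip_cds(tx$cds, ex),
                                    frame = tx$frame, attrs = tx$attrs)
    # exonic delta of the *recovery* event: corrupted intron len - true len
    add("junction", rule, tid, tx$chrom, tx$strand, old_s, old_e,
        res$cs, old_e, delta = res$d, satisfiable = satisfiable)
    TRUE
  }

  # candidate shifts in both directions (positive: corrupted exon
  # truncated; negative: corrupted exon extended into the intron), never a
  # multiple of 3; sign_first orders the preferred direction first
  shifts_nonmod3 <- function(sign_first = 1L) {
    d <- sample(4:20, 17)
    d <- d[d %% 3L != 0L]
    if (sign_first > 0L) c(d, -d) else c(-d, d)
  }

  planted <- 0L
  while (planted < n_single) {
    tid <- take(1L, need_exons = 3L)
    sign_first <- if (planted %% 2L == 0L) 1L else -1L
    if (plant_shift(tid, 1L, shifts_nonmod3(sign_first), "boundary_shift"))
      planted <- planted + 1L
  }
  # frame-restoring pairs: deltas d1, d2 with d1 + d2 = 0 (mod 3), neither 0
  planted <- 0L
  while (planted < n_pairs) {
    tid <- take(1L, need_exons = 4L)
    tx <- txs[[tid]]
    ok1 <- plant_shift(tid, 1L, c(4L, 7L, 10L, 13L), "frameshift_pair")
    ok2 <- plant_shift(tid, 2L, c(5L, 8L, 11L, 14L), "frameshift_pair")
    if (ok1 && ok2) planted <- planted + 1L
  }

  ## -- UTR truncations ----------------------------------------------------
  trunc_len <- function() 100L + 10L * sample.int(10L, 1L)
  for (k in seq_len(config$n_utr3_plants)) {
    tid <- take(1L)
    tx <- txs[[tid]]
    t_len <- trunc_len()
    ex <- tx$exons; sp <- tx_span(tx)
    if (tx$strand == "+") {
      ex[nrow(ex), 2L] <- ex[nrow(ex), 2L] - t_len
      add("utr3", "truncation", tid, tx$chrom, tx$strand,
          sp[["start"]], sp[["end"]], sp[["start"]], sp[["end"]] - t_len,
          delta = t_len, satisfiable = TRUE)
    } else {
      ex[1L, 1L] <- ex[1L, 1L] + t_len
      add("utr3", "truncation", tid, tx$chrom, tx$strand,
          sp[["start"]], sp[["end"]], sp[["start"]] + t_len, sp[["end"]],
          delta = t_len, satisfiable = TRUE)
    }
    txs[[tid]] <- transcript_model(tx$transcript_id, tx$gene_id, tx$chrom,
                                   tx$strand, ex,
                                   cds = .clip_cds(tx$cds, ex),
                                   frame = tx$frame, attrs = tx$attrs)
  }
  for (k in seq_len(config$n_utr5_plants)) {
    tid <- take(1L)
    tx <- txs[[tid]]
    t_len <- trunc_len()
    ex <- tx$exons; sp <- tx_span(tx)
    if (tx$strand == "+") {
      ex[1L, 1L] <- ex[1L, 1L] + t_len
      add("utr5", "truncation", tid, tx$chrom, tx$strand,
          sp[["start"]], sp[["end"]], sp[["start"]] + t_len, sp[["end"]],
          delta = t_len, satisfiable = TRUE)
    } else {
      ex[nrow(ex), 2L] <- ex[nrow(ex), 2L] - t_len
      add("utr5", "truncation", tid, tx$chrom, tx$strand,
          sp[["start"]], sp[["end"]], sp[["start"]], sp[["end"]] - t_len,
          delta = t_len, satisfiable = TRUE)
    }
    txs[[tid]] <- transcript_model(tx$transcript_id, tx$gene_id, tx$chrom,
                                   tx$strand, ex,
                                   cds = .clip_cds(tx$cds, ex),
                                   frame = tx$frame, attrs = tx$attrs)
  }

  ## -- internal exon deletions (new-exon plants) ---------------------------
  for (k in seq_len(config$n_new_exon_plants)) {
    tid <- take(1L, need_exons = 3L)
    tx <- txs[[tid]]
    ki <- 2L  # delete the second exon (internal by need_exons >= 3)
    del <- tx$exons[ki, ]
    ex <- tx$exons[-ki, , drop = FALSE]
    txs[[tid]] <- transcript_model(tx$transcript_id, tx$gene_id, tx$chrom,
                                   tx$strand, ex,
                                   cds = .clip_cds(tx$cds, ex),
                                   frame = tx$frame, attrs = tx$attrs)
    add("new_exon", "exon_deletion", tid, tx$chrom, tx$strand,
        del[[1L]], del[[2L]], NA, NA, delta = del[[2L]] - del[[1L]],
        satisfiable = TRUE)
  }

  ## -- whole-transcript deletions (novel transcript plants) ----------------
  for (k in seq_len(config$n_new_transcript_plants)) {
    tid <- take(1L)
    tx <- txs[[tid]]
    sp <- tx_span(tx)
    txs[[tid]] <- NULL
    add("new_transcript", "transcript_deletion", tid, tx$chrom, tx$strand,
        sp[["start"]], sp[["end"]], NA, NA,
        delta = nrow(tx$exons), satisfiable = TRUE)
  }

  ## -- decoys ---------------------------------------------------------------
  if (isTRUE(config$plant_decoys)) {
    # (1) boundary shift breaking the 80-120% band: unrecoverable
    repeat {
      tid <- take(1L, need_exons = 3L)
      tx <- txs[[tid]]
      lead_len <- tx$exons[1L, 2L] - tx$exons[1L, 1L]
      d <- ceiling(lead_len * 0.30)   # true/corrupt ratio > 1.2
      intron_len <- tx$exons[2L, 1L] - tx$exons[1L, 2L]
      if (d >= intron_len - 4L) next
      ex <- tx$exons
      old_s <- ex[1L, 2L]; old_e <- ex[2L, 1L]
      ex[1L, 2L] <- old_s + d   # corrupted exon longer: ratio < 0.8
      txs[[tid]] <- transcript_model(tx$transcript_id, tx$gene_id, tx$chrom,
                                     tx$strand, ex,
                                     cds = .clip_cds(tx$cds, ex),
                                     frame = tx$frame, attrs = tx$attrs)
      add("junction", "decoy_exon_ratio", tid, tx$chrom, tx$strand,
          old_s, old_e, old_s + d, old_e, delta = -d, satisfiable = FALSE)
      break
    }
    # (2) boundary shift whose true junction gets only 1 read
    repeat {
      tid <- take(1L, need_exons = 3L)
      if (plant_shift(tid, 1L, shifts_nonmod3(), "decoy_low_reads",
                      satisfiable = FALSE)) break
    }
    # (3) boundary shift whose corrupted intron keeps 2 reads of support
    repeat {
      tid <- take(1L, need_exons = 3L)
      if (plant_shift(tid, 1L, shifts_nonmod3(), "decoy_old_supported",
                      satisfiable = FALSE)) break
    }
    # (4) UTR truncation below the minimum reportable extension
    tid <- take(1L)
    tx <- txs[[tid]]
    t_len <- refine_config$utr_min_extension - 20L
    ex <- tx$exons; sp <- tx_span(tx)
    if (tx$strand == "+") {
      ex[nrow(ex), 2L] <- ex[nrow(ex), 2L] - t_len
      add("utr3", "decoy_short_extension", tid, tx$chrom, tx$strand,
          sp[["start"]], sp[["end"]], sp[["start"]], sp[["end"]] - t_len,
          delta = t_len, satisfiable = FALSE)
    } else {
      ex[1L, 1L] <- ex[1L, 1L] + t_len
      add("utr3", "decoy_short_extension", tid, tx$chrom, tx$strand,
          sp[["start"]], sp[["end"]], sp[["start"]] + t_len, sp[["end"]],
          delta = t_len, satisfiable = FALSE)
    }
    txs[[tid]] <- transcript_model(tx$transcript_id, tx$gene_id, tx$chrom,
                                   tx$strand, ex,
                                   cds = .clip_cds(tx$cds, ex),
                                   frame = tx$frame, attrs = tx$attrs)
    # (5) terminal-exon deletion: island falls outside the transcript span
    tid <- take(1L, need_exons = 3L)
    tx <- txs[[tid]]
    ki <- nrow(tx$exons)
    del <- tx$exons[ki, ]
    ex <- tx$exons[-ki, , drop = FALSE]
    txs[[tid]] <- transcript_model(tx$transcript_id, tx$gene_id, tx$chrom,
                                   tx$strand, ex,
                                   cds = .clip_cds(tx$cds, ex),
                                   frame = tx$frame, attrs = tx$attrs)
    add("new_exon", "decoy_outside_span", tid, tx$chrom, tx$strand,
        del[[1L]], del[[2L]], NA, NA, delta = del[[2L]] - del[[1L]],
        satisfiable = FALSE)
  }

  ledger <- do.call(rbind, c(ledger, list(make.row.names = FALSE)))
  list(models = gene_model_set(txs, provenance = "putative"),
       ledger = ledger)
}

## ---- evidence -------------------------------------------------------------

#' Simulate coverage and junction evidence from the true models
#'
#' Evidence always reflects the true structures: per-sample depths are
#' Poisson around the exonic mean on true exonic bases (per strand) and
#' around the noise mean elsewhere; every true junction receives
#' per-sample reads from the configured range with a total of at least
#' two. Junctions present only in a corrupted annotation get no reads.
#' When a plant ledger is supplied, its evidence-level decoys are honoured:
#' a `decoy_low_reads` plant's true junction is capped at one read total,
#' and a `decoy_old_supported` plant's corrupted junction receives two
#' reads.
#'
#' @param true_models the true `gene_model_set`.
#' @param config a `sim_config`.
#' @param plant_ledger optional ledger from [corrupt_annotation()].
#' @return list: `coverage` (list of `coverage_track`s, one per sample and
#'   strand) and `junctions` (a `junction_table`).
#' @export
simulate_evidence <- function(true_models, config, plant_ledger = NULL) {
  set.seed(config$seed + 2L)
  chrom_names <- sprintf("chr%d", seq_len(config$n_chroms))
  samples <- sprintf("S%d", seq_len(config$n_samples))
  coverage <- list()
  for (s in samples) {
    for (st in c("+", "-")) {
      depth <- lapply(chrom_names, function(cn)
        if (config$intronic_noise > 0)
          stats::rpois(config$chrom_length, config$intronic_noise)
        else integer(config$chrom_length))
      names(depth) <- chrom_names
      for (tx in true_models$transcripts) {
        if (tx$strand != st) next
        for (k in seq_len(nrow(tx$exons))) {
          idx <- (tx$exons[k, 1L] + 1L):tx$exons[k, 2L]
          depth[[tx$chrom]][idx] <- stats::rpois(length(idx),
                                                 config$exonic_depth)
        }
      }
      coverage[[length(coverage) + 1L]] <- coverage_track(s, st, depth)
    }
  }

  low_keys <- character(0); old_rows <- NULL
  if (!is.null(plant_ledger)) {
    lr <- plant_ledger[plant_ledger$rule == "decoy_low_reads", , drop = FALSE]
    low_keys <- .jx_key(lr$chrom, lr$true_start, lr$true_end, lr$strand)
    os <- plant_ledger[plant_ledger$rule == "decoy_old_supported", ,
                       drop = FALSE]
    if (nrow(os))
      old_rows <- data.frame(chrom = os$chrom, start = os$corrupt_start,
                             end = os$corrupt_end, strand = os$strand,
                             sample = samples[1L], reads = 2L,
                             stringsAsFactors = FALSE)
  }

  rows <- list()
  for (tx in true_models$transcripts) {
    intr <- introns_of(tx)
    for (i in seq_len(nrow(intr))) {
      key <- .jx_key(intr$chrom[i], intr$start[i], intr$end[i],
                     intr$strand[i])
      if (key %in% low_keys) {
        rows[[key]] <- data.frame(chrom = intr$chrom[i],
                                  start = intr$start[i], end = intr$end[i],
                                  strand = intr$strand[i],
                                  sample = samples[1L], reads = 1L,
                                  stringsAsFactors = FALSE)
        next
      }
      if (!is.null(rows[[key]])) next  # shared junction already simulated
      counts <- .runif_int(config$n_samples, config$junction_reads)
      while (sum(counts) < 2L)
        counts <- .runif_int(config$n_samples, config$junction_reads)
      keep <- counts > 0L
      rows[[key]] <- data.frame(chrom = intr$chrom[i], start = intr$start[i],
                                end = intr$end[i], strand = intr$strand[i],
                                sample = samples[keep], reads = counts[keep],
                                stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, c(unname(rows), list(old_rows),
                              list(make.row.names = FALSE)))
  if (is.null(records))
    records <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          sample = character(0), reads = integer(0))
  list(coverage = coverage, junctions = junction_table(records))
}

#' Simulate a complete benchmark dataset
#'
#' Convenience wrapper running [simulate_genome_and_models()],
#' [corrupt_annotation()] and [simulate_evidence()] with one config.
#'
#' @param config a `sim_config`.
#' @param refine_config thresholds the plants must satisfy.
#' @return list: `genome`, `truth` (true models), `models` (corrupted),
#'   `ledger`, `evidence` (list with `coverage`, `junctions`, `genome`),
#'   `conservation`.
#' @export
simulate_dataset <- function(config = sim_config(),
                             refine_config = refinement_config()) {
  gm <- simulate_genome_and_models(config)
  cr <- corrupt_annotation(gm$models, config, gm$genome, refine_config)
  ev <- simulate_evidence(gm$models, config, cr$ledger)
  list(genome = gm$genome, truth = gm$models, models = cr$models,
       ledger = cr$ledger,
       evidence = list(coverage = ev$coverage, junctions = ev$junctions,
                       genome = gm$genome),
       conservation = gm$conservation)
}

## ---- recovery check --------------------------------------------------------

#' Compare a refinement run against a plant ledger
#'
#' A junction plant is recovered when a junction event restores exactly the
#' true intron from the corrupted one; a UTR plant when the revised
#' transcript end equals the true end; a new-exon plant when a new-exon
#' event recreates the deleted exon's coordinates; a new-transcript plant
#' when an assembled transcript has exactly the deleted transcript's exon
#' structure. Off-ledger events are events matching no satisfiable plant.
#'
#' @param ledger plant ledger from [corrupt_annotation()].
#' @param result a `gm_refinement` from [refine()].
#' @return list: `table` (ledger with a `recovered` column),
#'   `recovery_rate` (fraction of satisfiable plants recovered),
#'   `decoys_reported` (unsatisfiable plants matched by an event),
#'   `off_ledger_events` (count).
#' @export
recovery_report <- function(ledger, result) {
  ev <- result$events
  matched_event <- rep(FALSE, nrow(ev))
  recovered <- logical(nrow(ledger))
  for (i in seq_len(nrow(ledger))) {
    p <- ledger[i, ]
    hit <- integer(0)
    if (p$category == "junction") {
      hit <- which(ev$event_type == "junction" &
                     ev$transcript_id == p$transcript_id &
                     ev$old_start == p$corrupt_start &
                     ev$old_end == p$corrupt_end &
                     ev$new_start == p$true_start &
                     ev$new_end == p$true_end)
    } else if (p$category %in% c("utr5", "utr3")) {
      hit <- which(ev$event_type == p$category &
                     ev$transcript_id == p$transcript_id &
                     ev$new_start == p$true_start &
                     ev$new_end == p$true_end)
    } else if (p$category == "new_exon") {
      hit <- which(ev$event_type == "new_exon" &
                     ev$transcript_id == p$transcript_id &
                     ev$new_start == p$true_start &
                     ev$new_end == p$true_end)
    } else if (p$category == "new_transcript") {
      for (j in which(ev$event_type == "new_transcript")) {
        ntx <- result$models$transcripts[[ev$transcript_id[j]]]
        if (is.null(ntx) || ntx$chrom != p$chrom || ntx$strand != p$strand)
          next
        sp <- tx_span(ntx)
        if (sp[["start"]] == p$true_start && sp[["end"]] == p$true_end)
          hit <- c(hit, j)
      }
    }
    recovered[i] <- length(hit) > 0L
    matched_event[hit] <- TRUE
  }
  sat <- ledger$satisfiable
  list(table = cbind(ledger, recovered = recovered),
       recovery_rate = if (any(sat)) mean(recovered[sat]) else NA_real_,
       decoys_reported = sum(recovered[!sat]),
       off_ledger_events = sum(!matched_event))
}
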