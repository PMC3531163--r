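test_that("summary percentages follow the one-decimal rounding rule", {
  expect_equal(summary_percentage(12303, 42820), 28.7)
  expect_equal(summary_percentage(1, 3), 33.3)
  expect_equal(summary_percentage(0, 10), 0)
})

test_that("splice PFMs are forced by construction and match hand tallies", {
  set.seed(61)
  # 30 junctions all starting GT..AG on random backgrounds
  txs <- lapply(1:30, function(i) {
    s <- 100 + (i - 1) * 600
    toy_tx(sprintf("t%02d", i), c(s, s + 150, s + 350, s + 500),
           strand = sample(c("+", "-"), 1))
  })
  models <- gene_model_set(txs)
  genome <- plant_splice_sites(random_genome(20000, seed = 62), models)
  pfm <- splice_pfm(models, genome)
  # donor offsets 0,+1 are the invariant GT; acceptor -2,-1 the AG
  expect_equal(pfm$donor$freq["G", "0"], 1)
  expect_equal(pfm$donor$freq["T", "1"], 1)
  expect_equal(pfm$donor$ic[c("0", "1")], c(`0` = 2, `1` = 2))
  expect_equal(pfm$acceptor$freq["A", "-2"], 1)
  expect_equal(pfm$acceptor$freq["G", "-1"], 1)
  # all columns are proper distributions
  expect_true(all(abs(colSums(pfm$donor$freq) - 1) < 1e-9))
  expect_true(all(abs(colSums(pfm$acceptor$freq) - 1) < 1e-9))
  expect_true(all(pfm$donor$ic >= 0 & pfm$donor$ic <= 2))

  # frequencies equal the per-anchor brute-force tally
  keys <- junction_keys(models)
  expect_equal(unname(pfm$donor$freq),
               unname(oracle_pfm(genome, keys, "donor", -3:5)))
  expect_equal(unname(pfm$acceptor$freq),
               unname(oracle_pfm(genome, keys, "acceptor", -13:2)))
})

test_that("a single junction yields a one-hot PFM", {
  tx <- toy_tx("t", c(100, 200, 300, 400))
  models <- gene_model_set(list(tx))
  genome <- random_genome(600, seed = 8)
  pfm <- splice_pfm(models, genome)
  expect_true(all(pfm$donor$freq %in% c(0, 1)))
  expect_equal(unname(colSums(pfm$donor$freq)), rep(1, 9))
  expect_equal(pfm$donor$n, 1)
})

test_that("short introns are skipped and counted", {
  tx <- toy_tx("t", c(100, 200, 210, 300))  # 10-base intron
  models <- gene_model_set(list(tx))
  pfm <- splice_pfm(models, random_genome(600, seed = 8))
  expect_equal(pfm$n_skipped, 1)
  expect_equal(pfm$donor$n, 0)
})

test_that("planted poly(A) hexamers appear at their planted offsets", {
  set.seed(41)
  offs <- integer(0)
  txs <- list(); chars <- strsplit(random_genome(40000, seed = 42)$seq, "")[[1]]
  for (i in 1:25) {
    s <- 200 + (i - 1) * 1500
    strand <- sample(c("+", "-"), 1)
    txs[[i]] <- toy_tx(sprintf("t%02d", i), c(s, s + 400), strand = strand)
    off <- sample(-40:-15, 1)
    offs <- c(offs, off)
    if (strand == "+") {
      a <- s + 400 - 1
      chars[(a + off + 1):(a + off + 6)] <- strsplit("AATAAA", "")[[1]]
    } else {
      a <- s
      chars[(a - off - 5 + 1):(a - off + 1)] <- strsplit("TTTATT", "")[[1]]
    }
  }
  genome <- toy_genome(paste(chars, collapse = ""))
  models <- gene_model_set(txs)
  prof <- hexamer_end_profile(models, genome)
  # every planted offset is found; total planted mass is at least 1 anchor
  # per transcript
  for (o in unique(offs)) {
    got <- prof$profile$frequency[prof$profile$offset == o]
    expect_gte(got, sum(offs == o) / length(offs))
  }
  expect_gte(sum(prof$profile$frequency[prof$profile$offset %in% -40:-15]),
             1)
  # control anchored at the 5' start carries no planted signal
  expect_lt(max(prof$control$frequency), 0.2)
})

test_that("a motif-free genome gives an all-zero hexamer profile", {
  g <- toy_genome(strrep("C", 5000))
  models <- gene_model_set(list(toy_tx("t", c(1000, 2000))))
  prof <- hexamer_end_profile(models, g)
  expect_true(all(prof$profile$frequency == 0))
  expect_true(all(prof$control$frequency == 0))
})

test_that("hexamer profile equals a brute-force scan", {
  set.seed(43)
  txs <- lapply(1:30, function(i) {
    s <- 300 + (i - 1) * 700
    toy_tx(sprintf("t%02d", i), c(s, s + 300),
           strand = sample(c("+", "-"), 1))
  })
  models <- gene_model_set(txs)
  genome <- random_genome(25000, seed = 44)
  prof <- hexamer_end_profile(models, genome, motif = "AATAAA",
                              window = c(-20L, 5L))
  # brute force: extract the whole 3' region per transcript and compare
  for (o in seq(-20, 4)) {
    hits <- 0
    for (tx in txs) {
      sp <- tx_span(tx)
      if (tx$strand == "+") {
        a <- sp[["end"]] - 1 + o
        h <- genome_subseq(genome, "chr1", a, a + 6)
      } else {
        a <- sp[["start"]] - o
        h <- revcomp(genome_subseq(genome, "chr1", a - 5, a + 1))
      }
      if (h == "AATAAA") hits <- hits + 1
    }
    expect_equal(prof$profile$frequency[prof$profile$offset == o],
                 hits / length(txs))
  }
})

test_that("conservation profiles step at junction boundaries and match brute force", {
  txs <- lapply(1:20, function(i) {
    s <- 100 + (i - 1) * 800
    toy_tx(sprintf("t%02d", i), c(s, s + 200, s + 400, s + 600),
           strand = if (i %% 2) "+" else "-")
  })
  models <- gene_model_set(txs)
  # score 1 on exons, 0 elsewhere
  score <- list(chr1 = numeric(20000))
  for (tx in txs)
    for (k in 1:2)
      score$chr1[(tx$exons[k, 1] + 1):tx$exons[k, 2]] <- 1
  prof <- conservation_junction_profile(models, score, half_window = 20)
  expect_equal(prof$n_anchors, 20)
  don <- prof$donor
  expect_true(all(don$value[don$offset < 0] == 1))
  expect_true(all(don$value[don$offset >= 0] == 0))
  acc <- prof$acceptor
  expect_true(all(acc$value[acc$offset < 0] == 0))
  expect_true(all(acc$value[acc$offset >= 0] == 1))

  # brute force on a noisy track
  set.seed(3)
  score$chr1 <- runif(20000)
  prof2 <- conservation_junction_profile(models, score, half_window = 10)
  keys <- junction_keys(models)
  for (o in seq(-10, 9)) {
    vals <- vapply(seq_len(nrow(keys)), function(i) {
      p <- if (keys$strand[i] == "+") keys$start[i] + o
      else keys$end[i] - 1 - o
      score$chr1[p + 1]
    }, numeric(1))
    expect_equal(prof2$donor$value[prof2$donor$offset == o], mean(vals))
  }
})

test_that("empty model sets yield empty profiles", {
  prof <- conservation_junction_profile(gene_model_set(list()),
                                        list(chr1 = numeric(100)))
  expect_equal(prof$n_anchors, 0)
})

test_that("end-distance histogram bins signed distances to the nearest TSS", {
  models <- gene_model_set(list(toy_tx("a", c(1000, 2000)),
                                toy_tx("b", c(8000, 9000), strand = "-")))
  # peak centred exactly on transcript a's TSS
  peaks <- data.frame(chrom = "chr1", start = 950L, end = 1050L)
  h <- end_distance_profile(peaks, models)
  expect_equal(sum(h$counts), 1)
  expect_equal(h$counts[which(h$breaks == 0)], 1)
  # no transcript end within the window
  far <- data.frame(chrom = "chr1", start = 40000L, end = 40100L)
  expect_equal(sum(end_distance_profile(far, models)$counts), 0)
  # minus-strand TSS at the genomic end; downstream is leftward
  p2 <- data.frame(chrom = "chr1", start = 8840L, end = 8860L)
  h2 <- end_distance_profile(p2, models)
  d <- 9000 - 1 - 8850  # sense distance +149 -> bin [100,200)
  expect_equal(h2$counts[findInterval(149, h2$breaks)], 1)

  # random fixture vs brute force nearest-end search
  set.seed(19)
  rpeaks <- data.frame(chrom = "chr1",
                       start = sample(0:12000, 40), end = 0L)
  rpeaks$end <- rpeaks$start + 100L
  h3 <- end_distance_profile(rpeaks, models, window = 5000, bin = 100)
  dists <- c()
  for (i in 1:40) {
    mid <- (rpeaks$start[i] + rpeaks$end[i]) %/% 2
    cand <- c(`+` = mid - 1000, `-` = (9000 - 1) - mid)
    d <- cand[which.min(abs(cand))]
    if (abs(d) <= 5000) dists <- c(dists, d)
  }
  expect_equal(sum(h3$counts), length(dists))
})

test_that("coverage categories separate revised exon from revised intron", {
  # candidate (996, 1196): the revision moves the donor 4 bases left (4
  # disputed bases become intronic) and the acceptor 4 bases left (4
  # disputed bases become exonic)
  fx <- make_jx_fixture(candidate = c(996L, 1196L))
  cfg <- refinement_config()
  ev <- propose_junction_revisions(fx$models, fx$junctions, fx$genome, cfg)
  expect_equal(nrow(ev), 1)
  revised <- apply_junction_revisions(fx$models, ev)
  # depth 30 on true (revised) exons, 0 on the true intron
  tracks <- list(toy_track("s1", "+", 2000,
                           rbind(c(900, 996, 30), c(1196, 1400, 30))))
  cats <- boundary_coverage_categories(fx$models, revised, ev, tracks)
  expect_equal(stats::median(cats$revised_exon), 1)
  expect_equal(stats::median(cats$revised_intron), 0)
  expect_lt(cats$p_value, 0.05)
  # rank-sum statistic equals the all-pairs count oracle
  expect_equal(cats$statistic,
               oracle_ranksum_W(cats$revised_exon, cats$revised_intron))
  # window is [900,1400): 296 bases exonic under both models, 196 intronic
  # under both, 4 disputed each way
  expect_equal(length(cats$exon), 296)
  expect_equal(length(cats$intron), 196)
  expect_equal(length(cats$revised_exon), 4)
  expect_equal(length(cats$revised_intron), 4)
})

test_that("undisputed annotations leave the revised categories empty", {
  tx <- toy_tx("t", c(100, 300, 500, 700))
  models <- gene_model_set(list(tx))
  cats <- boundary_coverage_categories(models, models,
                                       gmrefine:::.empty_events(), list())
  expect_equal(length(cats$revised_exon), 0)
  expect_equal(length(cats$revised_intron), 0)
  expect_true(is.na(cats$p_value))
})

test_that("summary_report reproduces printed-count arithmetic", {
  fx <- sim_fixture()
  rep <- summary_report(fx$ds$models, fx$ds$evidence, fx$res$events)
  rt <- rep$revision_table
  n_tx <- length(fx$ds$models)
  for (i in seq_len(nrow(rt)))
    expect_equal(rt$percentage[i],
                 round(100 * rt$transcripts[i] / n_tx, 1))
  expect_equal(rt$events[rt$category == "total"],
               sum(rt$events[rt$category != "total"]))
  # transcripts with several revisions are counted once in the total
  expect_equal(rt$transcripts[rt$category == "total"],
               length(affected_transcripts(fx$res$events)))
  expect_lte(rt$transcripts[rt$category == "total"],
             sum(rt$transcripts[rt$category != "total"]))
  # on this fixture every annotated feature is evidence-covered except the
  # corrupted-only junctions
  ct <- rep$coverage_table
  expect_equal(ct$covered[ct$category == "transcripts"], n_tx)
})
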