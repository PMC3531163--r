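test_that("generators are pure functions of the config seed", {
  cfg <- sim_config(seed = 5, n_genes = 10L, chrom_length = 120000L,
                    n_junction_plants = 2L, n_utr5_plants = 1L,
                    n_utr3_plants = 1L, n_new_exon_plants = 1L,
                    n_new_transcript_plants = 1L, plant_decoys = FALSE)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(model_spans(a$truth), model_spans(b$truth))
  expect_identical(a$ledger, b$ledger)
  expect_identical(a$evidence$junctions$records, b$evidence$junctions$records)
  expect_identical(a$evidence$coverage[[1]]$depth,
                   b$evidence$coverage[[1]]$depth)
  expect_identical(a$conservation, b$conservation)
})

test_that("every generated intron carries canonical splice dinucleotides", {
  fx <- sim_fixture()
  for (tx in fx$ds$truth$transcripts) {
    intr <- introns_of(tx)
    for (i in seq_len(nrow(intr)))
      expect_true(splice_dinucleotides(fx$ds$genome, intr$chrom[i],
                                       intr$start[i], intr$end[i],
                                       intr$strand[i])$canonical)
  }
})

test_that("planted poly(A) signals concentrate in the planting window", {
  fx <- sim_fixture()
  prof <- hexamer_end_profile(fx$ds$truth, fx$ds$genome)
  window_mass <- sum(prof$profile$frequency[prof$profile$offset %in% -40:-15])
  expect_gte(window_mass, 1)
})

test_that("exonic coverage matches the configured depth regime", {
  fx <- sim_fixture()
  cfg <- fx$cfg
  tx <- fx$ds$truth$transcripts[[1]]
  tr <- Filter(function(t) t$strand == tx$strand,
               fx$ds$evidence$coverage)[[1]]
  d <- unlist(lapply(seq_len(nrow(tx$exons)), function(k)
    depth_window(tr, tx$chrom, tx$exons[k, 1], tx$exons[k, 2])))
  # law of large numbers: the empirical mean sits within 3 standard errors
  se <- sqrt(cfg$exonic_depth / length(d))
  expect_lt(abs(mean(d) - cfg$exonic_depth), 3 * se)
  # intergenic bases carry the configured noise depth (0 by default)
  sp <- model_spans(fx$ds$truth)
  gap <- min(sp$start[sp$chrom == tx$chrom]) - 300
  expect_equal(sum(depth_window(tr, tx$chrom, gap - 200, gap)), 0)
})

test_that("corrupted-only junctions receive no evidence reads", {
  fx <- sim_fixture()
  shifts <- fx$ds$ledger[fx$ds$ledger$category == "junction" &
                           fx$ds$ledger$rule != "decoy_old_supported", ]
  for (i in seq_len(nrow(shifts)))
    expect_equal(junction_support(fx$ds$evidence$junctions,
                                  shifts$chrom[i], shifts$corrupt_start[i],
                                  shifts$corrupt_end[i],
                                  shifts$strand[i])[["reads"]], 0L)
  # while every true junction of an undeleted transcript is supported
  tx <- fx$ds$truth$transcripts[[1]]
  intr <- introns_of(tx)
  for (i in seq_len(nrow(intr)))
    expect_gte(junction_support(fx$ds$evidence$junctions, intr$chrom[i],
                                intr$start[i], intr$end[i],
                                intr$strand[i])[["reads"]], 2L)
})

test_that("corruption matches its ledger entry coordinates", {
  fx <- sim_fixture()
  ledger <- fx$ds$ledger
  # UTR truncations displace the corrupted span end by exactly delta
  utr <- ledger[ledger$category %in% c("utr5", "utr3") &
                  ledger$satisfiable, ]
  for (i in seq_len(nrow(utr))) {
    ctx <- fx$ds$models$transcripts[[utr$transcript_id[i]]]
    sp <- tx_span(ctx)
    expect_equal(unname(sp), c(utr$corrupt_start[i], utr$corrupt_end[i]))
    expect_equal((utr$corrupt_start[i] - utr$true_start[i]) +
                   (utr$true_end[i] - utr$corrupt_end[i]), utr$delta[i])
  }
  # frame-restoring pairs cancel modulo 3
  pairs <- ledger[ledger$rule == "frameshift_pair", ]
  for (tid in unique(pairs$transcript_id))
    expect_equal(sum(pairs$delta[pairs$transcript_id == tid]) %% 3, 0)
  # the short-extension decoy stays below the reporting threshold
  decoy <- ledger[ledger$rule == "decoy_short_extension", ]
  expect_true(all(decoy$delta < refinement_config()$utr_min_extension))
  expect_true(all(!decoy$satisfiable))
})

test_that("the full pipeline recovers all satisfiable plants and no decoys", {
  fx <- sim_fixture()
  rec <- recovery_report(fx$ds$ledger, fx$res)
  expect_equal(rec$recovery_rate, 1)
  expect_equal(rec$decoys_reported, 0)
  expect_equal(rec$off_ledger_events, 0)
  # assembled novel transcripts reproduce the deleted exon structures
  del <- fx$ds$ledger[fx$ds$ledger$category == "new_transcript", ]
  for (i in seq_len(nrow(del))) {
    truth_tx <- fx$ds$truth$transcripts[[del$transcript_id[i]]]
    hit <- Filter(function(t) t$chrom == truth_tx$chrom &&
                    t$strand == truth_tx$strand &&
                    identical(unname(t$exons), unname(truth_tx$exons)),
                  fx$res$models$transcripts)
    expect_equal(length(hit), 1)
  }
})

test_that("refinement event structure follows the stage contracts", {
  fx <- sim_fixture()
  ev <- fx$res$events
  old_models <- fx$ds$models
  new_models <- fx$res$models
  # junction revisions preserve exon counts; new exons add exactly one
  for (tid in unique(ev$transcript_id[ev$event_type == "junction"]))
    expect_equal(nrow(new_models$transcripts[[tid]]$exons) -
                   sum(ev$event_type == "new_exon" &
                         ev$transcript_id == tid),
                 nrow(old_models$transcripts[[tid]]$exons))
  # every revised or novel splice boundary is canonical
  cfg <- refinement_config()
  for (tid in unique(ev$transcript_id)) {
    tx <- new_models$transcripts[[tid]]
    intr <- introns_of(tx)
    for (i in seq_len(nrow(intr)))
      expect_true(splice_dinucleotides(fx$ds$genome, intr$chrom[i],
                                       intr$start[i], intr$end[i],
                                       intr$strand[i])$canonical)
  }
})
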