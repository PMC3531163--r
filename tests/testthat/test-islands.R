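test_that("island calling finds maximal pooled-depth runs", {
  cfg <- refinement_config()
  tracks <- list(toy_track("s1", "+", 1000, rbind(c(500, 700, 10))))
  isl <- call_coverage_islands(tracks, "+", cfg)
  expect_equal(nrow(isl), 1)
  expect_equal(isl$start, 500)
  expect_equal(isl$end, 700)

  # a 40-base run is below the minimum island length
  tracks2 <- list(toy_track("s1", "+", 1000, rbind(c(500, 540, 10))))
  expect_equal(nrow(call_coverage_islands(tracks2, "+", cfg)), 0)

  # depth pools across samples: 3 + 3 crosses the threshold of 5
  tracks3 <- list(toy_track("s1", "+", 1000, rbind(c(100, 200, 3))),
                  toy_track("s2", "+", 1000, rbind(c(100, 200, 3))))
  expect_equal(nrow(call_coverage_islands(tracks3, "+", cfg)), 1)
})

test_that("island calling equals a brute-force scan on random step tracks", {
  cfg <- refinement_config()
  set.seed(31)
  for (rep in 1:20) {
    d <- rep(sample(0:12, 40, TRUE), times = sample(5:60, 40, TRUE))
    d <- d[1:min(length(d), 1500)]
    tr <- coverage_track("s1", "+", list(chr1 = as.numeric(d)))
    isl <- call_coverage_islands(list(tr), "+", cfg)
    want <- oracle_islands(d, cfg$island_min_depth, cfg$island_min_length)
    expect_equal(nrow(isl), nrow(want))
    if (nrow(want)) {
      expect_equal(isl$start, want[, 1])
      expect_equal(isl$end, want[, 2])
    }
  }
})

test_that("an intronic island linked on both sides becomes a new exon", {
  fx <- make_new_exon_fixture()
  ev <- find_new_exons(fx$models, fx$islands, fx$junctions, fx$genome,
                       refinement_config())
  expect_equal(nrow(ev), 1)
  expect_equal(ev$event_type, "new_exon")
  expect_equal(ev$transcript_id, "t1")
  expect_equal(ev$new_start, 500)
  expect_equal(ev$new_end, 700)

  revised <- apply_new_exon_events(fx$models, ev)
  expect_equal(nrow(revised$transcripts[["t1"]]$exons), 3)
  expect_equal(unname(revised$transcripts[["t1"]]$exons[2, ]), c(500, 700))
})

test_that("islands overlapping annotated exons by 30% or more are rejected", {
  # a second transcript's exon overlaps the 200-base island by 80 bases (40%)
  fx <- make_new_exon_fixture(extra_exon = c(620, 700))
  ev <- find_new_exons(fx$models, fx$islands, fx$junctions, fx$genome,
                       refinement_config())
  expect_equal(nrow(ev), 0)
  # 40 bases (20%) is allowed
  fx2 <- make_new_exon_fixture(extra_exon = c(660, 700))
  ev2 <- find_new_exons(fx2$models, fx2$islands, fx2$junctions, fx2$genome,
                        refinement_config())
  expect_equal(nrow(ev2), 1)
})

test_that("an island linked on one side only is rejected", {
  fx <- make_new_exon_fixture(link_right = FALSE)
  expect_equal(nrow(find_new_exons(fx$models, fx$islands, fx$junctions,
                                   fx$genome, refinement_config())), 0)
  fx2 <- make_new_exon_fixture(link_left = FALSE)
  expect_equal(nrow(find_new_exons(fx2$models, fx2$islands, fx2$junctions,
                                   fx2$genome, refinement_config())), 0)
})

test_that("an island outside any transcript span cannot become a new exon", {
  fx <- make_new_exon_fixture()
  fx$islands$start <- 1500L; fx$islands$end <- 1700L
  expect_equal(nrow(find_new_exons(fx$models, fx$islands, fx$junctions,
                                   fx$genome, refinement_config())), 0)
})

test_that("two linked intergenic islands assemble into a 2-exon transcript", {
  fx <- make_new_tx_fixture()
  res <- assemble_new_transcripts(fx$islands, fx$junctions, fx$models,
                                  fx$genome, refinement_config())
  expect_equal(nrow(res$events), 1)
  tx <- res$transcripts[[res$events$transcript_id]]
  expect_equal(nrow(tx$exons), 2)
  expect_equal(unname(tx$exons[1, ]), c(300, 500))
  expect_equal(unname(tx$exons[2, ]), c(800, 1000))
})

test_that("a single island or an unlinked pair yields no transcript", {
  fx <- make_new_tx_fixture(n_islands = 1)
  res <- assemble_new_transcripts(fx$islands, fx$junctions, fx$models,
                                  fx$genome, refinement_config())
  expect_equal(nrow(res$events), 0)

  fx2 <- make_new_tx_fixture()
  fx2$junctions <- junction_table(
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), sample = character(0),
               reads = integer(0)))
  res2 <- assemble_new_transcripts(fx2$islands, fx2$junctions, fx2$models,
                                   fx2$genome, refinement_config())
  expect_equal(nrow(res2$events), 0)
})

test_that("chains overlapping annotated transcripts are not intergenic", {
  # an annotated gene whose intron covers the chain region blocks assembly
  fx <- make_new_tx_fixture(annotated = c(100, 200, 1100, 1200))
  res <- assemble_new_transcripts(fx$islands, fx$junctions, fx$models,
                                  fx$genome, refinement_config())
  expect_equal(nrow(res$events), 0)
})

test_that("novel-transcript clustering matches a connected-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    txs <- lapply(seq_len(n), function(i) {
      s <- sample(seq(0, 5000, 250), 1)
      toy_tx(sprintf("n%02d", i),
             c(s, s + 200, s + 300, s + 500),
             strand = sample(c("+", "-"), 1))
    })
    got <- cluster_new_transcripts(txs)
    # oracle: explicit linkage graph + igraph components
    g <- igraph::make_empty_graph(n, directed = FALSE)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      a <- txs[[i]]; b <- txs[[j]]
      share_jx <- nrow(merge(introns_of(a), introns_of(b))) > 0
      ovl <- FALSE
      if (a$chrom == b$chrom && a$strand == b$strand)
        for (x in seq_len(nrow(a$exons)))
          if (any(b$exons[, 1] < a$exons[x, 2] &
                    b$exons[, 2] > a$exons[x, 1])) ovl <- TRUE
      if (share_jx || ovl) g <- igraph::add_edges(g, c(i, j))
    }
    comp <- igraph::components(g)$membership
    # identical partitions (up to labels)
    expect_equal(length(unique(got)), length(unique(comp)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      expect_equal(unname(got[i] == got[j]), unname(comp[i] == comp[j]))
  }
})

test_that("same-strand exonic overlap links, opposite strands do not", {
  a <- toy_tx("a", c(100, 300, 400, 600), strand = "+")
  b <- toy_tx("b", c(200, 350, 450, 700), strand = "+")
  expect_equal(length(unique(cluster_new_transcripts(list(a, b)))), 1)
  b2 <- toy_tx("b", c(200, 350, 450, 700), strand = "-")
  expect_equal(length(unique(cluster_new_transcripts(list(a, b2)))), 2)
  # shared junction links even without exon overlap
  c1 <- toy_tx("c1", c(100, 200, 500, 600), strand = "+")
  c2 <- toy_tx("c2", c(150, 200, 500, 550), strand = "+")
  expect_equal(length(unique(cluster_new_transcripts(list(c1, c2)))), 1)
})
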